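#' Assemble a multivariable MR instrument set
#'
#' Instruments are the union of each exposure's genome-wide-significant,
#' LD-clumped variants. For every union member the association with every
#' exposure is looked up (variants missing from any exposure GWAS are dropped
#' and audited, rather than imputed as zero), all exposure betas are aligned
#' to a shared effect allele, and the set is harmonized against the outcome
#' with the same rules as [harmonize()] (missing-in-outcome, palindromic,
#' outcome-significant, allele-mismatch).
#'
#' @param exposures named list of `summary_stats` (primary exposure first),
#'   full GWAS tables.
#' @param outcome `summary_stats` of the outcome GWAS.
#' @param p_threshold instrument selection threshold (default 5e-8).
#' @param ld optional LD r-squared matrix for clumping the union (passed to
#'   [clump()]); skipped when `NULL`.
#' @param outcome_p_exclude outcome-significance exclusion (default 5e-8).
#' @param r2_threshold,window_kb clumping parameters.
#' @return An `mvmr_set`: list with `exposure_names`, `variants` (data.frame
#'   with one `beta_<exposure>` / `se_<exposure>` column pair per exposure
#'   plus `beta_out`, `se_out`) and `audit`.
#' @export
build_mvmr_set <- function(exposures, outcome, p_threshold = 5e-8, ld = NULL,
                           outcome_p_exclude = 5e-8,
                           r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(is.list(exposures), length(exposures) >= 2,
            inherits(outcome, "summary_stats"))
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    names(exposures) <- vapply(exposures, function(e) e$trait_name, character(1))
  }
  e_names <- names(exposures)

  # union of per-exposure instruments (selected, then clumped if LD given)
  inst <- lapply(exposures, function(e) {
    s <- suppressWarnings(select_instruments(e, p_threshold))
    if (!is.null(ld) && nrow(s$records) > 0) s <- clump(s, ld, r2_threshold, window_kb)
    s$records
  })
  union_ids <- unique(unlist(lapply(inst, `[[`, "variant_id")))
  if (length(union_ids) == 0) stop("build_mvmr_set: empty instrument union")

  # allele reference: first exposure contributing each variant
  ref <- do.call(rbind, lapply(exposures, function(e) {
    e$records[e$records$variant_id %in% union_ids,
              c("variant_id", "effect_allele", "other_allele", "eaf"), drop = FALSE]
  }))
  ref <- ref[!duplicated(ref$variant_id), , drop = FALSE]
  ref <- ref[match(union_ids, ref$variant_id), , drop = FALSE]

  audit <- c(missing_in_exposure = 0L, missing_in_outcome = 0L,
             palindromic = 0L, outcome_significant = 0L, allele_mismatch = 0L)

  # cross-exposure lookup, aligned to the reference allele
  bmat <- matrix(NA_real_, length(union_ids), length(e_names),
                 dimnames = list(union_ids, e_names))
  smat <- bmat
  for (en in e_names) {
    er <- exposures[[en]]$records
    m <- match(union_ids, er$variant_id)
    hit <- !is.na(m)
    same <- hit & er$effect_allele[m] == ref$effect_allele &
                  er$other_allele[m] == ref$other_allele
    flp <- hit & er$effect_allele[m] == ref$other_allele &
                 er$other_allele[m] == ref$effect_allele
    bmat[same, en] <- er$beta[m[same]]
    bmat[flp, en] <- -er$beta[m[flp]]
    smat[same | flp, en] <- er$se[m[same | flp]]
  }
  complete <- stats::complete.cases(bmat)
  audit["missing_in_exposure"] <- sum(!complete)
  union_ids <- union_ids[complete]
  ref <- ref[complete, , drop = FALSE]
  bmat <- bmat[complete, , drop = FALSE]
  smat <- smat[complete, , drop = FALSE]

  # outcome harmonization, same filter order as harmonize()
  ou <- outcome$records
  present <- union_ids %in% ou$variant_id
  audit["missing_in_outcome"] <- sum(!present)
  keep <- present
  pal <- is_palindromic(ref$effect_allele, ref$other_allele) & keep
  audit["palindromic"] <- sum(pal)
  keep <- keep & !pal
  om <- ou[match(union_ids, ou$variant_id), , drop = FALSE]
  sig <- keep & om$pval < outcome_p_exclude
  audit["outcome_significant"] <- sum(sig)
  keep <- keep & !sig
  same <- om$effect_allele == ref$effect_allele & om$other_allele == ref$other_allele
  flp <- om$effect_allele == ref$other_allele & om$other_allele == ref$effect_allele
  mism <- keep & !(same | flp)
  audit["allele_mismatch"] <- sum(mism)
  keep <- keep & !mism

  if (!any(keep)) stop("build_mvmr_set: zero variants retained")
  beta_out <- ifelse(same, om$beta, -om$beta)[keep]
  variants <- data.frame(variant_id = union_ids[keep], stringsAsFactors = FALSE)
  for (en in e_names) {
    variants[[paste0("beta_", en)]] <- bmat[keep, en]
    variants[[paste0("se_", en)]] <- smat[keep, en]
  }
  variants$beta_out <- beta_out
  variants$se_out <- om$se[keep]
  rownames(variants) <- NULL

  structure(list(exposure_names = e_names, outcome_name = outcome$trait_name,
                 variants = variants, audit = audit),
            class = "mvmr_set")
}

#' Construct an mvmr_set directly from aligned matrices
#'
#' For simulations and tests where exposure-beta matrices are already aligned
#' to a shared effect allele.
#'
#' @param beta_exp J x E matrix of exposure betas (columns named).
#' @param se_exp J x E matrix of exposure standard errors.
#' @param beta_out,se_out outcome associations.
#' @param variant_id optional ids.
#' @param outcome_name label.
#' @return An `mvmr_set`.
#' @export
mvmr_set <- function(beta_exp, se_exp, beta_out, se_out, variant_id = NULL,
                     outcome_name = "outcome") {
  beta_exp <- as.matrix(beta_exp)
  se_exp <- as.matrix(se_exp)
  j <- nrow(beta_exp)
  if (is.null(colnames(beta_exp))) {
    colnames(beta_exp) <- paste0("exposure", seq_len(ncol(beta_exp)))
  }
  e_names <- colnames(beta_exp)
  if (is.null(variant_id)) variant_id <- paste0("snp", seq_len(j))
  variants <- data.frame(variant_id = as.character(variant_id),
                         stringsAsFactors = FALSE)
  for (k in seq_along(e_names)) {
    variants[[paste0("beta_", e_names[k])]] <- beta_exp[, k]
    variants[[paste0("se_", e_names[k])]] <- se_exp[, k]
  }
  variants$beta_out <- beta_out
  variants$se_out <- se_out
  structure(list(exposure_names = e_names, outcome_name = outcome_name,
                 variants = variants,
                 audit = c(missing_in_exposure = 0L, missing_in_outcome = 0L,
                           palindromic = 0L, outcome_significant = 0L,
                           allele_mismatch = 0L)),
            class = "mvmr_set")
}

#' Multivariable IVW
#'
#' Weighted multiple regression of the outcome betas on the matrix of exposure
#' betas with no intercept and weights `1/se_out^2`, giving each exposure's
#' direct effect conditional on the others. Standard errors carry the
#' multiplicative random-effects inflation `max(1, sqrt(RSS_w / (J - E)))`.
#'
#' @param m an `mvmr_set` with more variants than exposures.
#' @return list of `mr_estimate` (method `"mvmr_ivw"`), one per exposure, in
#'   exposure order, named.
#' @export
mvmr_ivw <- function(m) {
  stopifnot(inherits(m, "mvmr_set"))
  v <- m$variants
  e_names <- m$exposure_names
  x <- as.matrix(v[, paste0("beta_", e_names), drop = FALSE])
  j <- nrow(x); e <- ncol(x)
  if (j <= e) stop("mvmr_ivw: need more variants (", j, ") than exposures (", e, ")")
  qrx <- qr(x)
  if (qrx$rank < e) {
    bad <- e_names[qrx$pivot[(qrx$rank + 1):e]]
    stop("mvmr_ivw: collinear exposure matrix; offending exposure(s): ",
         paste(bad, collapse = ", "))
  }
  w <- 1 / v$se_out^2
  xw <- x * sqrt(w)
  yw <- v$beta_out * sqrt(w)
  xtx_inv <- chol2inv(chol(crossprod(xw)))
  coef <- drop(xtx_inv %*% crossprod(xw, yw))
  rss <- sum((yw - xw %*% coef)^2)
  phi <- max(1, sqrt(rss / (j - e)))
  ses <- phi * sqrt(diag(xtx_inv))
  out <- lapply(seq_len(e), function(k) {
    mr_estimate("mvmr_ivw", beta = coef[k], se = ses[k], n_snps = j,
                exposure = e_names[k], phi = phi)
  })
  names(out) <- e_names
  out
}
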