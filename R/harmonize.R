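#' Harmonize exposure instruments against an outcome GWAS
#'
#' Aligns outcome associations to the exposure's effect allele and applies,
#' in order, the standard exclusion filters, each tallied in the audit:
#'
#' 1. `missing_in_outcome`: instruments absent from the outcome GWAS;
#' 2. `palindromic`: variants with complementary alleles (A/T or C/G),
#'    removed regardless of allele frequency because strand orientation is
#'    ambiguous;
#' 3. `outcome_significant`: variants associated with the outcome at
#'    `pval < outcome_p_exclude`, which would violate the exclusion
#'    restriction;
#' 4. `allele_mismatch`: variants whose outcome alleles match the exposure
#'    pair in neither orientation.
#'
#' When the outcome effect allele equals the exposure other allele (flipped
#' orientation), the outcome beta is negated and the outcome eaf replaced by
#' `1 - eaf`.
#'
#' @param exposure `summary_stats` of selected, clumped instruments.
#' @param outcome `summary_stats` of the outcome GWAS.
#' @param outcome_p_exclude outcome-significance exclusion threshold
#'   (default 5e-8).
#' @return A `harmonized_set`: list with `exposure_name`, `outcome_name`,
#'   `variants` (data.frame: `variant_id`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`, `eaf`, `pval_exp`, `pval_out`) and `audit` (named integer
#'   vector of drop counts summing to input minus retained).
#' @export
harmonize <- function(exposure, outcome, outcome_p_exclude = 5e-8) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  ex <- exposure$records
  ou <- outcome$records
  n_in <- nrow(ex)
  audit <- c(missing_in_outcome = 0L, palindromic = 0L,
             outcome_significant = 0L, allele_mismatch = 0L)

  # 1. missing in outcome
  present <- ex$variant_id %in% ou$variant_id
  audit["missing_in_outcome"] <- sum(!present)
  ex <- ex[present, , drop = FALSE]

  # 2. palindromic (complementary allele pair), regardless of eaf
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  audit["palindromic"] <- sum(pal)
  ex <- ex[!pal, , drop = FALSE]

  # 3. outcome-significant
  om <- ou[match(ex$variant_id, ou$variant_id), , drop = FALSE]
  sig <- om$pval < outcome_p_exclude
  audit["outcome_significant"] <- sum(sig)
  ex <- ex[!sig, , drop = FALSE]
  om <- om[!sig, , drop = FALSE]

  # 4. allele orientation
  same <- om$effect_allele == ex$effect_allele & om$other_allele == ex$other_allele
  flip <- om$effect_allele == ex$other_allele & om$other_allele == ex$effect_allele
  mism <- !(same | flip)
  audit["allele_mismatch"] <- sum(mism)
  ex <- ex[!mism, , drop = FALSE]
  om <- om[!mism, , drop = FALSE]
  same <- same[!mism]

  beta_out <- ifelse(same, om$beta, -om$beta)

  variants <- data.frame(
    variant_id = ex$variant_id,
    beta_exp = ex$beta, se_exp = ex$se,
    beta_out = beta_out, se_out = om$se,
    eaf = ex$eaf,
    pval_exp = ex$pval, pval_out = om$pval,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    stringsAsFactors = FALSE
  )
  rownames(variants) <- NULL
  stopifnot(sum(audit) == n_in - nrow(variants))
  if (nrow(variants) == 0) {
    stop("harmonize: zero variants retained for ", exposure$trait_name,
         " -> ", outcome$trait_name)
  }
  structure(list(exposure_name = exposure$trait_name,
                 outcome_name = outcome$trait_name,
                 variants = variants, audit = audit),
            class = "harmonized_set")
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s, %d variants retained\n",
              x$exposure_name, x$outcome_name, nrow(x$variants)))
  cat("  dropped:", paste(sprintf("%s=%d", names(x$audit), x$audit),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Construct a harmonized_set directly from aligned vectors
#'
#' Convenience constructor for simulations and tests where exposure and
#' outcome betas are already expressed on a shared effect allele.
#'
#' @param beta_exp,se_exp exposure associations and standard errors.
#' @param beta_out,se_out outcome associations and standard errors.
#' @param variant_id optional ids (default `snp1..snpJ`).
#' @param eaf optional effect-allele frequencies.
#' @param exposure_name,outcome_name labels.
#' @return A `harmonized_set` with an all-zero audit.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           variant_id = NULL, eaf = NA_real_,
                           exposure_name = "exposure", outcome_name = "outcome") {
  j <- length(beta_exp)
  stopifnot(length(se_exp) == j, length(beta_out) == j, length(se_out) == j,
            all(se_exp > 0), all(se_out > 0))
  if (is.null(variant_id)) variant_id <- paste0("snp", seq_len(j))
  variants <- data.frame(
    variant_id = as.character(variant_id),
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out,
    eaf = rep_len(eaf, j),
    pval_exp = 2 * stats::pnorm(-abs(beta_exp / se_exp)),
    pval_out = 2 * stats::pnorm(-abs(beta_out / se_out)),
    effect_allele = "A", other_allele = "G",
    stringsAsFactors = FALSE
  )
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 variants = variants,
                 audit = c(missing_in_outcome = 0L, palindromic = 0L,
                           outcome_significant = 0L, allele_mismatch = 0L)),
            class = "harmonized_set")
}

#' Write / read an LD r-squared matrix as TSV
#'
#' Square matrix with a variant-id header row and first column.
#'
#' @param ld numeric matrix with variant-id dimnames.
#' @param path file path.
#' @return `write_ld_matrix` returns `path` invisibly; `read_ld_matrix`
#'   returns the matrix.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(is.matrix(ld), !is.null(rownames(ld)))
  out <- data.frame(variant_id = rownames(ld), ld, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- ids
  colnames(m) <- names(tab)[-1]
  storage.mode(m) <- "double"
  m
}
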