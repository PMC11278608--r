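#' GWAS summary statistics container
#'
#' A `summary_stats` object holds one trait's GWAS summary associations, one
#' row per variant. Betas are log-odds for binary traits and SD units for
#' continuous traits. Rows violating hard invariants (non-positive standard
#' error, p-value outside (0, 1], identical or malformed alleles, allele
#' frequency outside (0, 1), sample size < 1, duplicated variant id) are
#' dropped with a message; rows whose p-value disagrees with the normal
#' approximation 2*pnorm(-|beta/se|) by more than 10% (relative, on the z
#' scale) are kept but flagged in the `zp_flag` column, since published GWAS
#' tables round both fields.
#'
#' @param records data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and optionally `eaf`, `n`, `chr`,
#'   `pos`.
#' @param trait_name trait label.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param quiet suppress the dropped-row message.
#' @return A `summary_stats` object: list with `trait_name`, `trait_type`,
#'   `records` (validated data.frame) and `n_dropped` (named counts).
#' @export
summary_stats <- function(records, trait_name, trait_type = c("continuous", "binary"),
                          quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  req <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) {
    stop("summary_stats: missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  rec$variant_id <- as.character(rec$variant_id)
  rec$effect_allele <- toupper(as.character(rec$effect_allele))
  rec$other_allele <- toupper(as.character(rec$other_allele))
  for (col in c("eaf", "n", "chr", "pos")) {
    if (!col %in% names(rec)) rec[[col]] <- NA_real_
  }
  rec$beta <- as.numeric(rec$beta)
  rec$se <- as.numeric(rec$se)
  rec$pval <- as.numeric(rec$pval)
  rec$eaf <- as.numeric(rec$eaf)
  rec$n <- as.numeric(rec$n)

  bases <- c("A", "C", "G", "T")
  drop <- list(
    bad_allele   = !(rec$effect_allele %in% bases) | !(rec$other_allele %in% bases) |
                   rec$effect_allele == rec$other_allele,
    bad_se       = !is.finite(rec$se) | rec$se <= 0,
    bad_pval     = !is.finite(rec$pval) | rec$pval <= 0 | rec$pval > 1,
    bad_beta     = !is.finite(rec$beta),
    bad_eaf      = !is.na(rec$eaf) & (rec$eaf <= 0 | rec$eaf >= 1),
    bad_n        = !is.na(rec$n) & rec$n < 1,
    dup_id       = duplicated(rec$variant_id)
  )
  bad <- Reduce(`|`, drop)
  n_dropped <- vapply(drop, sum, integer(1))
  if (any(bad) && !quiet) {
    message("summary_stats [", trait_name, "]: dropped ", sum(bad),
            " invalid row(s) (",
            paste(sprintf("%s=%d", names(n_dropped)[n_dropped > 0],
                          n_dropped[n_dropped > 0]), collapse = ", "), ")")
  }
  rec <- rec[!bad, , drop = FALSE]

  # z/p consistency flag (10% relative tolerance on z; rounding-tolerant)
  z_from_p <- stats::qnorm(pmax(rec$pval, .Machine$double.xmin) / 2, lower.tail = FALSE)
  z_obs <- abs(rec$beta / rec$se)
  rec$zp_flag <- is.finite(z_from_p) & z_obs > 0 &
    abs(z_from_p - z_obs) > 0.1 * pmax(z_obs, z_from_p)
  rec <- rec[, c("variant_id", "effect_allele", "other_allele", "eaf",
                 "beta", "se", "pval", "n", "chr", "pos", "zp_flag"),
             drop = FALSE]
  rownames(rec) <- NULL

  structure(list(trait_name = trait_name, trait_type = trait_type,
                 records = rec, n_dropped = n_dropped),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d variants\n",
              x$trait_name, x$trait_type, nrow(x$records)))
  invisible(x)
}

#' Number of variants in a summary_stats object
#' @param stats a `summary_stats` object.
#' @return integer count.
#' @export
n_variants <- function(stats) nrow(stats$records)

# canonical TSV column order of the on-disk dialect
.ss_cols <- c("SNP", "chr", "pos", "effect_allele", "other_allele",
              "eaf", "beta", "se", "pval", "n")

#' Read GWAS summary statistics from a TSV file
#'
#' The native dialect has columns `SNP, chr, pos, effect_allele, other_allele,
#' eaf, beta, se, pval, n` with missing eaf encoded as `NA`. Foreign headers
#' are adapted through `dialect`, a named character vector mapping canonical
#' names to the file's column names, e.g.
#' `c(SNP = "rsid", beta = "Effect")`.
#'
#' @param path path to a tab-separated file.
#' @param trait_name trait label; default the file name without extension.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param dialect optional named character vector remapping column names.
#' @param quiet passed to [summary_stats()].
#' @return A `summary_stats` object.
#' @export
read_summary_stats <- function(path, trait_name = NULL,
                               trait_type = c("continuous", "binary"),
                               dialect = NULL, quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("read_summary_stats: file not found: ", path)
  if (is.null(trait_name)) trait_name <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (nrow(tab) == 0) stop("read_summary_stats: empty file: ", path)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(tab)) {
        stop("read_summary_stats: dialect column '", src, "' (for '", canon,
             "') not present in ", path)
      }
      names(tab)[names(tab) == src] <- canon
    }
  }
  mandatory <- c("SNP", "effect_allele", "other_allele", "beta", "se", "pval")
  miss <- setdiff(mandatory, names(tab))
  if (length(miss) > 0) {
    stop("read_summary_stats: missing mandatory column(s): ",
         paste(miss, collapse = ", "), " (use `dialect` to remap)")
  }
  names(tab)[names(tab) == "SNP"] <- "variant_id"
  summary_stats(tab, trait_name = trait_name, trait_type = trait_type, quiet = quiet)
}

#' Write GWAS summary statistics in the native TSV dialect
#'
#' Round-trips exactly through [read_summary_stats()]: numeric fields are
#' written with 17 significant digits.
#'
#' @param stats a `summary_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  rec <- stats$records
  out <- data.frame(
    SNP = rec$variant_id, chr = rec$chr, pos = rec$pos,
    effect_allele = rec$effect_allele, other_allele = rec$other_allele,
    eaf = rec$eaf, beta = rec$beta, se = rec$se, pval = rec$pval, n = rec$n,
    stringsAsFactors = FALSE
  )
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA_character_, formatC(x, digits = 17, format = "g"))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Select genome-wide-significant instruments
#'
#' Retains exactly the variants with `pval < p_threshold` (default the
#' conventional genome-wide significance level 5e-8).
#'
#' @param stats a `summary_stats` object.
#' @param p_threshold significance threshold in (0, 1).
#' @return A `summary_stats` object restricted to significant variants. Zero
#'   survivors raise a warning, not an error.
#' @export
select_instruments <- function(stats, p_threshold = 5e-8) {
  stopifnot(inherits(stats, "summary_stats"),
            is.numeric(p_threshold), length(p_threshold) == 1,
            p_threshold > 0, p_threshold <= 1)
  keep <- stats$records$pval < p_threshold
  out <- stats
  out$records <- stats$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  if (nrow(out$records) == 0) {
    warning("select_instruments: no variant passes p < ", p_threshold,
            " for trait '", stats$trait_name, "'")
  }
  out
}

#' Greedy LD clumping
#'
#' Standard greedy clumping: variants are visited in ascending p-value order
#' (ties broken by variant id, lexicographically); a variant is accepted iff
#' its LD r-squared with every already-accepted variant on the same chromosome
#' within `window_kb` kilobases is below `r2_threshold`. The returned object
#' keeps the input row order restricted to the accepted set, so the result is
#' invariant to input permutation.
#'
#' @param stats a `summary_stats` object with `chr` and `pos` filled in.
#' @param ld square numeric matrix of pairwise r-squared values with variant
#'   ids as dimnames, symmetric with unit diagonal, covering all variants.
#' @param r2_threshold LD r-squared threshold (default 0.001).
#' @param window_kb window half-width in kilobases (default 10000); variants
#'   farther apart than this are treated as independent.
#' @return A clumped `summary_stats` object.
#' @export
clump <- function(stats, ld, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(stats, "summary_stats"), is.matrix(ld))
  rec <- stats$records
  if (nrow(rec) == 0) return(stats)
  if (any(is.na(rec$chr)) || any(is.na(rec$pos))) {
    stop("clump: all variants need chr and pos")
  }
  missing_ld <- setdiff(rec$variant_id, rownames(ld))
  if (length(missing_ld) > 0) {
    stop("clump: variant(s) absent from LD matrix: ",
         paste(utils::head(missing_ld, 5), collapse = ", "),
         if (length(missing_ld) > 5) ", ...")
  }
  ord <- order(rec$pval, rec$variant_id)
  accepted <- character(0)
  for (i in ord) {
    id <- rec$variant_id[i]
    if (length(accepted) > 0) {
      acc <- rec[match(accepted, rec$variant_id), , drop = FALSE]
      near <- acc$chr == rec$chr[i] &
        abs(acc$pos - rec$pos[i]) <= window_kb * 1000
      if (any(near) && any(ld[id, acc$variant_id[near]] >= r2_threshold)) next
    }
    accepted <- c(accepted, id)
  }
  out <- stats
  out$records <- rec[rec$variant_id %in% accepted, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Instrument-strength F statistic
#'
#' Per-variant variance explained is computed as `2*eaf*(1-eaf)*beta^2`
#' (unit-variance phenotype assumed), summed into a total R-squared, and the
#' F statistic follows `F = R2 * (N - K - 1) / (K * (1 - R2))` with K the
#' number of instruments and N the sample size. `F <= 10` flags the instrument
#' set as weak by the usual convention.
#'
#' @param stats a `summary_stats` object of instruments (continuous-trait
#'   betas in SD units); every record needs `eaf`.
#' @param n sample size of the exposure GWAS; must exceed K + 1.
#' @return A list of class `instrument_strength`: `r2_total`, `k`, `n`,
#'   `f_stat`, `weak`, `per_variant_r2` (named).
#' @export
f_statistics <- function(stats, n) {
  stopifnot(inherits(stats, "summary_stats"), is.numeric(n), length(n) == 1)
  rec <- stats$records
  k <- nrow(rec)
  if (k == 0) stop("f_statistics: no instruments")
  if (n <= k + 1) stop("f_statistics: need n > k + 1 (n = ", n, ", k = ", k, ")")
  if (any(is.na(rec$eaf))) {
    stop("f_statistics: missing eaf for variant(s): ",
         paste(utils::head(rec$variant_id[is.na(rec$eaf)], 5), collapse = ", "))
  }
  r2 <- 2 * rec$eaf * (1 - rec$eaf) * rec$beta^2
  names(r2) <- rec$variant_id
  r2_total <- sum(r2)
  if (r2_total >= 1) stop("f_statistics: total R-squared >= 1; inconsistent inputs")
  f <- r2_total * (n - k - 1) / (k * (1 - r2_total))
  structure(list(r2_total = r2_total, k = k, n = n, f_stat = f,
                 weak = f <= 10, per_variant_r2 = r2),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: R2 = %.4g over %d variants (n = %g), F = %.2f%s\n",
              x$r2_total, x$k, x$n, x$f_stat,
              if (x$weak) " [weak: F <= 10]" else ""))
  invisible(x)
}
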