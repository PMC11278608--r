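#' Cochran's Q heterogeneity test
#'
#' Heterogeneity of the per-variant Wald ratios around the IVW estimate:
#' `Q = sum_j w_j (r_j - beta_IVW)^2` with `r_j = beta_out_j / beta_exp_j`
#' and `w_j = (beta_exp_j / se_out_j)^2`, referred to a chi-squared
#' distribution with J - 1 degrees of freedom.
#'
#' @param h a `harmonized_set` with at least 2 variants.
#' @return list `(Q, df, p)`.
#' @export
cochran_q <- function(h) {
  v <- .h_variants(h)
  j <- nrow(v)
  if (j < 2) stop("cochran_q: need >= 2 variants")
  r <- v$beta_out / v$beta_exp
  w <- (v$beta_exp / v$se_out)^2
  beta <- sum(w * r) / sum(w)
  q <- sum(w * (r - beta)^2)
  list(Q = q, df = j - 1L, p = stats::pchisq(q, j - 1, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept component of [egger()] with its two-sided normal p-value. A
#' nonzero intercept indicates that the average pleiotropic effect across
#' instruments differs from zero.
#'
#' @param h a `harmonized_set` with at least 3 variants.
#' @return list `(b, se, p)`.
#' @export
egger_intercept_test <- function(h) {
  int <- egger(h)$intercept
  list(b = int$beta, se = int$se, p = int$pval)
}

# leave-one-out IVW point estimates, vectorized:
# beta_(-j) = (S1 - w_j bx_j by_j) / (S2 - w_j bx_j^2)
.loo_ivw_beta <- function(bx, by, w) {
  s1 <- sum(w * bx * by)
  s2 <- sum(w * bx^2)
  (s1 - w * bx * by) / (s2 - w * bx^2)
}

#' MR-PRESSO outlier detection and correction
#'
#' Simulation-based residual-sum-of-squares test for horizontal pleiotropy:
#'
#' * **Global test** — observed `RSS = sum_j r_j^2` with
#'   `r_j = beta_out_j - beta_IVW(-j) * beta_exp_j` (leave-one-out expected
#'   values); the null distribution is built by drawing, `n_sim` times,
#'   `beta_out*_j ~ N(beta_IVW(-j) * beta_exp_j, se_out_j)` and recomputing
#'   the RSS on the simulated data. The global p-value is the +1-smoothed
#'   empirical exceedance probability (floor `1/(n_sim+1)`).
#' * **Outlier test** — each variant's squared residual is compared with its
#'   simulated counterparts; the +1-smoothed empirical p-value is Bonferroni
#'   corrected over J, and variants with corrected p below `signif` are
#'   flagged.
#' * **Corrected estimate** — IVW on the unflagged variants (absent if all
#'   are flagged).
#' * **Distortion test** — the relative difference between corrected and
#'   original estimates is compared with a bootstrap distribution obtained by
#'   removing `n_boot` random subsets of the same size as the flagged set.
#'
#' @param h a `harmonized_set` with at least 4 variants.
#' @param n_sim simulation draws for the null distribution (default 1000).
#' @param signif significance level for outlier calls (default 0.05).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param n_boot random subsets for the distortion test (default 1000).
#' @return list of class `mr_presso`: `global_rss`, `global_p`,
#'   `outlier_ids`, `outlier_p` (named, Bonferroni-corrected),
#'   `raw_estimate`, `corrected_estimate` (or `NULL`), `distortion_p`
#'   (`NA` when no outliers are flagged).
#' @export
mr_presso <- function(h, n_sim = 1000, signif = 0.05, seed = 1, n_boot = 1000) {
  v <- .h_variants(h)
  j <- nrow(v)
  if (j < 4) stop("mr_presso: need >= 4 variants (have ", j, ")")
  bx <- v$beta_exp
  by <- v$beta_out
  seY <- v$se_out
  w <- 1 / seY^2

  loo_beta <- .loo_ivw_beta(bx, by, w)
  expected <- loo_beta * bx
  res_obs <- by - expected
  rss_obs <- sum(res_obs^2)

  sim <- with_seed(seed, {
    # J x n_sim simulated outcome betas under the no-pleiotropy null
    by_star <- matrix(stats::rnorm(j * n_sim, mean = expected, sd = seY),
                      nrow = j, ncol = n_sim)
    # leave-one-out IVW recomputed per simulated dataset (vectorized)
    s1 <- colSums(w * bx * by_star)
    s2 <- sum(w * bx^2)
    loo_num <- sweep(-(w * bx) * by_star, 2, s1, `+`)   # S1 - w_j bx_j by*_j
    loo_den <- s2 - w * bx^2
    res_sim <- by_star - (loo_num / loo_den) * bx
    list(rss = colSums(res_sim^2), res2 = res_sim^2)
  })

  global_p <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  p_out <- (1 + rowSums(sim$res2 >= res_obs^2)) / (n_sim + 1)
  p_out_adj <- pmin(1, p_out * j)
  names(p_out_adj) <- v$variant_id
  flagged <- v$variant_id[p_out_adj < signif]

  raw <- ivw(h)
  corrected <- NULL
  distortion_p <- NA_real_
  if (length(flagged) > 0 && length(flagged) < j - 1) {
    keep <- !(v$variant_id %in% flagged)
    h_keep <- h
    h_keep$variants <- v[keep, , drop = FALSE]
    corrected <- ivw(h_keep)
    d_obs <- (corrected$beta - raw$beta) / abs(raw$beta)
    d_boot <- with_seed(seed + 1L, {
      vapply(seq_len(n_boot), function(b) {
        drop <- sample.int(j, length(flagged))
        fit <- .ivw_fit(bx[-drop], by[-drop], seY[-drop])
        (fit$beta - raw$beta) / abs(raw$beta)
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_boot) >= abs(d_obs))) / (n_boot + 1)
  }

  structure(list(global_rss = rss_obs, global_p = global_p,
                 outlier_ids = flagged, outlier_p = p_out_adj,
                 raw_estimate = raw, corrected_estimate = corrected,
                 distortion_p = distortion_p,
                 n_sim = n_sim, signif = signif),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.4g, global p = %.4g (%d sims)\n",
              x$global_rss, x$global_p, x$n_sim))
  if (length(x$outlier_ids) > 0) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
    if (!is.null(x$corrected_estimate)) {
      cat(sprintf("  corrected beta = %.4g (raw %.4g), distortion p = %.4g\n",
                  x$corrected_estimate$beta, x$raw_estimate$beta, x$distortion_p))
    }
  } else cat("  no outliers flagged\n")
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimator J times, omitting each variant in turn, to show
#' whether the pooled estimate is driven by any single instrument. Rows are
#' emitted in the input variant order.
#'
#' @param h a `harmonized_set` with at least 3 variants.
#' @return data.frame with columns `snp, beta, se, ci_low, ci_high, pval`.
#' @export
leave_one_out <- function(h) {
  v <- .h_variants(h)
  j <- nrow(v)
  if (j < 3) stop("leave_one_out: need >= 3 variants (have ", j, ")")
  rows <- lapply(seq_len(j), function(i) {
    hi <- h
    hi$variants <- v[-i, , drop = FALSE]
    est <- ivw(hi)
    data.frame(snp = v$variant_id[i], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full sensitivity battery
#'
#' Cochran's Q, the MR-Egger intercept test, MR-PRESSO and leave-one-out in
#' one report. Components whose preconditions fail are set to `NULL` with a
#' message.
#'
#' @param h a `harmonized_set`.
#' @param n_sim MR-PRESSO simulation draws.
#' @param seed RNG seed for MR-PRESSO.
#' @return list of class `sensitivity_report` with elements `cochran_q`,
#'   `egger_intercept`, `presso`, `loo`.
#' @export
sensitivity_battery <- function(h, n_sim = 1000, seed = 1) {
  try_part <- function(f) tryCatch(f(), error = function(e) {
    message("sensitivity_battery: ", conditionMessage(e))
    NULL
  })
  structure(list(
    cochran_q = try_part(function() cochran_q(h)),
    egger_intercept = try_part(function() egger_intercept_test(h)),
    presso = try_part(function() mr_presso(h, n_sim = n_sim, seed = seed)),
    loo = try_part(function() leave_one_out(h))
  ), class = "sensitivity_report")
}
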