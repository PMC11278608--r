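#' Causal-effect estimate container
#'
#' Every estimator returns an `mr_estimate`: the causal effect `beta` (log-odds
#' scale for a binary outcome, SD units otherwise), its standard error, a 95%
#' normal confidence interval `beta +/- 1.96 * se`, a two-sided normal p-value,
#' the method label and instrument count, plus method-specific diagnostics.
#'
#' @param method method label.
#' @param beta point estimate.
#' @param se standard error (> 0, or 0 for degenerate noiseless fits).
#' @param n_snps number of instruments used.
#' @param ... extra diagnostic fields stored on the object.
#' @return An `mr_estimate` object.
#' @export
mr_estimate <- function(method, beta, se, n_snps, ...) {
  stopifnot(is.numeric(beta), is.numeric(se), se >= 0)
  z <- if (se > 0) beta / se else sign(beta) * Inf
  pval <- if (se > 0) {
    max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)  # never underflow to 0
  } else as.numeric(beta == 0)
  structure(c(list(method = method, beta = beta, se = se,
                   ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                   pval = pval,
                   n_snps = as.integer(n_snps)),
              list(...)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s]: beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, %d SNPs\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps))
  if (!is.null(x$or)) {
    cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f)\n", x$or, x$or_ci_low, x$or_ci_high))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             or = if (is.null(x$or)) NA_real_ else x$or,
             or_ci_low = if (is.null(x$or_ci_low)) NA_real_ else x$or_ci_low,
             or_ci_high = if (is.null(x$or_ci_high)) NA_real_ else x$or_ci_high,
             stringsAsFactors = FALSE)
}

#' Wald ratio for a single variant
#'
#' The building block of all two-sample MR estimators: the outcome association
#' divided by the exposure association, with the first-order standard error
#' `se_out / |beta_exp|` (exposure-side uncertainty ignored).
#'
#' @param beta_exp,se_exp exposure association and standard error.
#' @param beta_out,se_out outcome association and standard error.
#' @return An `mr_estimate` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (beta_exp == 0) stop("wald_ratio: beta_exp = 0, ratio undefined")
  mr_estimate("wald_ratio", beta = beta_out / beta_exp,
              se = se_out / abs(beta_exp), n_snps = 1L)
}

.h_variants <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  h$variants
}

# core IVW fit on raw vectors; returns list(beta, se, Q, phi, se_fixed)
.ivw_fit <- function(bx, by, seY) {
  w <- 1 / seY^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  se_fixed <- sqrt(1 / sxx)
  q <- sum(w * (by - beta * bx)^2)
  j <- length(bx)
  phi <- if (j > 1) max(1, sqrt(q / (j - 1))) else 1
  list(beta = beta, se = phi * se_fixed, Q = q, phi = phi, se_fixed = se_fixed)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of the outcome betas on the exposure betas through the
#' origin with weights `1/se_out^2` — equivalently the inverse-variance
#' meta-analysis of the per-variant Wald ratios. Uses multiplicative random
#' effects: the fixed-effect standard error is inflated by
#' `max(1, sqrt(Q/(J-1)))`, so under-dispersion falls back to the fixed-effect
#' answer and heterogeneity widens the interval.
#'
#' @param h a `harmonized_set` with at least 2 variants.
#' @return An `mr_estimate` with method `"ivw"` and diagnostics `Q`, `phi`.
#' @export
ivw <- function(h) {
  v <- .h_variants(h)
  if (nrow(v) < 2) stop("ivw: need >= 2 variants (have ", nrow(v),
                        "); fall back to wald_ratio")
  fit <- .ivw_fit(v$beta_exp, v$beta_out, v$se_out)
  mr_estimate("ivw", beta = fit$beta, se = fit$se, n_snps = nrow(v),
              Q = fit$Q, phi = fit$phi)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas *with* an intercept,
#' weights `1/se_out^2`. A nonzero intercept indicates directional pleiotropy;
#' the slope is the pleiotropy-adjusted causal effect under the InSIDE
#' assumption. Inputs are oriented so all exposure betas are non-negative
#' (outcome betas flipped along) before fitting. Both coefficients share the
#' multiplicative random-effects inflation `max(1, sqrt(RSS_w/(J-2)))`.
#'
#' @param h a `harmonized_set` with at least 3 variants.
#' @return list with `slope` and `intercept`, each an `mr_estimate`.
#' @export
egger <- function(h) {
  v <- .h_variants(h)
  j <- nrow(v)
  if (j < 3) stop("egger: need >= 3 variants (have ", j, ")")
  flip <- sign(v$beta_exp)
  flip[flip == 0] <- 1
  bx <- v$beta_exp * flip
  by <- v$beta_out * flip
  w <- 1 / v$se_out^2
  xbar <- sum(w * bx) / sum(w)
  ybar <- sum(w * by) / sum(w)
  sxx <- sum(w * (bx - xbar)^2)
  if (sxx <= 0) stop("egger: no spread in exposure betas")
  slope <- sum(w * (bx - xbar) * (by - ybar)) / sxx
  intercept <- ybar - slope * xbar
  rss <- sum(w * (by - intercept - slope * bx)^2)
  phi <- max(1, sqrt(rss / (j - 2)))
  se_slope <- phi * sqrt(1 / sxx)
  se_int <- phi * sqrt(1 / sum(w) + xbar^2 / sxx)
  list(
    slope = mr_estimate("egger_slope", beta = slope, se = se_slope,
                        n_snps = j, phi = phi),
    intercept = mr_estimate("egger_intercept", beta = intercept, se = se_int,
                            n_snps = j, phi = phi)
  )
}

# weighted median of `x` with weights `w`: value at cumulative weight 0.5,
# linearly interpolated between adjacent order statistics
.weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(x[1])
  if (0.5 >= cw[length(cw)]) return(x[length(x)])
  stats::approx(cw, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' The weighted median of the per-variant Wald ratios with weights
#' `beta_exp^2 / se_out^2` (inverse variance of each ratio), consistent when
#' at least half the total weight comes from valid instruments. The standard
#' error comes from a seeded parametric bootstrap: exposure and outcome betas
#' are resampled from normal distributions centred on their estimates and the
#' weighted median recomputed.
#'
#' @param h a `harmonized_set` with at least 3 variants.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1) {
  v <- .h_variants(h)
  j <- nrow(v)
  if (j < 3) stop("weighted_median: need >= 3 variants (have ", j, ")")
  ratio <- v$beta_out / v$beta_exp
  w <- v$beta_exp^2 / v$se_out^2
  est <- .weighted_median(ratio, w)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(j, v$beta_exp, v$se_exp)
      by <- stats::rnorm(j, v$beta_out, v$se_out)
      ok <- bx != 0
      .weighted_median(by[ok] / bx[ok], bx[ok]^2 / v$se_out[ok]^2)
    }, numeric(1))
  })
  mr_estimate("weighted_median", beta = est, se = stats::sd(boot), n_snps = j)
}

# weighted Gaussian-KDE argmax over a 512-point grid; bandwidth given
.kde_mode <- function(x, w, bw, n_grid = 512) {
  w <- w / sum(w)
  grid <- seq(min(x) - 3 * bw, max(x) + 3 * bw, length.out = n_grid)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm((g - x) / bw)), numeric(1))
  grid[which.max(dens)]
}

.mode_bandwidth <- function(x, phi) {
  s <- min(stats::sd(x), stats::IQR(x) / 1.34)
  phi * 1.06 * s * length(x)^(-1 / 5)
}

#' Simple and weighted mode estimators
#'
#' Mode-based estimation: the per-variant Wald ratios are smoothed with a
#' Gaussian kernel (Silverman bandwidth `1.06 * min(SD, IQR/1.34) * J^(-1/5)`,
#' scaled by `phi`) and the causal effect is taken as the density argmax on a
#' 512-point grid spanning the ratios plus/minus three bandwidths. The simple
#' mode weights ratios uniformly; the weighted mode weights them by the
#' inverse variance of each ratio (`beta_exp^2 / se_out^2`, normalized).
#' Consistent when the largest group of instruments sharing the same ratio is
#' valid (ZEMPA). If all ratios coincide the common ratio is returned
#' directly. SE by seeded parametric bootstrap.
#'
#' @param h a `harmonized_set` with at least 3 variants.
#' @param weighted use inverse-variance weights (`TRUE`) or uniform (`FALSE`).
#' @param phi bandwidth scale factor (default 1).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_mode"` or `"simple_mode"`.
#' @export
mode_estimate <- function(h, weighted = TRUE, phi = 1, n_boot = 1000, seed = 1) {
  v <- .h_variants(h)
  j <- nrow(v)
  if (j < 3) stop("mode_estimate: need >= 3 variants (have ", j, ")")
  point <- function(bx, by, seY) {
    r <- by / bx
    w <- if (weighted) bx^2 / seY^2 else rep(1, length(r))
    bw <- .mode_bandwidth(r, phi)
    if (!is.finite(bw) || bw <= 0) return(r[1])
    .kde_mode(r, w, bw)
  }
  est <- point(v$beta_exp, v$beta_out, v$se_out)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(j, v$beta_exp, v$se_exp)
      by <- stats::rnorm(j, v$beta_out, v$se_out)
      ok <- bx != 0
      point(bx[ok], by[ok], v$se_out[ok])
    }, numeric(1))
  })
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
              beta = est, se = stats::sd(boot), n_snps = j)
}

#' Express an estimate on the odds-ratio scale
#'
#' For a binary outcome whose betas are log-odds, attaches
#' `or = exp(beta)`, `or_ci_low = exp(ci_low)`, `or_ci_high = exp(ci_high)`.
#'
#' @param est an `mr_estimate` with beta on the log-odds scale.
#' @return The estimate with `or`, `or_ci_low`, `or_ci_high` fields set.
#' @export
to_odds_ratio <- function(est) {
  stopifnot(inherits(est, "mr_estimate"))
  est$or <- exp(est$beta)
  est$or_ci_low <- exp(est$ci_low)
  est$or_ci_high <- exp(est$ci_high)
  est
}

#' Run the full estimator battery on a harmonized set
#'
#' IVW (primary), MR-Egger slope, weighted median, simple mode and weighted
#' mode, as one tidy table. Estimators whose instrument-count preconditions
#' fail are skipped with a message.
#'
#' @param h a `harmonized_set`.
#' @param n_boot bootstrap draws for median/mode standard errors.
#' @param seed RNG seed for the bootstraps.
#' @param or_scale also report odds-ratio columns (binary outcome).
#' @return data.frame with one row per method (columns `method, nsnp, beta,
#'   se, ci_low, ci_high, pval, or, or_ci_low, or_ci_high`).
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed = 1, or_scale = TRUE) {
  fits <- list()
  add <- function(f) {
    est <- tryCatch(f(), error = function(e) {
      message("mr_all_methods: skipped - ", conditionMessage(e))
      NULL
    })
    if (!is.null(est)) fits[[length(fits) + 1]] <<- est
  }
  add(function() ivw(h))
  add(function() egger(h)$slope)
  add(function() weighted_median(h, n_boot = n_boot, seed = seed))
  add(function() mode_estimate(h, weighted = FALSE, n_boot = n_boot, seed = seed))
  add(function() mode_estimate(h, weighted = TRUE, n_boot = n_boot, seed = seed))
  if (or_scale) fits <- lapply(fits, to_odds_ratio)
  do.call(rbind, lapply(fits, as.data.frame))
}
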