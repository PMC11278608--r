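#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH: order the m p-values ascending, set
#' `adj_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1, and return the
#' adjusted values in the original input order.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stopifnot(all(pvals > 0 & pvals <= 1))
  m <- length(pvals)
  ord <- order(pvals)
  adj <- pmin(1, rev(cummin(rev(m * pvals[ord] / seq_len(m)))))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Delta-method indirect effect
#'
#' Product-of-coefficients mediated effect: `point = beta1 * beta2` with the
#' first-order delta-method standard error
#' `sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)` (the two estimates come from
#' non-overlapping samples, so the cross-covariance term is dropped) and a
#' 95% normal confidence interval.
#'
#' @param beta1,se1 exposure-to-mediator effect and its standard error.
#' @param beta2,se2 mediator-to-outcome effect and its standard error.
#' @return list `(point, se, ci_low, ci_high)`.
#' @export
indirect_effect <- function(beta1, se1, beta2, se2) {
  stopifnot(se1 > 0, se2 > 0)
  point <- beta1 * beta2
  se <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  list(point = point, se = se,
       ci_low = point - 1.96 * se, ci_high = point + 1.96 * se)
}

#' Proportion of the total effect that is mediated
#'
#' `100 * indirect / total`, in percent. Negative when the indirect effect
#' opposes the total effect (direction-inconsistent mediation).
#'
#' @param indirect indirect (mediated) effect `beta1 * beta2`.
#' @param total total exposure-to-outcome effect (nonzero), on the same scale.
#' @return proportion mediated, percent.
#' @export
proportion_mediated <- function(indirect, total) {
  if (total == 0) stop("proportion_mediated: total effect is zero; undefined")
  100 * indirect / total
}

# univariable select -> clump -> harmonize -> IVW for one exposure/outcome pair
.uni_mr <- function(exposure, outcome, cfg) {
  sel <- suppressWarnings(select_instruments(exposure, cfg$p_threshold))
  if (nrow(sel$records) == 0) stop("no instruments at p < ", cfg$p_threshold)
  if (!is.null(cfg$ld)) {
    sel <- clump(sel, cfg$ld, cfg$r2_threshold, cfg$window_kb)
  }
  h <- harmonize(sel, outcome, cfg$outcome_p_exclude)
  list(est = ivw(h), h = h)
}

#' Default thresholds for screening runs
#'
#' @param p_threshold instrument significance threshold.
#' @param outcome_p_exclude outcome-significance exclusion threshold.
#' @param ld optional LD matrix used to clump instruments.
#' @param r2_threshold,window_kb clumping parameters.
#' @param alpha nominal significance level for screening calls.
#' @return a named list consumed by the screening functions.
#' @export
screen_config <- function(p_threshold = 5e-8, outcome_p_exclude = 5e-8,
                          ld = NULL, r2_threshold = 0.001, window_kb = 10000,
                          alpha = 0.05) {
  list(p_threshold = p_threshold, outcome_p_exclude = outcome_p_exclude,
       ld = ld, r2_threshold = r2_threshold, window_kb = window_kb,
       alpha = alpha)
}

# shared screening engine: one IVW per (instrument source, outcome) pair,
# then BH across the panel
.screen_panel <- function(pairs, cfg, beta_col) {
  rows <- lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    fit <- tryCatch(.uni_mr(p$exposure, p$outcome, cfg), error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(mediator = nm, beta = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
                 nsnp = 0L, failed = TRUE,
                 reason = conditionMessage(fit), stringsAsFactors = FALSE)
    } else {
      e <- fit$est
      data.frame(mediator = nm, beta = e$beta, se = e$se,
                 ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
                 nsnp = e$n_snps, failed = FALSE, reason = "",
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- NA_real_
  ok <- !tab$failed
  if (any(ok)) tab$p_adj[ok] <- bh_adjust(tab$pval[ok])
  tab$tier <- ifelse(tab$failed, "failed",
              ifelse(tab$pval < cfg$alpha & tab$p_adj < cfg$alpha, "significant",
              ifelse(tab$pval < cfg$alpha, "suggestive", "not_selected")))
  names(tab)[names(tab) == "beta"] <- beta_col
  rownames(tab) <- NULL
  tab
}

#' Step 1 of two-step mediation: exposure to mediators
#'
#' Runs the full univariable pipeline (instrument selection, optional
#' clumping, harmonization, IVW) from the exposure to each mediator in the
#' panel, then applies Benjamini-Hochberg adjustment across the panel.
#' Mediators are classed `significant` (p < alpha and adjusted p < alpha),
#' `suggestive` (p < alpha only), `not_selected`, or `failed` (e.g. zero
#' surviving instruments; recorded, never silently dropped).
#'
#' @param exposure `summary_stats` of the exposure GWAS.
#' @param mediators named list of `summary_stats`, one per mediator.
#' @param cfg a [screen_config()] list.
#' @return data.frame with columns `mediator, beta1, se, ci_low, ci_high,
#'   pval, p_adj, nsnp, tier, failed, reason`.
#' @export
screen_step1 <- function(exposure, mediators, cfg = screen_config()) {
  stopifnot(length(mediators) > 0)
  pairs <- lapply(mediators, function(m) list(exposure = exposure, outcome = m))
  .screen_panel(pairs, cfg, "beta1")
}

#' Step 2 of two-step mediation: mediators to outcome
#'
#' Same machinery as [screen_step1()], but instruments are selected from each
#' mediator's own GWAS and the outcome is fixed.
#'
#' @param mediators named list of `summary_stats`.
#' @param outcome `summary_stats` of the outcome GWAS.
#' @param cfg a [screen_config()] list.
#' @return data.frame as in [screen_step1()] with the effect column `beta2`.
#' @export
screen_step2 <- function(mediators, outcome, cfg = screen_config()) {
  stopifnot(length(mediators) > 0)
  pairs <- lapply(mediators, function(m) list(exposure = m, outcome = outcome))
  .screen_panel(pairs, cfg, "beta2")
}

#' Combine the two screening steps into mediation results
#'
#' Joins the step-1 and step-2 tables by mediator, computes the indirect
#' effect `beta1 * beta2` with its delta-method CI and the proportion of the
#' total effect mediated. A mediator enters the headline table only if it is
#' `significant` in both steps *and* its indirect effect has the same sign as
#' the total effect; everything else is retained in the full table with its
#' tier (`mediator`, `step2_fail`, `step1_fail`, `direction_inconsistent`,
#' or `failed`). Proportions are reported as-is and never renormalized to sum
#' to 100% across mediators.
#'
#' @param total an `mr_estimate` of the total exposure-to-outcome effect
#'   (univariable IVW), or a single beta on the same scale as
#'   `beta1 * beta2`.
#' @param step1 output of [screen_step1()].
#' @param step2 output of [screen_step2()].
#' @return list with `full` (all mediators, tiers and audit columns) and
#'   `headline` (the Table-1-shaped selection: `mediator, beta1, beta1_ci_low,
#'   beta1_ci_high, beta2, beta2_ci_low, beta2_ci_high, indirect,
#'   indirect_ci_low, indirect_ci_high, proportion_pct`).
#' @export
run_mediation <- function(total, step1, step2) {
  beta_total <- if (inherits(total, "mr_estimate")) total$beta else as.numeric(total)
  if (beta_total == 0) stop("run_mediation: total effect is zero")
  stopifnot(all(step1$mediator %in% step2$mediator) ||
            all(step2$mediator %in% step1$mediator))
  m2 <- step2[match(step1$mediator, step2$mediator), , drop = FALSE]

  ind <- Map(function(b1, s1, b2, s2) {
    if (any(is.na(c(b1, s1, b2, s2)))) {
      list(point = NA_real_, se = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    } else indirect_effect(b1, s1, b2, s2)
  }, step1$beta1, step1$se, m2$beta2, m2$se)

  full <- data.frame(
    mediator = step1$mediator,
    beta1 = step1$beta1, se1 = step1$se,
    beta1_ci_low = step1$ci_low, beta1_ci_high = step1$ci_high,
    pval1 = step1$pval, p_adj1 = step1$p_adj, tier1 = step1$tier,
    beta2 = m2$beta2, se2 = m2$se,
    beta2_ci_low = m2$ci_low, beta2_ci_high = m2$ci_high,
    pval2 = m2$pval, p_adj2 = m2$p_adj, tier2 = m2$tier,
    indirect = vapply(ind, `[[`, numeric(1), "point"),
    indirect_se = vapply(ind, `[[`, numeric(1), "se"),
    indirect_ci_low = vapply(ind, `[[`, numeric(1), "ci_low"),
    indirect_ci_high = vapply(ind, `[[`, numeric(1), "ci_high"),
    total = beta_total,
    stringsAsFactors = FALSE
  )
  full$proportion_pct <- ifelse(is.na(full$indirect), NA_real_,
                                100 * full$indirect / beta_total)
  full$direction_consistent <- !is.na(full$indirect) &
    sign(full$indirect) == sign(beta_total)
  full$tier <- ifelse(full$tier1 == "failed" | full$tier2 == "failed", "failed",
               ifelse(full$tier1 != "significant", "step1_fail",
               ifelse(full$tier2 != "significant", "step2_fail",
               ifelse(!full$direction_consistent, "direction_inconsistent",
                      "mediator"))))
  sel <- full$tier == "mediator"
  headline <- full[sel, c("mediator", "beta1", "beta1_ci_low", "beta1_ci_high",
                          "beta2", "beta2_ci_low", "beta2_ci_high",
                          "indirect", "indirect_ci_low", "indirect_ci_high",
                          "proportion_pct"), drop = FALSE]
  rownames(headline) <- NULL
  list(full = full, headline = headline)
}
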