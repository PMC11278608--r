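# Independent oracles, written from the definitions, never calling package
# internals. Used to cross-check the implementation on small inputs.

# weighted median: explicit scan over sorted ratios; breakpoints at
# cumulative weight minus half the step, linear interpolation by hand
oracle_weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  p <- numeric(length(x))
  acc <- 0
  for (i in seq_along(x)) {
    p[i] <- acc + w[i] / 2
    acc <- acc + w[i]
  }
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  for (i in seq_len(length(x) - 1)) {
    if (p[i] <= 0.5 && 0.5 <= p[i + 1]) {
      if (p[i + 1] == p[i]) return(x[i])
      return(x[i] + (x[i + 1] - x[i]) * (0.5 - p[i]) / (p[i + 1] - p[i]))
    }
  }
  stop("unreachable")
}

# IVW closed form: weighted least squares through the origin, plus
# multiplicative random-effects scale, written out directly
oracle_ivw <- function(bx, by, seY) {
  w <- 1 / seY^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  q <- sum(w * (by - beta * bx)^2)
  phi <- max(1, sqrt(q / (length(bx) - 1)))
  list(beta = beta, se = phi / sqrt(sum(w * bx^2)), Q = q)
}

# BH step-up by double loop over the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    adj[ord[i]] <- min(1, min(vals))
  }
  adj
}

# exhaustive clumping verifier: TRUE iff no retained pair within the window
# violates the threshold AND every dropped variant conflicts with a retained
# variant that precedes it in (pval, id) order
oracle_clump_valid <- function(records, kept_ids, ld, r2_threshold, window_kb) {
  conflict <- function(a, b) {
    records$chr[a] == records$chr[b] &&
      abs(records$pos[a] - records$pos[b]) <= window_kb * 1000 &&
      ld[records$variant_id[a], records$variant_id[b]] >= r2_threshold
  }
  kept <- which(records$variant_id %in% kept_ids)
  dropped <- setdiff(seq_len(nrow(records)), kept)
  for (a in kept) for (b in kept) {
    if (a < b && conflict(a, b)) return(FALSE)
  }
  better <- function(a, b) {        # a precedes b in greedy order
    records$pval[a] < records$pval[b] ||
      (records$pval[a] == records$pval[b] &&
         records$variant_id[a] < records$variant_id[b])
  }
  for (d in dropped) {
    if (!any(vapply(kept, function(k) better(k, d) && conflict(k, d), logical(1)))) {
      return(FALSE)
    }
  }
  TRUE
}

# small well-formed variant table
toy_records <- function(n = 3, seed = 42) {
  set.seed(seed)
  beta <- stats::rnorm(n, 0, 0.1)
  se <- stats::runif(n, 0.005, 0.02)
  data.frame(
    variant_id = sprintf("rs%03d", seq_len(n)),
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = stats::runif(n, 0.1, 0.5),
    beta = beta, se = se,
    # clamp away from 0: extreme z-scores underflow and (0,1] rows get dropped
    pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
    n = 1e5,
    chr = rep(1:2, length.out = n),
    pos = seq_len(n) * 1e6,
    stringsAsFactors = FALSE
  )
}

toy_stats <- function(n = 3, seed = 42, trait = "toy", type = "continuous") {
  summary_stats(toy_records(n, seed), trait, type, quiet = TRUE)
}

# harmonized set with known structure: by = beta * bx + noise
sim_hset <- function(j, beta, se_out = 0.015, se_exp = 0.004,
                     gamma_mean = 0.08, gamma_sd = 0.03, pleio = 0) {
  gamma <- stats::rnorm(j, gamma_mean, gamma_sd)
  bx <- gamma + stats::rnorm(j, 0, se_exp)
  by <- beta * gamma + pleio + stats::rnorm(j, 0, se_out)
  harmonized_set(bx, rep(se_exp, j), by, rep(se_out, j))
}

# spike-in world for the outlier-correction claim: a small panel whose first
# instrument is strong (gamma = 0.15), so the bias induced by a 10-SE
# pleiotropic offset on it dwarfs the IVW sampling noise and "corrected is
# closer to truth" is a property of the method, not of luck
sim_spike_hset <- function(beta, j = 10, se_out = 0.015, spike_mult = 10) {
  gamma <- c(0.15, stats::rnorm(j - 1, 0.08, 0.03))
  bx <- gamma + stats::rnorm(j, 0, 0.004)
  by <- beta * gamma + stats::rnorm(j, 0, se_out)
  by[1] <- by[1] + spike_mult * se_out
  harmonized_set(bx, rep(0.004, j), by, rep(se_out, j))
}
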