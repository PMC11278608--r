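test_that("wald_ratio is the outcome/exposure ratio with first-order SE", {
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.01)$beta, 0)
  w <- wald_ratio(1, 0.02, 0.05, 0.03)
  expect_equal(w$beta, 0.05)
  expect_equal(w$se, 0.03)
  w2 <- wald_ratio(0.1, 0.01, 0.02, 0.01)
  expect_equal(w2$beta, 0.2)
  expect_equal(w2$se, 0.1)
  expect_error(wald_ratio(0, 0.01, 0.02, 0.01), "undefined")
})

test_that("mr_estimate enforces the CI and OR invariants", {
  e <- mr_estimate("ivw", beta = 0.14, se = 0.026, n_snps = 10L)
  expect_equal(e$ci_low, 0.14 - 1.96 * 0.026)
  expect_equal(e$ci_high, 0.14 + 1.96 * 0.026)
  o <- to_odds_ratio(e)
  expect_equal(o$or, exp(e$beta))
  expect_equal(o$or_ci_low, exp(e$ci_low))
  expect_equal(o$or_ci_high, exp(e$ci_high))
  # null effect and reciprocal symmetry
  expect_equal(to_odds_ratio(mr_estimate("ivw", 0, 0.1, 2L))$or, 1)
  a <- to_odds_ratio(mr_estimate("ivw", 0.3, 0.05, 2L))
  b <- to_odds_ratio(mr_estimate("ivw", -0.3, 0.05, 2L))
  expect_equal(a$or, 1 / b$or)
})

test_that("ivw matches the closed-form weighted-least-squares oracle", {
  # two identical ratios: beta = c, Q = 0, phi = 1
  h <- harmonized_set(c(0.1, 0.2), c(0.01, 0.01), c(0.03, 0.06), c(0.01, 0.01))
  e <- ivw(h)
  expect_equal(e$beta, 0.3)
  expect_equal(e$Q, 0)
  expect_equal(e$phi, 1)

  # J = 3 worked example against the independent closed form
  bx <- c(0.1, 0.2, 0.15); by <- c(0.02, 0.05, 0.03); seY <- c(0.01, 0.01, 0.02)
  h3 <- harmonized_set(bx, rep(0.005, 3), by, seY)
  e3 <- ivw(h3)
  o <- oracle_ivw(bx, by, seY)
  expect_equal(e3$beta, o$beta, tolerance = 1e-14)
  expect_equal(e3$se, o$se, tolerance = 1e-14)
  expect_equal(e3$Q, o$Q, tolerance = 1e-14)

  expect_error(ivw(harmonized_set(0.1, 0.01, 0.02, 0.01)), ">= 2")

  # parameter recovery: true beta = 0.14, J = 50, strong instruments
  reps <- withr::with_seed(401, {
    vapply(1:50, function(i) ivw(sim_hset(50, 0.14))$beta, numeric(1))
  })
  mc_se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.14), 3 * mc_se + 1e-12)
})

test_that("ivw with equal outcome SEs reduces to OLS through the origin", {
  withr::with_seed(7, {
    bx <- rnorm(20, 0.1, 0.03)
    by <- 0.2 * bx + rnorm(20, 0, 0.01)
  })
  h <- harmonized_set(bx, rep(0.005, 20), by, rep(0.012, 20))
  expect_equal(ivw(h)$beta, sum(bx * by) / sum(bx^2), tolerance = 1e-13)
})

test_that("egger recovers an exact line and respects orientation", {
  bx <- seq(0.05, 0.2, length.out = 6)
  by <- 0.006 + 0.1 * bx
  h <- harmonized_set(bx, rep(0.004, 6), by, rep(0.01, 6))
  fit <- egger(h)
  expect_equal(fit$slope$beta, 0.1, tolerance = 1e-12)
  expect_equal(fit$intercept$beta, 0.006, tolerance = 1e-12)
  expect_equal(fit$slope$phi, 1)  # noiseless: inflation floored at 1

  # joint sign flip of (beta_exp, beta_out) leaves both coefficients unchanged
  h_neg <- harmonized_set(-bx, rep(0.004, 6), -by, rep(0.01, 6))
  fit_neg <- egger(h_neg)
  expect_equal(fit_neg$slope$beta, fit$slope$beta, tolerance = 1e-12)
  expect_equal(fit_neg$intercept$beta, fit$intercept$beta, tolerance = 1e-12)
  expect_equal(fit_neg$slope$se, fit$slope$se, tolerance = 1e-12)

  expect_error(egger(harmonized_set(bx[1:2], rep(0.004, 2), by[1:2], rep(0.01, 2))),
               ">= 3")
})

test_that("egger slope equals ivw on noiseless collinear data", {
  bx <- seq(0.05, 0.2, length.out = 5)
  by <- 0.12 * bx   # intercept exactly 0
  h <- harmonized_set(bx, rep(0.004, 5), by, rep(0.01, 5))
  expect_equal(egger(h)$slope$beta, ivw(h)$beta, tolerance = 1e-12)
  expect_equal(egger(h)$intercept$beta, 0, tolerance = 1e-14)
})

test_that("egger intercept recovers directional pleiotropy", {
  ints <- withr::with_seed(402, {
    vapply(1:200, function(i) {
      egger(sim_hset(60, 0.14, pleio = rnorm(60, 0.01, 0.005)))$intercept$beta
    }, numeric(1))
  })
  mc_se <- sd(ints) / sqrt(length(ints))
  expect_lt(abs(mean(ints) - 0.01), 3 * mc_se + 1e-12)
})

test_that("weighted_median matches equal-weight median and brute-force oracle", {
  # equal weights, ratios {1, 2, 9} -> ordinary median
  h <- harmonized_set(c(0.1, 0.1, 0.1), rep(0.004, 3),
                      c(0.1, 0.2, 0.9), rep(0.01, 3))
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$beta, 2)

  # all ratios equal c -> c with small bootstrap SE
  h2 <- harmonized_set(c(0.1, 0.2, 0.4), rep(1e-5, 3),
                       c(0.05, 0.10, 0.20), rep(1e-5, 3))
  wm2 <- weighted_median(h2, n_boot = 200, seed = 2)
  expect_equal(wm2$beta, 0.5)
  expect_lt(wm2$se, 0.01)

  # unequal weights vs independent cumulative-weight scan
  withr::with_seed(11, {
    for (i in 1:10) {
      j <- sample(5:12, 1)
      bx <- rnorm(j, 0.1, 0.04); bx[abs(bx) < 0.01] <- 0.05
      by <- rnorm(j, 0.02, 0.02)
      seY <- runif(j, 0.005, 0.03)
      h <- harmonized_set(bx, rep(0.004, j), by, seY)
      got <- weighted_median(h, n_boot = 2, seed = 3)$beta
      expect_equal(got, oracle_weighted_median(by / bx, bx^2 / seY^2),
                   tolerance = 1e-12)
    }
  })
  expect_error(weighted_median(harmonized_set(0.1, 0.01, 0.02, 0.01)), ">= 3")
})

test_that("weighted_median is permutation invariant and bounded by the ratios", {
  withr::with_seed(12, {
    bx <- runif(8, 0.05, 0.2); by <- rnorm(8, 0.02, 0.03); seY <- runif(8, 0.01, 0.03)
  })
  h <- harmonized_set(bx, rep(0.004, 8), by, seY)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  hp <- harmonized_set(bx[perm], rep(0.004, 8), by[perm], seY[perm])
  expect_equal(weighted_median(h, n_boot = 2, seed = 1)$beta,
               weighted_median(hp, n_boot = 2, seed = 1)$beta, tolerance = 1e-12)
  r <- by / bx
  expect_gte(weighted_median(h, n_boot = 2, seed = 1)$beta, min(r))
  expect_lte(weighted_median(h, n_boot = 2, seed = 1)$beta, max(r))
})

test_that("mode_estimate finds the dominant ratio cluster", {
  # simple mode: cluster majority at 0.1
  h <- harmonized_set(rep(0.1, 4), rep(0.004, 4),
                      c(0.01, 0.01, 0.01, 0.05), rep(0.01, 4))
  sm <- mode_estimate(h, weighted = FALSE, n_boot = 50, seed = 4)
  expect_lt(abs(sm$beta - 0.1), 0.05)

  # degenerate: all ratios identical
  h2 <- harmonized_set(c(0.1, 0.2, 0.4), rep(1e-6, 3),
                       c(0.03, 0.06, 0.12), rep(1e-6, 3))
  expect_equal(mode_estimate(h2, n_boot = 20, seed = 5)$beta, 0.3)

  # bimodal: majority count in lower cluster, inverse-variance weight upper
  bx <- c(0.1, 0.1, 0.1, 0.3, 0.3)
  by <- c(0.010, 0.011, 0.009, 0.150, 0.151)   # ratios ~0.1 and ~0.5
  seY <- c(0.02, 0.02, 0.02, 0.002, 0.002)     # upper cluster far more precise
  h3 <- harmonized_set(bx, rep(0.004, 5), by, seY)
  simple <- mode_estimate(h3, weighted = FALSE, n_boot = 2, seed = 6)$beta
  weighted <- mode_estimate(h3, weighted = TRUE, n_boot = 2, seed = 6)$beta
  expect_lt(abs(simple - 0.1), 0.1)
  expect_lt(abs(weighted - 0.5), 0.1)

  # verified by direct density evaluation at the two cluster centres
  r <- by / bx
  w_inv <- bx^2 / seY^2; w_inv <- w_inv / sum(w_inv)
  bw <- 1.06 * min(sd(r), IQR(r) / 1.34) * length(r)^(-0.2)
  dens <- function(g, w) sum(w * dnorm((g - r) / bw))
  expect_gt(dens(0.1, rep(0.2, 5)), dens(0.5, rep(0.2, 5)))
  expect_gt(dens(0.5, w_inv), dens(0.1, w_inv))
})

test_that("all estimators are equivariant under joint sign flip", {
  withr::with_seed(13, {
    bx <- runif(10, 0.05, 0.2); by <- 0.15 * bx + rnorm(10, 0, 0.01)
  })
  h <- harmonized_set(bx, rep(0.004, 10), by, rep(0.012, 10))
  hf <- harmonized_set(-bx, rep(0.004, 10), -by, rep(0.012, 10))
  expect_equal(ivw(hf)$beta, ivw(h)$beta, tolerance = 1e-12)
  expect_equal(egger(hf)$slope$beta, egger(h)$slope$beta, tolerance = 1e-12)
  expect_equal(weighted_median(hf, n_boot = 2, seed = 1)$beta,
               weighted_median(h, n_boot = 2, seed = 1)$beta, tolerance = 1e-12)
  expect_equal(mode_estimate(hf, n_boot = 2, seed = 1)$beta,
               mode_estimate(h, n_boot = 2, seed = 1)$beta, tolerance = 1e-6)
})

test_that("mr_all_methods returns the tidy five-method table", {
  h <- withr::with_seed(14, sim_hset(30, 0.14))
  tab <- mr_all_methods(h, n_boot = 100, seed = 2)
  expect_equal(tab$method,
               c("ivw", "egger_slope", "weighted_median", "simple_mode",
                 "weighted_mode"))
  expect_true(all(c("or", "or_ci_low", "or_ci_high") %in% names(tab)))
  expect_equal(tab$or, exp(tab$beta))
  # reproducible under the same seed
  tab2 <- mr_all_methods(h, n_boot = 100, seed = 2)
  expect_identical(tab, tab2)
})
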