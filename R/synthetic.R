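#' Scenario specification for the synthetic GWAS generator
#'
#' Encodes the structural model behind a two-stage MR study: instruments act
#' on the exposure with effects `gamma_j`, the exposure carries a total effect
#' `beta_total` onto the outcome, and each mediator sits on an
#' exposure -> mediator -> outcome path with effects `a` (exposure to
#' mediator) and `b` (mediator to outcome), contributing `a * b` of the total.
#' Each mediator also has its own independent instruments so the
#' mediator-to-outcome leg is estimable.
#'
#' Defaults emulate the scale of the seed study: a binary exposure GWAS of
#' ~660k with ~9.5% cases (a large type-2-diabetes meta-analysis), a binary
#' outcome GWAS of ~392k with ~2.3% cases (a biobank valve-stenosis
#' endpoint), continuous mediator GWAS of ~115k (an NMR metabolomics panel),
#' around 120 genome-wide-significant post-clumping instruments with
#' per-allele effects of mean 0.08 SD/log-odds, and a total effect of
#' `log(1.153)`.
#'
#' @param seed RNG seed; the generator is deterministic given the spec.
#' @param n_exposure,n_outcome,n_mediator_gwas GWAS sample sizes.
#' @param j_instruments instruments per trait (exposure, and each mediator).
#' @param j_outcome_instruments instruments acting directly on the outcome,
#'   so reverse-direction MR is estimable (default: `j_instruments`).
#' @param beta_reverse true outcome-to-exposure effect carried by the outcome
#'   instruments (default 0: no reverse causation).
#' @param j_null additional null variants (no effect anywhere), to exercise
#'   instrument selection.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param gamma_mean,gamma_sd distribution of true instrument effects.
#' @param beta_total true total exposure-to-outcome effect (log-odds).
#' @param mediators data.frame with columns `name`, `a`, `b` (may be empty).
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_mean,pleiotropy_sd pleiotropic effect distribution
#'   (mean only used in directional mode).
#' @param ld_block_size,ld_block_r2 optional LD structure: each exposure
#'   instrument is replicated into a block of `ld_block_size` correlated
#'   proxies with pairwise r-squared `ld_block_r2`; `ld_block_size = 1`
#'   disables blocks.
#' @param case_fraction_exposure,case_fraction_outcome case fractions of the
#'   binary traits.
#' @param exposure_binary treat the exposure as binary (log-odds betas).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(seed = 1,
                          n_exposure = 659316, n_outcome = 392149,
                          n_mediator_gwas = 115078,
                          j_instruments = 120,
                          j_outcome_instruments = j_instruments,
                          beta_reverse = 0, j_null = 100,
                          maf_range = c(0.05, 0.5),
                          gamma_mean = 0.08, gamma_sd = 0.03,
                          beta_total = log(1.153),
                          mediators = data.frame(name = character(),
                                                 a = numeric(), b = numeric()),
                          pleiotropy = c("none", "balanced", "directional"),
                          pleiotropy_mean = 0.01, pleiotropy_sd = 0.01,
                          ld_block_size = 1, ld_block_r2 = 0.8,
                          case_fraction_exposure = 0.0954,
                          case_fraction_outcome = 0.0233,
                          exposure_binary = TRUE) {
  pleiotropy <- match.arg(pleiotropy)
  spec <- list(seed = seed, n_exposure = n_exposure, n_outcome = n_outcome,
               n_mediator_gwas = n_mediator_gwas,
               j_instruments = j_instruments,
               j_outcome_instruments = j_outcome_instruments,
               beta_reverse = beta_reverse, j_null = j_null,
               maf_range = maf_range, gamma_mean = gamma_mean,
               gamma_sd = gamma_sd, beta_total = beta_total,
               mediators = mediators, pleiotropy = pleiotropy,
               pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
               ld_block_size = ld_block_size, ld_block_r2 = ld_block_r2,
               case_fraction_exposure = case_fraction_exposure,
               case_fraction_outcome = case_fraction_outcome,
               exposure_binary = exposure_binary)
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
        maf_range[1] <= maf_range[2], "maf_range must lie within (0, 0.5]")
  chk(all(c("name", "a", "b") %in% names(mediators)),
      "mediators needs columns name, a, b")
  chk(j_instruments >= 2, "j_instruments must be >= 2")
  chk(j_outcome_instruments >= 0, "j_outcome_instruments must be >= 0")
  chk(j_null >= 0, "j_null must be >= 0")
  chk(all(is.finite(c(beta_total, beta_reverse, mediators$a, mediators$b))),
      "effects must be finite")
  chk(ld_block_size >= 1 && ld_block_r2 >= 0 && ld_block_r2 < 1,
      "ld_block_size >= 1 and ld_block_r2 in [0, 1)")
  chk(case_fraction_exposure > 0 && case_fraction_exposure < 1 &&
        case_fraction_outcome > 0 && case_fraction_outcome < 1,
      "case fractions must be in (0, 1)")
  chk(all(c(n_exposure, n_outcome, n_mediator_gwas) >= 10),
      "sample sizes must be >= 10")
  if (length(problems) > 0) {
    stop("scenario_spec: invalid specification:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(spec, class = "scenario_spec")
}

# sampling standard error of a per-allele beta at allele frequency `maf`
# in a GWAS of size `n`; binary traits scale by case-fraction variance
.beta_se <- function(maf, n, case_fraction = NULL) {
  denom <- 2 * maf * (1 - maf) * n
  if (!is.null(case_fraction)) denom <- denom * case_fraction * (1 - case_fraction)
  1 / sqrt(denom)
}

# non-palindromic allele pairs; draw one per variant
.allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2, byrow = TRUE)

.make_stats <- function(ids, alleles, eaf, chr, pos, truth, se, n, trait, type) {
  obs <- truth + stats::rnorm(length(truth), 0, se)
  # p-values floored at the smallest positive double: underflow to exactly 0
  # would make rows fail the (0, 1] invariant and silently vanish
  summary_stats(data.frame(
    variant_id = ids, effect_allele = alleles[, 1], other_allele = alleles[, 2],
    eaf = eaf, beta = obs, se = se,
    pval = pmax(2 * stats::pnorm(-abs(obs / se)), .Machine$double.xmin),
    n = n, chr = chr, pos = pos,
    stringsAsFactors = FALSE
  ), trait_name = trait, trait_type = type, quiet = TRUE)
}

#' Simulate a full two-stage GWAS scenario
#'
#' Draws MAFs and true instrument effects from the spec, propagates them
#' through the structural model (mediator associations `a * gamma_j` plus the
#' mediator's own instruments; outcome associations `beta_total * gamma_j`
#' plus each mediator instrument's `b * delta_k` plus any pleiotropy term,
#' which acts on the outcome only), and adds sampling noise with standard
#' error `1 / sqrt(2 * maf * (1-maf) * n)` for continuous traits and
#' `1 / sqrt(2 * maf * (1-maf) * n * v * (1-v))` for binary traits with case
#' fraction `v`. All traits report every variant (exposure instruments,
#' mediator instruments, LD proxies and nulls), so harmonization never drops
#' variants for absence unless the caller subsets.
#'
#' With `ld_block_size > 1`, every exposure instrument heads a block of
#' proxies at nearby positions whose true effects are attenuated by
#' `sqrt(r2)` and which share r-squared `ld_block_r2` in the emitted LD
#' matrix, so greedy clumping should retain about one variant per block.
#'
#' @param spec a [scenario_spec()].
#' @return list with `exposure`, `outcome` (`summary_stats`), `mediators`
#'   (named list of `summary_stats`), `ld` (r-squared matrix over all
#'   variants) and `truth` (list: `gamma`, `maf`, per-mediator `delta`,
#'   `pleiotropy`, plus the spec).
#' @export
simulate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(spec$seed, {
    jx <- spec$j_instruments
    bs <- spec$ld_block_size
    meds <- spec$mediators
    n_med <- nrow(meds)
    jm <- if (n_med > 0) spec$j_instruments else 0
    jo <- spec$j_outcome_instruments

    n_core <- jx * bs + n_med * jm + jo + spec$j_null
    maf <- stats::runif(n_core, spec$maf_range[1], spec$maf_range[2])
    alleles <- .allele_pairs[sample.int(nrow(.allele_pairs), n_core, replace = TRUE), ,
                             drop = FALSE]
    ids <- sprintf("rs%06d", seq_len(n_core))

    # positions: one block per exposure instrument, blocks/nulls spaced far
    # beyond any clumping window (25 Mb), proxies 1 kb apart within a block
    chr <- integer(n_core)
    pos <- numeric(n_core)
    block_of <- rep(seq_len(jx), each = bs)
    idx_exp <- seq_len(jx * bs)
    chr[idx_exp] <- ((block_of - 1) %% 22) + 1
    pos[idx_exp] <- ((block_of - 1) %/% 22 + 1) * 25e6 +
      (seq_along(idx_exp) - (block_of - 1) * bs - 1) * 1000
    rest <- setdiff(seq_len(n_core), idx_exp)
    chr[rest] <- ((seq_along(rest) - 1) %% 22) + 1
    pos[rest] <- 1e9 + ((seq_along(rest) - 1) %/% 22 + 1) * 25e6

    # true effects
    gamma_lead <- stats::rnorm(jx, spec$gamma_mean, spec$gamma_sd)
    gamma <- numeric(n_core)
    gamma[idx_exp] <- gamma_lead[block_of] *
      ifelse(seq_along(idx_exp) %% bs == 1 | bs == 1, 1, sqrt(spec$ld_block_r2))

    # outcome's own instruments feed back on the exposure via beta_reverse
    eta_vec <- numeric(n_core)
    if (jo > 0) {
      idx_out <- jx * bs + n_med * jm + seq_len(jo)
      eta_vec[idx_out] <- stats::rnorm(jo, spec$gamma_mean, spec$gamma_sd)
      gamma <- gamma + spec$beta_reverse * eta_vec
    }

    delta <- vector("list", n_med)   # each mediator's own instruments
    med_truth <- matrix(0, n_core, max(n_med, 1))
    if (n_med > 0) {
      for (k in seq_len(n_med)) {
        idx_k <- jx * bs + (k - 1) * jm + seq_len(jm)
        delta[[k]] <- stats::rnorm(jm, spec$gamma_mean, spec$gamma_sd)
        med_truth[, k] <- meds$a[k] * gamma
        med_truth[idx_k, k] <- med_truth[idx_k, k] + delta[[k]]
      }
      names(delta) <- meds$name
    }

    pleio <- numeric(n_core)
    if (spec$pleiotropy == "balanced") {
      pleio[idx_exp] <- stats::rnorm(length(idx_exp), 0, spec$pleiotropy_sd)
    } else if (spec$pleiotropy == "directional") {
      pleio[idx_exp] <- stats::rnorm(length(idx_exp), spec$pleiotropy_mean,
                                     spec$pleiotropy_sd)
    }

    out_truth <- spec$beta_total * gamma + pleio + eta_vec
    if (n_med > 0) {
      for (k in seq_len(n_med)) {
        idx_k <- jx * bs + (k - 1) * jm + seq_len(jm)
        out_truth[idx_k] <- out_truth[idx_k] + meds$b[k] * delta[[k]]
      }
    }

    se_exp <- .beta_se(maf, spec$n_exposure,
                       if (spec$exposure_binary) spec$case_fraction_exposure else NULL)
    se_out <- .beta_se(maf, spec$n_outcome, spec$case_fraction_outcome)
    se_med <- .beta_se(maf, spec$n_mediator_gwas)

    exposure <- .make_stats(ids, alleles, maf, chr, pos, gamma, se_exp,
                            spec$n_exposure, "exposure",
                            if (spec$exposure_binary) "binary" else "continuous")
    outcome <- .make_stats(ids, alleles, maf, chr, pos, out_truth, se_out,
                           spec$n_outcome, "outcome", "binary")
    mediators <- list()
    if (n_med > 0) {
      for (k in seq_len(n_med)) {
        mediators[[meds$name[k]]] <- .make_stats(
          ids, alleles, maf, chr, pos, med_truth[, k], se_med,
          spec$n_mediator_gwas, meds$name[k], "continuous")
      }
    }

    # LD: identity plus within-block off-diagonals
    ld <- diag(n_core)
    dimnames(ld) <- list(ids, ids)
    if (bs > 1) {
      for (b in seq_len(jx)) {
        idx_b <- (b - 1) * bs + seq_len(bs)
        ld[idx_b, idx_b] <- spec$ld_block_r2
        diag(ld)[idx_b] <- 1
      }
    }

    list(exposure = exposure, outcome = outcome, mediators = mediators,
         ld = ld,
         truth = list(gamma = stats::setNames(gamma, ids), maf = maf,
                      delta = delta, eta = stats::setNames(eta_vec, ids),
                      pleiotropy = pleio, spec = spec))
  })
}
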