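#' Run configuration
#'
#' Collects file paths, column dialects and thresholds for a full two-stage
#' run. Configs are stored as JSON; [read_run_config()] validates that every
#' referenced path exists.
#'
#' @param exposure,outcome paths to summary-stats TSVs.
#' @param mediators named character vector of mediator TSV paths (may be
#'   empty).
#' @param covariates named character vector of secondary-exposure TSV paths
#'   for the multivariable adjustment (may be empty).
#' @param ld optional path to an LD matrix TSV.
#' @param exposure_type,outcome_type trait types.
#' @param dialect optional named character vector remapping foreign column
#'   headers (applied to every input).
#' @param p_threshold,r2_threshold,window_kb,outcome_p_exclude thresholds.
#' @param n_boot,presso_n_sim bootstrap and MR-PRESSO simulation counts.
#' @param seed master seed for every stochastic component (mandatory).
#' @param out_dir output directory for report tables.
#' @return A `run_config` list.
#' @export
run_config <- function(exposure, outcome, mediators = character(),
                       covariates = character(), ld = NULL,
                       exposure_type = "binary", outcome_type = "binary",
                       dialect = NULL,
                       p_threshold = 5e-8, r2_threshold = 0.001,
                       window_kb = 10000, outcome_p_exclude = 5e-8,
                       n_boot = 1000, presso_n_sim = 1000,
                       seed = 1, out_dir = ".") {
  # normalize path collections to named character vectors (JSON round trip
  # may deliver named lists)
  mediators <- if (length(mediators) == 0) character() else unlist(mediators)
  covariates <- if (length(covariates) == 0) character() else unlist(covariates)
  structure(list(exposure = exposure, outcome = outcome,
                 mediators = mediators, covariates = covariates, ld = ld,
                 exposure_type = exposure_type, outcome_type = outcome_type,
                 dialect = dialect,
                 p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb, outcome_p_exclude = outcome_p_exclude,
                 n_boot = n_boot, presso_n_sim = presso_n_sim,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file holding the fields of [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
  for (p in c(cfg$exposure, cfg$outcome, cfg$mediators, cfg$covariates, cfg$ld)) {
    if (!is.null(p) && !file.exists(p)) stop("read_run_config: missing input: ", p)
  }
  cfg
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  # keep names through auto_unbox by serializing path maps as objects
  x$mediators <- as.list(cfg$mediators)
  x$covariates <- as.list(cfg$covariates)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.load_inputs <- function(cfg) {
  ld <- if (!is.null(cfg$ld)) read_ld_matrix(cfg$ld) else NULL
  meds <- lapply(cfg$mediators, function(p)
    read_summary_stats(p, dialect = cfg$dialect, quiet = TRUE))
  covs <- lapply(cfg$covariates, function(p)
    read_summary_stats(p, dialect = cfg$dialect, trait_type = "continuous",
                       quiet = TRUE))
  list(
    exposure = read_summary_stats(cfg$exposure, trait_type = cfg$exposure_type,
                                  dialect = cfg$dialect, quiet = TRUE),
    outcome = read_summary_stats(cfg$outcome, trait_type = cfg$outcome_type,
                                 dialect = cfg$dialect, quiet = TRUE),
    mediators = meds, covariates = covs, ld = ld
  )
}

.write_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# one direction of univariable MR: all estimators + sensitivity battery
.analyse_direction <- function(exposure, outcome, cfg, ld, label, log) {
  res <- tryCatch({
    sel <- suppressWarnings(select_instruments(exposure, cfg$p_threshold))
    log(sprintf("[%s] %d/%d variants pass p < %g", label,
                n_variants(sel), n_variants(exposure), cfg$p_threshold))
    if (n_variants(sel) == 0) stop("no instruments")
    if (!is.null(ld)) {
      sel <- clump(sel, ld, cfg$r2_threshold, cfg$window_kb)
      log(sprintf("[%s] %d variants after clumping", label, n_variants(sel)))
    }
    h <- harmonize(sel, outcome, cfg$outcome_p_exclude)
    log(sprintf("[%s] harmonized %d variants (dropped: %s)", label,
                nrow(h$variants),
                paste(sprintf("%s=%d", names(h$audit), h$audit), collapse = ", ")))
    est <- mr_all_methods(h, n_boot = cfg$n_boot, seed = cfg$seed,
                          or_scale = outcome$trait_type == "binary")
    sens <- sensitivity_battery(h, n_sim = cfg$presso_n_sim, seed = cfg$seed)
    list(harmonized = h, estimates = est, sensitivity = sens, error = NULL)
  }, error = function(e) {
    log(sprintf("[%s] FAILED: %s", label, conditionMessage(e)))
    list(harmonized = NULL, estimates = NULL, sensitivity = NULL,
         error = conditionMessage(e))
  })
  res
}

#' Stage 1: bidirectional univariable MR plus multivariable adjustment
#'
#' Forward MR (exposure to outcome, all five estimators with odds-ratio
#' columns for binary outcomes), reverse MR (outcome as exposure, same
#' thresholds), the sensitivity battery on each direction, and — when
#' covariate exposures are configured — multivariable IVW adjusting the
#' primary exposure for each covariate separately. Per-analysis errors are
#' recorded in the bundle without aborting the rest. All tables are written
#' under `cfg$out_dir` and every filter count is logged.
#'
#' @param cfg a `run_config` (or path to one).
#' @return A report bundle (list): `forward`, `reverse`, `mvmr`, `log`,
#'   `files`.
#' @export
run_stage1 <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logs <- character(0)
  log <- function(msg) logs <<- c(logs, msg)
  inp <- .load_inputs(cfg)

  forward <- .analyse_direction(inp$exposure, inp$outcome, cfg, inp$ld,
                                "forward", log)
  reverse <- .analyse_direction(inp$outcome, inp$exposure, cfg, inp$ld,
                                "reverse", log)

  mvmr_out <- NULL
  if (length(inp$covariates) > 0) {
    mvmr_out <- lapply(names(inp$covariates), function(cv) {
      tryCatch({
        m <- build_mvmr_set(
          stats::setNames(list(inp$exposure, inp$covariates[[cv]]),
                          c(inp$exposure$trait_name, cv)),
          inp$outcome, p_threshold = cfg$p_threshold, ld = inp$ld,
          outcome_p_exclude = cfg$outcome_p_exclude,
          r2_threshold = cfg$r2_threshold, window_kb = cfg$window_kb)
        ests <- mvmr_ivw(m)
        log(sprintf("[mvmr:%s] %d variants (dropped: %s)", cv,
                    nrow(m$variants),
                    paste(sprintf("%s=%d", names(m$audit), m$audit), collapse = ", ")))
        tab <- do.call(rbind, lapply(ests, function(e) {
          d <- as.data.frame(to_odds_ratio(e))
          d$exposure <- e$exposure
          d
        }))
        tab$adjusted_for <- cv
        tab
      }, error = function(e) {
        log(sprintf("[mvmr:%s] FAILED: %s", cv, conditionMessage(e)))
        NULL
      })
    })
    mvmr_out <- do.call(rbind, mvmr_out)
  }

  files <- character(0)
  if (!is.null(forward$estimates)) {
    files <- c(files, .write_tsv(forward$estimates, cfg$out_dir, "stage1_forward.tsv"))
    if (!is.null(forward$sensitivity$loo)) {
      files <- c(files, .write_tsv(forward$sensitivity$loo, cfg$out_dir,
                                   "stage1_forward_loo.tsv"))
    }
  }
  if (!is.null(reverse$estimates)) {
    files <- c(files, .write_tsv(reverse$estimates, cfg$out_dir, "stage1_reverse.tsv"))
  }
  if (!is.null(mvmr_out)) {
    files <- c(files, .write_tsv(mvmr_out, cfg$out_dir, "stage1_mvmr.tsv"))
  }
  writeLines(logs, file.path(cfg$out_dir, "stage1_log.txt"))
  list(forward = forward, reverse = reverse, mvmr = mvmr_out,
       log = logs, files = files)
}

#' Stage 2: two-step mediation over the mediator panel
#'
#' Runs [screen_step1()] (exposure to every mediator), [screen_step2()]
#' (every mediator to the outcome) and [run_mediation()] against the stage-1
#' total effect, writing the headline (Table-1-shaped) TSV and the full
#' per-mediator table with tiers and audit columns.
#'
#' @param cfg a `run_config` (or path to one).
#' @param total optional `mr_estimate` of the total effect; when `NULL` the
#'   forward univariable IVW is recomputed from the configured inputs.
#' @return list: `total`, `step1`, `step2`, `mediation` (full + headline),
#'   `log`, `files`.
#' @export
run_stage2 <- function(cfg, total = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logs <- character(0)
  log <- function(msg) logs <<- c(logs, msg)
  inp <- .load_inputs(cfg)
  if (length(inp$mediators) == 0) {
    warning("run_stage2: empty mediator panel; nothing to do")
    empty <- data.frame()
    return(list(total = total, step1 = empty, step2 = empty,
                mediation = list(full = empty, headline = empty),
                log = "empty mediator panel", files = character(0)))
  }
  scr <- screen_config(p_threshold = cfg$p_threshold,
                       outcome_p_exclude = cfg$outcome_p_exclude,
                       ld = inp$ld, r2_threshold = cfg$r2_threshold,
                       window_kb = cfg$window_kb)
  if (is.null(total)) {
    total <- .uni_mr(inp$exposure, inp$outcome, scr)$est
    log(sprintf("[total] IVW beta = %.4g (se %.4g) on %d SNPs",
                total$beta, total$se, total$n_snps))
  }
  step1 <- screen_step1(inp$exposure, inp$mediators, scr)
  log(sprintf("[step1] %d significant, %d suggestive, %d failed of %d",
              sum(step1$tier == "significant"), sum(step1$tier == "suggestive"),
              sum(step1$tier == "failed"), nrow(step1)))
  step2 <- screen_step2(inp$mediators, inp$outcome, scr)
  log(sprintf("[step2] %d significant, %d suggestive, %d failed of %d",
              sum(step2$tier == "significant"), sum(step2$tier == "suggestive"),
              sum(step2$tier == "failed"), nrow(step2)))
  med <- run_mediation(total, step1, step2)
  log(sprintf("[mediation] %d headline mediator(s)", nrow(med$headline)))

  files <- c(.write_tsv(step1, cfg$out_dir, "stage2_step1.tsv"),
             .write_tsv(step2, cfg$out_dir, "stage2_step2.tsv"),
             .write_tsv(med$full, cfg$out_dir, "stage2_full.tsv"),
             .write_tsv(med$headline, cfg$out_dir, "stage2_headline.tsv"))
  writeLines(logs, file.path(cfg$out_dir, "stage2_log.txt"))
  list(total = total, step1 = step1, step2 = step2, mediation = med,
       log = logs, files = files)
}

#' Write a simulated scenario to disk in the native TSV dialect
#'
#' Convenience wrapper used by the CLI `simulate` subcommand and by tests:
#' simulates a scenario and writes `exposure.tsv`, `outcome.tsv`, one TSV per
#' mediator, and `ld.tsv` under `out_dir`, returning a matching `run_config`.
#'
#' @param spec a [scenario_spec()].
#' @param out_dir output directory.
#' @return A `run_config` pointing at the written files.
#' @export
write_scenario <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- simulate_scenario(spec)
  ep <- file.path(out_dir, "exposure.tsv")
  op <- file.path(out_dir, "outcome.tsv")
  write_summary_stats(sc$exposure, ep)
  write_summary_stats(sc$outcome, op)
  mp <- vapply(names(sc$mediators), function(nm) {
    p <- file.path(out_dir, paste0("mediator_", nm, ".tsv"))
    write_summary_stats(sc$mediators[[nm]], p)
    p
  }, character(1))
  lp <- file.path(out_dir, "ld.tsv")
  write_ld_matrix(sc$ld, lp)
  run_config(exposure = ep, outcome = op, mediators = mp, ld = lp,
             exposure_type = sc$exposure$trait_type,
             outcome_type = "binary", seed = spec$seed,
             out_dir = file.path(out_dir, "reports"))
}
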