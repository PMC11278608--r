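test_that("read_summary_stats parses, validates and drops bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rec <- toy_records(3)
  write_summary_stats(summary_stats(rec, "toy", quiet = TRUE), path)
  ss <- read_summary_stats(path, trait_name = "toy", quiet = TRUE)
  expect_s3_class(ss, "summary_stats")
  expect_equal(n_variants(ss), 3)
  expect_equal(ss$records$variant_id, rec$variant_id)

  # se = 0 row dropped, with a message carrying the count
  bad <- rec
  bad$se[2] <- 0
  expect_message(ss2 <- summary_stats(bad, "toy"), "dropped 1")
  expect_equal(n_variants(ss2), 2)
  expect_false("rs002" %in% ss2$records$variant_id)

  # alleles upper-cased; duplicate ids dropped
  dup <- rbind(rec, rec[1, ])
  dup$effect_allele <- tolower(dup$effect_allele)
  ss3 <- summary_stats(dup, "toy", quiet = TRUE)
  expect_equal(n_variants(ss3), 3)
  expect_true(all(ss3$records$effect_allele %in% c("A", "C", "G", "T")))

  # errors: missing mandatory column (se), empty file, bad dialect
  expect_error(summary_stats(rec[, names(rec) != "se"], "toy"), "mandatory")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("SNP\teffect_allele\tother_allele\tbeta\tse\tpval", empty)
  expect_error(read_summary_stats(empty), "empty")
  expect_error(read_summary_stats(path, dialect = c(beta = "nope")), "nope")
})

test_that("TSV round trip is identity on all fields", {
  set.seed(9)
  for (rep in 1:3) {
    rec <- toy_records(25, seed = rep)
    rec$eaf[3] <- NA  # missing eaf encoded as NA
    ss <- summary_stats(rec, "trip", quiet = TRUE)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_summary_stats(ss, path)
    back <- read_summary_stats(path, trait_name = "trip", quiet = TRUE)
    expect_equal(back$records, ss$records, tolerance = 1e-15)
  }
})

test_that("dialect remaps foreign headers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rec <- toy_records(3)
  foreign <- data.frame(rsid = rec$variant_id, A1 = rec$effect_allele,
                        A2 = rec$other_allele, freq = rec$eaf, Effect = rec$beta,
                        StdErr = rec$se, P = rec$pval, N = rec$n)
  utils::write.table(foreign, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- read_summary_stats(path, trait_name = "f", quiet = TRUE,
                           dialect = c(SNP = "rsid", effect_allele = "A1",
                                       other_allele = "A2", eaf = "freq",
                                       beta = "Effect", se = "StdErr",
                                       pval = "P", n = "N"))
  expect_equal(ss$records$beta, rec$beta)
  expect_equal(ss$records$variant_id, rec$variant_id)
})

test_that("select_instruments filters exactly on the threshold", {
  rec <- toy_records(3)
  rec$pval <- c(1e-9, 1e-7, 1e-10)
  ss <- summary_stats(rec, "sel", quiet = TRUE)
  expect_equal(n_variants(select_instruments(ss, 5e-8)), 2)
  expect_equal(n_variants(select_instruments(ss, 1.0)), 3)
  rec$pval <- rep(0.5, 3)
  expect_warning(out <- select_instruments(summary_stats(rec, "s", quiet = TRUE), 5e-8),
                 "no variant")
  expect_equal(n_variants(out), 0)

  # brute-force filter oracle on a generated table with true instruments
  spec <- scenario_spec(seed = 21, j_instruments = 40, j_null = 60,
                        j_outcome_instruments = 0, n_exposure = 2e5,
                        exposure_binary = FALSE)
  sc <- simulate_scenario(spec)
  got <- select_instruments(sc$exposure, 5e-8)$records$variant_id
  want <- sc$exposure$records$variant_id[sc$exposure$records$pval < 5e-8]
  expect_identical(got, want)
})

test_that("clump implements greedy p-value-ordered LD pruning", {
  # dominant pair: r2 = 0.9, 1 kb apart, better p wins
  rec <- toy_records(2)
  rec$chr <- c(1, 1); rec$pos <- c(1e6, 1e6 + 1000)
  rec$pval <- c(1e-12, 1e-9)
  ld <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(rec$variant_id, rec$variant_id))
  ss <- summary_stats(rec, "c", quiet = TRUE)
  out <- clump(ss, ld)
  expect_equal(out$records$variant_id, "rs001")

  # diagonal-only LD keeps everything
  rec <- toy_records(5)
  ld <- diag(5); dimnames(ld) <- list(rec$variant_id, rec$variant_id)
  ss <- summary_stats(rec, "c", quiet = TRUE)
  expect_equal(n_variants(clump(ss, ld)), 5)

  # variant absent from LD matrix is a hard error
  expect_error(clump(ss, ld[-1, -1]), "absent from LD")
})

test_that("clump agrees with the exhaustive verification oracle", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 20
    rec <- toy_records(n, seed = 100 + rep)
    rec$chr <- sample(1:2, n, replace = TRUE)
    rec$pos <- sample.int(3e7, n)
    # block-structured LD: 4 blocks of 5
    ld <- diag(n)
    for (b in 0:3) {
      idx <- b * 5 + 1:5
      ld[idx, idx] <- 0.5
    }
    diag(ld) <- 1
    dimnames(ld) <- list(rec$variant_id, rec$variant_id)
    ss <- summary_stats(rec, "c", quiet = TRUE)
    kept <- clump(ss, ld, r2_threshold = 0.1, window_kb = 5000)$records$variant_id
    expect_true(oracle_clump_valid(rec, kept, ld, 0.1, 5000))

    # invariance to input row order, output in input order
    perm <- sample.int(n)
    ss_perm <- summary_stats(rec[perm, ], "c", quiet = TRUE)
    kept_perm <- clump(ss_perm, ld, 0.1, 5000)$records$variant_id
    expect_setequal(kept_perm, kept)
    expect_identical(kept_perm,
                     rec$variant_id[perm][rec$variant_id[perm] %in% kept])
  }
})

test_that("f_statistics follows the published formula", {
  # null case: all betas zero
  rec <- toy_records(4)
  rec$beta <- 0
  expect_equal(f_statistics(summary_stats(rec, "f", quiet = TRUE), 1000)$f_stat, 0)

  # R2 = 0.05, N = 1000, K = 10: ten variants each explaining 0.005
  rec <- toy_records(10)
  rec$eaf <- 0.5; rec$beta <- 0.1   # 2 * 0.25 * 0.01 = 0.005 each
  fs <- f_statistics(summary_stats(rec, "f", quiet = TRUE), 1000)
  expect_equal(fs$r2_total, 0.05)
  expect_equal(fs$f_stat, 0.05 * 989 / (10 * 0.95), tolerance = 1e-12)
  expect_true(fs$weak)
  expect_equal(sum(fs$per_variant_r2), fs$r2_total)

  # K = 1 strong instrument
  rec1 <- toy_records(1)
  rec1$eaf <- 0.5; rec1$beta <- 0.1
  fs1 <- f_statistics(summary_stats(rec1, "f", quiet = TRUE), 1e4)
  expect_equal(fs1$f_stat, 0.005 * 9998 / (1 * 0.995), tolerance = 1e-12)
  expect_false(fs1$weak)

  # errors: missing eaf names the variant; n too small
  rec$eaf[2] <- NA
  expect_error(f_statistics(summary_stats(rec, "f", quiet = TRUE), 1000), "rs002")
  expect_error(f_statistics(summary_stats(rec1, "f", quiet = TRUE), 2), "n > k")
})

test_that("f_statistics is monotone in R2 and N", {
  mk <- function(beta, n) {
    rec <- toy_records(5)
    rec$eaf <- 0.3; rec$beta <- beta
    f_statistics(summary_stats(rec, "f", quiet = TRUE), n)$f_stat
  }
  betas <- seq(0.02, 0.2, length.out = 8)
  f_by_r2 <- vapply(betas, mk, numeric(1), n = 1e4)
  expect_true(all(diff(f_by_r2) > 0))
  ns <- seq(1e3, 1e5, length.out = 8)
  f_by_n <- vapply(ns, function(n) mk(0.1, n), numeric(1))
  expect_true(all(diff(f_by_n) > 0))
})

test_that("harmonize aligns alleles, filters in order, and audits", {
  # strand-consistent flip: outcome alleles swapped -> beta negated
  ex <- toy_records(1)
  ex$effect_allele <- "A"; ex$other_allele <- "G"; ex$beta <- 0.1
  ou <- ex
  ou$effect_allele <- "G"; ou$other_allele <- "A"; ou$beta <- 0.2
  ou$pval <- 0.5; ou$eaf <- 0.3
  h <- harmonize(summary_stats(ex, "e", quiet = TRUE),
                 summary_stats(ou, "o", quiet = TRUE))
  expect_equal(h$variants$beta_out, -0.2)

  # 10-variant fixture: 1 palindromic, 1 missing in outcome, 1 outcome-significant
  ex <- toy_records(10, seed = 5)
  ex$effect_allele <- "A"; ex$other_allele <- "G"
  ex$effect_allele[4] <- "A"; ex$other_allele[4] <- "T"  # palindromic
  ou <- ex
  ou$pval <- 0.5
  ou$pval[7] <- 1e-9                                      # outcome-significant
  ou <- ou[-2, ]                                          # missing in outcome
  h <- harmonize(summary_stats(ex, "e", quiet = TRUE),
                 summary_stats(ou, "o", quiet = TRUE))
  expect_equal(nrow(h$variants), 7)
  expect_equal(unname(h$audit),
               c(1L, 1L, 1L, 0L))
  expect_equal(sum(h$audit), 10 - nrow(h$variants))

  # A/T exposure variant dropped as palindromic even with informative eaf
  expect_false("rs004" %in% h$variants$variant_id)

  # allele mismatch dropped
  ou2 <- ex
  ou2$pval <- 0.5
  ou2$other_allele[1] <- "C"
  h2 <- harmonize(summary_stats(ex, "e", quiet = TRUE),
                  summary_stats(ou2, "o", quiet = TRUE))
  expect_equal(unname(h2$audit["allele_mismatch"]), 1L)

  # zero retained is an error
  expect_error(
    harmonize(summary_stats(ex[4, ], "e", quiet = TRUE),
              summary_stats(ou, "o", quiet = TRUE)),
    "zero variants")
})

test_that("harmonize is idempotent", {
  ex <- toy_records(8, seed = 77)
  set.seed(78)
  ou <- ex
  ou$beta <- stats::rnorm(8, 0, 0.05)
  ou$pval <- 2 * stats::pnorm(-abs(ou$beta / ou$se))
  flip <- c(2, 5)  # swap outcome alleles on two variants
  ou$effect_allele[flip] <- ex$other_allele[flip]
  ou$other_allele[flip] <- ex$effect_allele[flip]
  ou$beta[flip] <- -ou$beta[flip]
  e1 <- summary_stats(ex, "e", quiet = TRUE)
  o1 <- summary_stats(ou, "o", quiet = TRUE)
  h1 <- harmonize(e1, o1)

  # rebuild exposure/outcome tables from the harmonized set and re-harmonize
  rebuild <- function(h, side) {
    v <- h$variants
    summary_stats(data.frame(
      variant_id = v$variant_id, effect_allele = v$effect_allele,
      other_allele = v$other_allele, eaf = v$eaf,
      beta = if (side == "exp") v$beta_exp else v$beta_out,
      se = if (side == "exp") v$se_exp else v$se_out,
      pval = if (side == "exp") v$pval_exp else v$pval_out,
      n = 1e5, stringsAsFactors = FALSE), side, quiet = TRUE)
  }
  h2 <- harmonize(rebuild(h1, "exp"), rebuild(h1, "out"))
  expect_equal(h2$variants[names(h2$variants) != "variant_id"],
               h1$variants[names(h1$variants) != "variant_id"])
  expect_equal(sum(h2$audit), 0)
})
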