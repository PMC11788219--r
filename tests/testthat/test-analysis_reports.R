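test_that("false-negative code profile matches the fixture's hand tally", {
  fx <- generate_fixture_small()
  retained <- filter_claims_window(fx$claims, fx$surgical, fx$config)
  counts <- error_analysis_fn(fx$expected$fn_participants, retained,
                              fx$config$fn_vocab)
  expect_identical(counts, fx$expected$fn_categories)
  # no false negatives -> all-zero counts
  none <- error_analysis_fn(character(0), retained, fx$config$fn_vocab)
  expect_identical(sum(none), 0L)
  # a participant with codes in several categories counts in each
  multi <- structure(data.frame(
    participant_id = "X", code_system = "ICD9",
    code = c("625.9", "V64.41", "V72.31"),
    service_date = as.Date("2008-01-01"), source = "ehr",
    stringsAsFactors = FALSE), class = c("claims_table", "data.frame"))
  counts <- error_analysis_fn("X", multi)
  expect_identical(counts[["pain"]], 1L)
  expect_identical(counts[["laparoscopy_laparotomy"]], 1L)
  expect_identical(counts[["other"]], 1L)
})

test_that("false-positive subtype tally matches the fixture's hand tally", {
  fx <- generate_fixture_small()
  tst <- test_labels(fx$claims, fx$surgical, fx$config)
  tally <- error_analysis_fp(fx$expected$fp_participants, tst)
  expect_identical(tally, fx$expected$fp_subtypes)
  expect_identical(sum(error_analysis_fp(character(0), tst)), 0L)
  # a perfectly specific cohort has no false positives to tally
  spec <- generator_spec(
    n_participants = 80,
    coding_specificity = c(overall = 1, SE = 1, OE = 1, DE = 1),
    rng_seed = 3)
  coh <- generate_cohort(spec)
  cfg <- run_config(rng_seed = 3)
  ref <- reference_labels(coh$surgical)
  tst <- test_labels(coh$claims, coh$surgical, cfg)
  fp_ids <- ref$participant_id[!ref$overall & tst$overall]
  expect_identical(length(fp_ids), 0L)
})

test_that("subgroup report matches the fixture's hand-computed strata", {
  fx <- generate_fixture_small()
  ref <- fx$expected$reference_labels
  tst <- fx$expected$test_labels
  w <- capture_warnings(sg <- subgroup_report(ref, tst, fx$surgical, fx$config))
  expect_true(any(grepl("unstable", w)))
  want <- fx$expected$subgroup
  for (stratum in names(want)) {
    rows <- sg[sg$stratum == stratum, ]
    expect_identical(rows$n[1], want[[stratum]]$n, info = stratum)
    expect_equal(rows$estimate[rows$metric == "percent_agreement"],
                 want[[stratum]]$agreement, tolerance = 1e-12, info = stratum)
    expect_equal(rows$estimate[rows$metric == "kappa"],
                 want[[stratum]]$kappa, tolerance = 1e-12, info = stratum)
    expect_true(all(rows$small_sample == (want[[stratum]]$n < 10)))
  }
  # ethnicity contrast excludes the participant with missing ethnicity
  eth_n <- sum(sg$n[sg$metric == "kappa" & grepl("hispanic", sg$stratum)])
  expect_identical(eth_n, nrow(fx$surgical) - 1L)
})

test_that("unknown race joins the WoC stratum only when configured to", {
  fx <- generate_fixture_small()
  surgical <- fx$surgical
  surgical$race_group[surgical$participant_id == "P09"] <- "unknown"
  ref <- fx$expected$reference_labels
  tst <- fx$expected$test_labels
  cfg_in <- fx$config
  cfg_out <- fx$config
  cfg_out$unknown_race_to_woc <- FALSE
  sg_in <- suppressWarnings(subgroup_report(ref, tst, surgical, cfg_in))
  sg_out <- suppressWarnings(subgroup_report(ref, tst, surgical, cfg_out))
  expect_identical(sg_in$n[sg_in$stratum == "woc"][1], 4L)
  expect_identical(sg_out$n[sg_out$stratum == "woc"][1], 3L)
  # race strata partition the cohort under the pooling default
  expect_identical(sg_in$n[sg_in$stratum == "woc"][1] +
                     sg_in$n[sg_in$stratum == "white"][1],
                   nrow(surgical))
})

test_that("run_pipeline writes all reports with conserved stage counts", {
  fx <- generate_fixture_small()
  paths <- write_fixture_csvs(fx)
  out_dir <- file.path(paths$dir, "out")
  bundle <- suppressWarnings(
    run_pipeline(paths$surgical, paths$claims, fx$config, out_dir))
  expect_true(all(file.exists(file.path(out_dir, c(
    "accuracy_table.csv", "accuracy_table.txt", "subgroup_table.csv",
    "error_fn.csv", "error_fp.csv", "run_log.txt")))))
  counts <- bundle$counts
  expect_identical(counts$participants, 10L)
  expect_identical(counts$claims_read, fx$expected$claims_read)
  expect_identical(counts$claims_retained, fx$expected$claims_retained)
  expect_identical(counts$claims_read,
                   counts$claims_retained + counts$claims_removed_window)
  # FN/FP counts equal the overall contingency cells
  t <- build_contingency(bundle$reference, bundle$test, "overall")
  expect_identical(counts$fn, t$fn)
  expect_identical(counts$fp, t$fp)
  expect_identical(bundle$fn_participants, fx$expected$fn_participants)
  expect_identical(bundle$fp_participants, fx$expected$fp_participants)
  expect_identical(bundle$error_fn, fx$expected$fn_categories)
  expect_identical(bundle$error_fp, fx$expected$fp_subtypes)
})

test_that("an empty claims file yields zero sensitivity and full specificity", {
  fx <- generate_fixture_small()
  paths <- write_fixture_csvs(fx)
  empty <- file.path(paths$dir, "empty_claims.csv")
  writeLines("participant_id,code_system,code,service_date,source", empty)
  bundle <- suppressWarnings(
    run_pipeline(paths$surgical, empty, fx$config, out_dir = NULL))
  acc <- bundle$accuracy
  expect_identical(
    acc$estimate[acc$comparison == "overall" & acc$metric == "sensitivity"], 0)
  expect_identical(
    acc$estimate[acc$comparison == "overall" & acc$metric == "specificity"], 1)
})

test_that("the smaller demographic stratum gets the wider kappa CI", {
  # emulates the published subgroup design (~49 vs ~363 participants):
  # with coding errors independent of demographics, CI width is driven by
  # stratum size
  coh <- generate_cohort(generator_spec(rng_seed = 29))
  cfg <- run_config(bootstrap_reps = 500L, rng_seed = 29)
  ref <- reference_labels(coh$surgical)
  tst <- test_labels(coh$claims, coh$surgical, cfg)
  sg <- suppressWarnings(subgroup_report(ref, tst, coh$surgical, cfg))
  width <- function(stratum) {
    r <- sg[sg$stratum == stratum & sg$metric == "kappa", ]
    r$upper - r$lower
  }
  expect_identical(sum(sg$n[sg$metric == "kappa" & sg$stratum %in% c("woc", "white")]),
                   412L)
  expect_gt(width("woc"), width("white"))
  expect_gt(width("hispanic_yes"), width("hispanic_no"))
})
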