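# Error analysis, diversity/subgroup analysis, and the pipeline driver.

#' False-negative code profile
#'
#' For the participants with surgically confirmed disease but no retained
#' endometriosis code (the false negatives of the overall comparison), bins
#' the codes that *are* present in their window-filtered claims into
#' categories — by default laparoscopy/laparotomy markers, pain, other
#' symptoms, with everything unmatched in `other` — and counts participants
#' per category. A participant with codes in several categories counts in
#' each.
#'
#' @param fn_participants Character vector of false-negative participant
#'   ids (from the overall comparison).
#' @param claims The window-filtered `claims_table`.
#' @param vocab Category-to-code-prefix map; see [default_fn_vocab()].
#' @return Named integer vector of participant counts, one per category
#'   plus `other` (all zero when there are no false negatives).
#' @export
error_analysis_fn <- function(fn_participants, claims,
                              vocab = default_fn_vocab()) {
  validate_fn_vocab(vocab)
  categories <- c(names(vocab), "other")
  counts <- stats::setNames(integer(length(categories)), categories)
  norm_vocab <- lapply(vocab, normalize_code)
  for (id in fn_participants) {
    codes <- normalize_code(claims$code[claims$participant_id == id])
    if (!length(codes)) next
    matched_any <- rep(FALSE, length(codes))
    for (cat in names(norm_vocab)) {
      hits <- vapply(codes, function(cd)
        any(startsWith(cd, norm_vocab[[cat]])), TRUE)
      if (any(hits)) counts[[cat]] <- counts[[cat]] + 1L
      matched_any <- matched_any | hits
    }
    if (any(!matched_any)) counts[["other"]] <- counts[["other"]] + 1L
  }
  counts
}

#' False-positive subtype tally
#'
#' For participants without surgically confirmed disease but with a
#' retained endometriosis code (the false positives of the overall
#' comparison), tallies which administrative subtype flags are present:
#' SE/OE/DE from subtype-mapped codes and NOS for codes with no
#' subtype-specific mapping. A participant may count in several.
#'
#' @param fp_participants Character vector of false-positive ids.
#' @param test Test-label data frame from [test_labels()] (must include the
#'   `nos` column).
#' @return Named integer vector `c(SE, OE, DE, NOS)`.
#' @export
error_analysis_fp <- function(fp_participants, test) {
  rows <- test[test$participant_id %in% fp_participants, , drop = FALSE]
  c(SE = sum(rows$SE), OE = sum(rows$OE), DE = sum(rows$DE),
    NOS = sum(rows$nos))
}

subgroup_strata <- function(demographics, config) {
  race <- demographics$race_group
  woc <- race == "woc" | (config$unknown_race_to_woc & race == "unknown")
  list(
    woc = demographics$participant_id[woc],
    white = demographics$participant_id[race == "white"],
    hispanic_yes = demographics$participant_id[demographics$hispanic == "yes"],
    hispanic_no = demographics$participant_id[demographics$hispanic == "no"]
  )
}

#' Subgroup (diversity) analysis
#'
#' Recomputes percent agreement, AUCR and Cohen's kappa of the overall
#' comparison — with percentile-bootstrap CIs — within demographic strata:
#' Women of Color vs White women, and Hispanic vs non-Hispanic ethnicity.
#' Participants with missing ethnicity are excluded from the ethnicity
#' contrast; whether unknown race joins the Women of Color stratum is
#' governed by `config$unknown_race_to_woc` (default `TRUE`, under which
#' the stratum sizes sum to the cohort). Strata smaller than 10
#' participants are reported with a small-sample warning flag.
#'
#' @param reference,test Label data frames covering the same participants.
#' @param demographics A `surgical_table` (supplies `race_group` and
#'   `hispanic`).
#' @param config A [run_config()].
#' @return A data frame with columns `stratum`, `n`, `metric`, `estimate`,
#'   `lower`, `upper`, `small_sample`.
#' @export
subgroup_report <- function(reference, test, demographics,
                            config = run_config()) {
  strata <- subgroup_strata(demographics, config)
  metrics <- c("percent_agreement", "aucr", "kappa")
  rows <- list()
  seed_offset <- 0L
  for (name in names(strata)) {
    ids <- strata[[name]]
    n <- length(ids)
    small <- n < 10L
    if (small) {
      warning(sprintf("stratum '%s' has only %d participants; estimates are unstable",
                      name, n), call. = FALSE)
    }
    r <- reference[reference$participant_id %in% ids, , drop = FALSE]
    t <- test[test$participant_id %in% ids, , drop = FALSE]
    seed_offset <- seed_offset + 1L
    cfg <- config
    cfg$rng_seed <- config$rng_seed + seed_offset
    for (m in metrics) {
      est <- if (n > 0L) metric_fun(m)(build_contingency(r, t, "overall")) else NA_real_
      if (n >= 2L && !is.na(est)) {
        ci <- bootstrap_ci(r, t, m, cfg, key = "overall")
        lo <- ci$lower
        hi <- ci$upper
      } else {
        lo <- hi <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = name, n = n, metric = m, estimate = est,
        lower = lo, upper = hi, small_sample = small,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full validation pipeline
#'
#' Reads the surgical reference and administrative claims tables, derives
#' reference labels (surgical typology) and test labels (ICD mapping +
#' window rule), computes the full accuracy report with bootstrap CIs, the
#' false-negative/false-positive error analyses and the subgroup report,
#' and writes everything to `out_dir`: `accuracy_table.csv`,
#' `accuracy_table.txt`, `subgroup_table.csv`, `error_fn.csv`,
#' `error_fp.csv` and `run_log.txt` (inputs, config, seed, and the
#' participant/claim counts at each stage).
#'
#' @param surgical_csv,claims_csv Input CSV paths.
#' @param config A [run_config()] (or a path handled by [load_config()]
#'   upstream).
#' @param out_dir Output directory, created if needed; `NULL` skips
#'   writing.
#' @return Invisibly, a list with `reference`, `test`, `accuracy`,
#'   `error_fn`, `error_fp`, `subgroups` and `counts`.
#' @export
run_pipeline <- function(surgical_csv, claims_csv, config = run_config(),
                         out_dir = NULL) {
  surgical <- read_surgical_table(surgical_csv)
  claims <- read_claims_table(claims_csv)

  reference <- reference_labels(surgical)
  retained <- filter_claims_window(claims, surgical, config)
  test <- test_labels(claims, surgical, config)

  accuracy <- full_report(reference, test, config)

  ord <- match(reference$participant_id, test$participant_id)
  fn_ids <- reference$participant_id[reference$overall & !test$overall[ord]]
  fp_ids <- reference$participant_id[!reference$overall & test$overall[ord]]
  fn_profile <- error_analysis_fn(fn_ids, retained, config$fn_vocab)
  fp_profile <- error_analysis_fp(fp_ids, test)
  subgroups <- subgroup_report(reference, test, surgical, config)

  counts <- list(
    participants = nrow(surgical),
    cases = sum(surgical$endometriosis_confirmed),
    claims_read = nrow(claims),
    claims_retained = nrow(retained),
    claims_removed_window = nrow(claims) - nrow(retained),
    fn = length(fn_ids), fp = length(fp_ids))

  bundle <- list(reference = reference, test = test, accuracy = accuracy,
                 error_fn = fn_profile, error_fp = fp_profile,
                 subgroups = subgroups, counts = counts,
                 fn_participants = fn_ids, fp_participants = fp_ids)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(accuracy),
                     file.path(out_dir, "accuracy_table.csv"), row.names = FALSE)
    writeLines(format_accuracy_table(accuracy),
               file.path(out_dir, "accuracy_table.txt"))
    utils::write.csv(subgroups, file.path(out_dir, "subgroup_table.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(category = names(fn_profile),
                                participants = as.integer(fn_profile)),
                     file.path(out_dir, "error_fn.csv"), row.names = FALSE)
    utils::write.csv(data.frame(subtype = names(fp_profile),
                                participants = as.integer(fp_profile)),
                     file.path(out_dir, "error_fp.csv"), row.names = FALSE)
    log_lines <- c(
      sprintf("surgical input : %s", surgical_csv),
      sprintf("claims input   : %s", claims_csv),
      sprintf("study period   : %s .. %s", config$study_start, config$study_end),
      sprintf("window         : surgery + %d days", config$window_days),
      sprintf("bootstrap      : %d reps, ci %.2f, seed %d",
              config$bootstrap_reps, config$ci_level, config$rng_seed),
      sprintf("participants   : %d (%d surgically confirmed)",
              counts$participants, counts$cases),
      sprintf("claims         : %d read, %d retained, %d removed by window/period",
              counts$claims_read, counts$claims_retained,
              counts$claims_removed_window),
      sprintf("errors         : %d false negatives, %d false positives",
              counts$fn, counts$fp))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(bundle)
}
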