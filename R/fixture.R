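# A 10-participant hand-written fixture exercising every pipeline branch,
# shipped together with its hand-computed expected outputs. All expected
# values below were enumerated by hand from the tables; nothing here calls
# the pipeline.

#' Hand-written 10-participant fixture
#'
#' Covers every branch of the pipeline: SE-only, OE-only, DE via cul-de-sac
#' obliteration, OE+DE, a missing-lesion-info case (assumed SE), a control
#' with a false-positive subtype code, a case made test-negative purely by
#' the 30-day window rule (P06 — the only such participant), a control with
#' distractor codes only, a boundary claim at exactly surgery + 30 days, a
#' duplicated claim row, and an unspecified (NOS) code.
#'
#' @return A list with `surgical` (a `surgical_table`), `claims` (a
#'   `claims_table`), `config` (the [run_config()] the expectations assume:
#'   default code map, 30-day window, 2007-2009 study period) and
#'   `expected`, the hand-computed truth: per-participant reference and
#'   test labels, 2x2 cells per comparison, stage counts, false-negative
#'   code categories, false-positive subtype tally and per-stratum 2x2
#'   cells with their kappas.
#' @export
generate_fixture_small <- function() {
  surgical <- new_surgical_table(data.frame(
    participant_id = sprintf("P%02d", 1:10),
    surgery_date = as.Date(c(
      "2007-05-10", "2007-08-01", "2008-02-15", "2008-06-20", "2008-09-05",
      "2008-11-12", "2009-01-08", "2009-03-30", "2009-05-17", "2009-07-02")),
    endometriosis_confirmed = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                                TRUE, FALSE, FALSE, FALSE, TRUE),
    rasrm_stage = c("I", "III", "IV", "IV", "none",
                    "I", "none", "none", "none", "II"),
    lesions = c("ovary:superficial",            # P01 SE only
                "ovary:deep",                   # P02 OE only
                "",                             # P03 DE via obliteration
                "ovary:deep|peritoneum:deep",   # P04 OE + DE
                "",                             # P05 no lesion info -> SE
                "peritoneum:superficial",       # P06 SE; only a late code
                "", "", "",                     # P07-P09 controls
                "ovary:superficial|peritoneum:superficial"),  # P10 SE
    culdesac_obliteration = c(FALSE, FALSE, TRUE, FALSE, FALSE,
                              FALSE, FALSE, FALSE, FALSE, FALSE),
    lesion_info_available = c(TRUE, TRUE, TRUE, TRUE, FALSE,
                              TRUE, TRUE, TRUE, TRUE, TRUE),
    race_group = c("white", "white", "woc", "white", "woc",
                   "white", "woc", "white", "white", "white"),
    hispanic = c("no", "yes", "no", "no", "yes",
                 "missing", "no", "yes", "no", "no"),
    stringsAsFactors = FALSE))

  claim <- function(id, system, code, date, source = "ehr") {
    data.frame(participant_id = id, code_system = system, code = code,
               service_date = as.Date(date), source = source,
               stringsAsFactors = FALSE)
  }
  claims <- new_claims_table(rbind(
    claim("P01", "ICD9",  "617.3",  "2007-05-20"),              # +10, SE
    claim("P02", "ICD9",  "617.1",  "2007-08-06"),              # +5, OE
    claim("P03", "ICD10", "N80.4",  "2008-03-06"),              # +20, DE
    claim("P04", "ICD9",  "617.1",  "2008-06-23"),              # +3, OE
    claim("P04", "ICD9",  "617.4",  "2008-06-27"),              # +7, DE
    claim("P04", "ICD9",  "617.1",  "2008-07-02"),              # +12, duplicate
    claim("P05", "ICD9",  "617.9",  "2008-09-20"),              # +15, NOS
    claim("P06", "ICD9",  "617.3",  "2008-12-13"),              # +31: removed
    claim("P06", "ICD9",  "625.9",  "2008-11-14"),              # +2, pain
    claim("P07", "ICD9",  "617.3",  "2009-01-08"),              # +0, FP (SE)
    claim("P08", "ICD9",  "789.00", "2009-03-31"),              # +1, pain
    claim("P08", "ICD9",  "V64.41", "2009-04-03"),              # +4, laparoscopy
    claim("P10", "ICD9",  "617.3",  "2009-08-01"),              # +30: boundary, kept
    claim("P10", "ICD10", "N80.9",  "2009-08-16")               # +45: removed
  ))

  config <- run_config(bootstrap_reps = 200L, rng_seed = 42L)

  ref <- data.frame(
    participant_id = surgical$participant_id,
    overall = surgical$endometriosis_confirmed,
    SE = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
    OE = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    DE = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  tst <- data.frame(
    participant_id = surgical$participant_id,
    overall = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    SE = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    OE = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    DE = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    nos = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)

  expected <- list(
    reference_labels = ref,
    test_labels = tst,
    contingency = list(
      overall = c(tp = 6L, fp = 1L, fn = 1L, tn = 2L),
      SE      = c(tp = 2L, fp = 1L, fn = 2L, tn = 5L),
      OE      = c(tp = 2L, fp = 0L, fn = 0L, tn = 8L),
      DE      = c(tp = 2L, fp = 0L, fn = 0L, tn = 8L)),
    overall_kappa = (0.8 - 0.58) / (1 - 0.58),   # p_o = 8/10, p_e = (7*7 + 3*3)/100
    claims_read = 14L,
    claims_retained = 12L,
    window_only_negative = "P06",
    fn_participants = "P06",
    fp_participants = "P07",
    fn_categories = c(laparoscopy_laparotomy = 0L, pain = 1L,
                      other_symptom = 0L, other = 0L),
    fp_subtypes = c(SE = 1L, OE = 0L, DE = 0L, NOS = 0L),
    subgroup = list(
      woc   = list(n = 3L, cells = c(tp = 2L, fp = 1L, fn = 0L, tn = 0L),
                   agreement = 2 / 3, kappa = 0),
      white = list(n = 7L, cells = c(tp = 4L, fp = 0L, fn = 1L, tn = 2L),
                   agreement = 6 / 7, kappa = 16 / 23),
      hispanic_yes = list(n = 3L, cells = c(tp = 2L, fp = 0L, fn = 0L, tn = 1L),
                          agreement = 1, kappa = 1),
      hispanic_no  = list(n = 6L, cells = c(tp = 4L, fp = 1L, fn = 0L, tn = 1L),
                          agreement = 5 / 6, kappa = 8 / 14))
  )
  list(surgical = surgical, claims = claims, config = config,
       expected = expected)
}
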