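# Synthetic cohort generator.
#
# Emulates the statistical structure the validation pipeline assumes: a
# surgical operative cohort with ~42% surgically confirmed endometriosis,
# non-exclusive subtype truth, imperfect participant-level diagnostic
# coding, distractor (pain/procedure) codes, and endometriosis codes dated
# outside the post-surgery window. It emulates structure only — no
# insurance churn, longitudinal care patterns or linkage noise.

# Small fixed distractor vocabulary (codes that are NOT endometriosis
# codes), mirroring the code families seen in false-negative error
# profiles: surgical-procedure markers, pelvic/abdominal pain, other
# gynecologic symptoms, and unrelated encounter codes.
distractor_pool <- function() {
  data.frame(
    code = c("V64.41", "54.21", "Z53.33",
             "625.9", "789.00", "R10.2",
             "626.8", "N92.6", "R53.83",
             "V72.31", "Z01.419"),
    code_system = c("ICD9", "ICD9", "ICD10",
                    "ICD9", "ICD9", "ICD10",
                    "ICD9", "ICD10", "ICD10",
                    "ICD9", "ICD10"),
    stringsAsFactors = FALSE)
}

#' Default false-negative code vocabulary
#'
#' Category-to-code-prefix map used by [error_analysis_fn()] to bin the
#' codes present for false-negative participants: laparoscopy/laparotomy
#' markers, pain codes and other gynecologic symptom codes; anything
#' unmatched falls into `other`. Prefix matching is dot- and
#' case-insensitive. The vocabulary is deliberately small and editable via
#' the config file (`vocab.<category>` keys).
#'
#' @return A named list of character prefix vectors.
#' @export
default_fn_vocab <- function() {
  list(
    laparoscopy_laparotomy = c("V64.4", "54.21", "Z53.3"),
    pain = c("625.9", "789.0", "R10"),
    other_symptom = c("626", "N92", "R53")
  )
}

NOS_ENDO_CODES <- data.frame(
  code = c("617.0", "617.2", "617.8", "617.9",
           "N80.0", "N80.2", "N80.8", "N80.9"),
  code_system = rep(c("ICD9", "ICD10"), each = 4),
  stringsAsFactors = FALSE)

#' Specification for the synthetic cohort generator
#'
#' Defaults reproduce the published structure of the Utah operative
#' validation cohort: 412 participants, 42% surgically confirmed
#' prevalence, non-exclusive subtype probabilities among cases (SE 0.827,
#' OE 0.220, DE 0.335), overall administrative coding sensitivity 0.88 and
#' specificity 0.87 with per-subtype values taken from the measured
#' accuracy table (a modeling choice — the generative truth was never
#' published), race distribution white/WoC/unknown = 363/33/16 and
#' Hispanic yes/no/missing = 51/339/22.
#'
#' Because superficial endometriosis is defined as *only* superficial
#' lesions, an SE draw is dropped whenever an OE/DE trigger is drawn for
#' the same case; OE and DE marginals are preserved and the realized SE
#' share among cases is ~0.43 (the published subtype counts are not
#' jointly attainable under the strict rule; see the methods vignette).
#'
#' @param n_participants Cohort size (default 412).
#' @param prevalence Probability of surgically confirmed endometriosis
#'   (default 0.42).
#' @param subtype_probs Named Bernoulli probabilities for SE/OE/DE among
#'   cases, sampled independently with empty sets resampled.
#' @param coding_sensitivity Named fractions (`overall`, `SE`, `OE`, `DE`):
#'   probability a case receives a within-window endometriosis code, and
#'   the target per-subtype code sensitivities.
#' @param coding_specificity Same shape: `1 - specificity` is the
#'   probability a negative participant receives a (subtype) code.
#' @param distractor_rate Expected number of non-endometriosis distractor
#'   codes per participant (Poisson; default 1.5).
#' @param late_code_rate Probability a case carries an additional
#'   endometriosis code dated past the window (default 0.10). Late codes
#'   are extra rows — the within-window label is still governed by the
#'   sensitivity draw — so an *uncoded* case with a late code is exactly a
#'   false negative created by the window rule.
#' @param missing_info_rate Probability an SE-only case lacks lesion
#'   detail on the operative form (default 10/173, the published share of
#'   cases assumed SE for that reason).
#' @param race_probs,hispanic_probs Named categorical distributions.
#' @param rng_seed Integer seed; identical specs generate byte-identical
#'   tables.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(n_participants = 412L,
                           prevalence = 0.42,
                           subtype_probs = c(SE = 0.827, OE = 0.220, DE = 0.335),
                           coding_sensitivity = c(overall = 0.88, SE = 0.86,
                                                  OE = 0.82, DE = 0.12),
                           coding_specificity = c(overall = 0.87, SE = 0.83,
                                                  OE = 0.92, DE = 0.99),
                           distractor_rate = 1.5,
                           late_code_rate = 0.10,
                           missing_info_rate = 10 / 173,
                           race_probs = c(white = 363, woc = 33, unknown = 16) / 412,
                           hispanic_probs = c(yes = 51, no = 339, missing = 22) / 412,
                           rng_seed = 1L) {
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 1L) {
    stop("n_participants must be a positive integer")
  }
  fracs <- c(prevalence, subtype_probs, coding_sensitivity,
             coding_specificity, late_code_rate, missing_info_rate)
  if (any(is.na(fracs)) || any(fracs < 0) || any(fracs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  stopifnot(all(SUBTYPES %in% names(subtype_probs)),
            all(c("overall", SUBTYPES) %in% names(coding_sensitivity)),
            all(c("overall", SUBTYPES) %in% names(coding_specificity)),
            distractor_rate >= 0,
            all(RACE_GROUPS %in% names(race_probs)),
            all(HISPANIC_LEVELS %in% names(hispanic_probs)))
  structure(list(
    n_participants = n_participants, prevalence = prevalence,
    subtype_probs = subtype_probs,
    coding_sensitivity = coding_sensitivity,
    coding_specificity = coding_specificity,
    distractor_rate = distractor_rate, late_code_rate = late_code_rate,
    missing_info_rate = missing_info_rate,
    race_probs = race_probs, hispanic_probs = hispanic_probs,
    rng_seed = as.integer(rng_seed)
  ), class = "generator_spec")
}

codes_for_subtype <- function(subtype, code_map) {
  names(code_map)[vapply(code_map, function(v) subtype %in% v, TRUE)]
}

endo_code_system <- function(code) {
  ifelse(startsWith(normalize_code(code), "N80"), "ICD10", "ICD9")
}

#' Generate a synthetic surgical + claims cohort
#'
#' Draws case status, subtype truth and consistent lesion records, then
#' emits administrative claims under a participant-level coding error
#' model: a case receives a within-window endometriosis code with
#' probability `coding_sensitivity["overall"]`, a control with probability
#' `1 - coding_specificity["overall"]`. Conditional on being coded, each
#' true subtype emits its mapped code with probability
#' `sens_s / sens_overall` and each false subtype with `1 - spec_s`; a
#' coded participant with no subtype-specific code receives an unspecified
#' (NOS) endometriosis code, so the overall label is preserved. Distractor
#' codes and out-of-window late codes are appended at the configured
#' rates. Every generated case's lesion list classifies back to its
#' sampled subtype set under [classify_surgical_subtypes()].
#'
#' @param spec A [generator_spec()].
#' @param config A [run_config()] supplying the code map, study period and
#'   window used to place claim dates.
#' @return A list with elements `surgical` (a `surgical_table`) and
#'   `claims` (a `claims_table`), plus a `truth` attribute (data frame of
#'   latent case/subtype/coded status) for parameter-recovery checks.
#'   Deterministic given `spec$rng_seed`.
#' @export
generate_cohort <- function(spec, config = run_config(rng_seed = spec$rng_seed)) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_participants
  if (n < 1L) stop("cannot generate an empty cohort")
  width <- max(4L, nchar(as.character(n)))
  ids <- sprintf("P%0*d", width, seq_len(n))
  sens <- spec$coding_sensitivity
  spc <- spec$coding_specificity
  sub_codes <- lapply(stats::setNames(SUBTYPES, SUBTYPES),
                      codes_for_subtype, code_map = config$code_map)
  for (s in SUBTYPES) {
    if (!length(sub_codes[[s]])) {
      # degenerate map (e.g. empty): fall back to NOS emission
      sub_codes[[s]] <- NOS_ENDO_CODES$code
    }
  }
  pool <- distractor_pool()
  span <- as.integer(config$study_end - config$study_start)
  margin <- min(60L, span %/% 4L)

  with_rng_seed(spec$rng_seed, {
    case <- stats::runif(n) < spec$prevalence
    surgery_date <- config$study_start + margin +
      floor(stats::runif(n) * (span - 2L * margin + 1L))
    race <- sample(names(spec$race_probs), n, TRUE, spec$race_probs)
    hisp <- sample(names(spec$hispanic_probs), n, TRUE, spec$hispanic_probs)

    truth <- data.frame(participant_id = ids, case = case,
                        SE = FALSE, OE = FALSE, DE = FALSE, coded = FALSE,
                        stringsAsFactors = FALSE)
    lesions <- character(n)
    oblit <- logical(n)
    info <- rep(TRUE, n)
    stage <- rep("none", n)
    stage_probs <- c(I = 98, II = 26, III = 17, IV = 27, none = 5) / 173

    claim_rows <- vector("list", n)
    for (i in seq_len(n)) {
      emit_code <- character(0)
      if (case[i]) {
        repeat {
          draw <- stats::runif(3L) < spec$subtype_probs[SUBTYPES]
          if (any(draw)) break
        }
        names(draw) <- SUBTYPES
        if (draw[["OE"]] || draw[["DE"]]) draw[["SE"]] <- FALSE
        truth$SE[i] <- draw[["SE"]]
        truth$OE[i] <- draw[["OE"]]
        truth$DE[i] <- draw[["DE"]]
        stage[i] <- sample(names(stage_probs), 1L, prob = stage_probs)

        toks <- character(0)
        if (draw[["SE"]]) {
          k <- sample(1:2, 1L)
          toks <- sample(c("ovary:superficial", "peritoneum:superficial"), k)
        }
        if (draw[["OE"]]) {
          toks <- c(toks, "ovary:deep")
          if (stats::runif(1) < 0.3) toks <- c(toks, "ovary:superficial")
        }
        if (draw[["DE"]]) {
          if (stats::runif(1) < 0.8) toks <- c(toks, "peritoneum:deep")
          else oblit[i] <- TRUE
          if (stats::runif(1) < 0.4) toks <- c(toks, "peritoneum:superficial")
        }
        if (draw[["SE"]] && !draw[["OE"]] && !draw[["DE"]] &&
            stats::runif(1) < spec$missing_info_rate) {
          info[i] <- FALSE
          toks <- character(0)
        }
        lesions[i] <- paste(unique(toks), collapse = "|")
      }

      coded <- if (case[i]) stats::runif(1) < sens[["overall"]]
               else stats::runif(1) < 1 - spc[["overall"]]
      truth$coded[i] <- coded
      if (coded) {
        for (s in SUBTYPES) {
          p <- if (truth[[s]][i]) min(1, sens[[s]] / sens[["overall"]])
               else 1 - spc[[s]]
          if (stats::runif(1) < p) {
            emit_code <- c(emit_code, sample(sub_codes[[s]], 1L))
          }
        }
        if (!length(emit_code)) {
          emit_code <- sample(NOS_ENDO_CODES$code, 1L)
        }
      }

      rows <- list()
      for (code in emit_code) {
        nrep <- sample(1:2, 1L)
        offs <- sample(-45:config$window_days, nrep, replace = TRUE)
        d <- surgery_date[i] + offs
        d <- pmin(pmax(d, config$study_start), config$study_end)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = ids[i], code_system = endo_code_system(code),
          code = code, service_date = d,
          source = sample(CLAIM_SOURCES, nrep, TRUE, c(0.15, 0.35, 0.5)),
          stringsAsFactors = FALSE)
      }
      if (case[i] && stats::runif(1) < spec$late_code_rate) {
        code <- if (length(emit_code)) sample(emit_code, 1L)
                else sample(NOS_ENDO_CODES$code, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = ids[i], code_system = endo_code_system(code),
          code = code,
          service_date = surgery_date[i] + config$window_days + sample(1:90, 1L),
          source = sample(CLAIM_SOURCES, 1L, TRUE, c(0.15, 0.35, 0.5)),
          stringsAsFactors = FALSE)
      }
      k <- stats::rpois(1L, spec$distractor_rate)
      if (k > 0L) {
        j <- sample(nrow(pool), k, replace = TRUE)
        d <- surgery_date[i] + sample(-45:config$window_days, k, replace = TRUE)
        d <- pmin(pmax(d, config$study_start), config$study_end)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = ids[i], code_system = pool$code_system[j],
          code = pool$code[j], service_date = d,
          source = sample(CLAIM_SOURCES, k, TRUE, c(0.15, 0.35, 0.5)),
          stringsAsFactors = FALSE)
      }
      if (length(rows)) claim_rows[[i]] <- do.call(rbind, rows)
    }

    surgical <- new_surgical_table(data.frame(
      participant_id = ids, surgery_date = surgery_date,
      endometriosis_confirmed = case, rasrm_stage = stage,
      lesions = lesions, culdesac_obliteration = oblit,
      lesion_info_available = info, race_group = race, hispanic = hisp,
      stringsAsFactors = FALSE))
    keep <- !vapply(claim_rows, is.null, TRUE)
    claims <- if (any(keep)) do.call(rbind, claim_rows[keep]) else
      data.frame(participant_id = character(), code_system = character(),
                 code = character(), service_date = as.Date(character()),
                 source = character(), stringsAsFactors = FALSE)
    rownames(claims) <- NULL
    out <- list(surgical = surgical, claims = new_claims_table(claims))
    attr(out, "truth") <- truth
    out
  })
}
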