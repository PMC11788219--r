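# Test method: endometriosis and subtype diagnoses from ICD-coded claims.

#' Default ICD code-to-subtype map
#'
#' Maps ICD-9 617.x / ICD-10 N80.x code prefixes to endometriosis subtypes,
#' reconstructed from the codes' anatomic-site titles: pelvic peritoneum
#' (617.3 / N80.3) to SE; ovary (617.1 / N80.1) to OE; rectovaginal septum
#' and vagina, and intestine (617.4, 617.5 / N80.4, N80.5) to DE. All other
#' endometriosis codes (uterus, fallopian tube, scar, other sites,
#' unspecified) count toward the overall diagnosis only (NOS). The map is a
#' named list of code prefixes; matching is longest-prefix, case-insensitive
#' and dot-insensitive, and is fully configurable via [run_config()] /
#' [load_config()].
#'
#' @return A named list; each element is a character vector of subtypes
#'   (`character(0)` marks an explicit NOS assignment).
#' @export
default_code_map <- function() {
  list(
    "617.1" = "OE", "N80.1" = "OE",
    "617.3" = "SE", "N80.3" = "SE",
    "617.4" = "DE", "617.5" = "DE", "N80.4" = "DE", "N80.5" = "DE"
  )
}

#' Is a code an endometriosis diagnosis code?
#'
#' A claim counts as an endometriosis diagnosis iff its code root (the part
#' before the dot, case-insensitively, with the dot optional) is ICD-9 `617`
#' or ICD-10 `N80`. Bare `"617"` / `"N80"` also match; anything else —
#' including pain and procedure distractor codes — returns `FALSE`.
#'
#' @param code Character vector of codes (dotted or undotted).
#' @param code_system Character vector, `"ICD9"` or `"ICD10"`, recycled
#'   against `code`.
#' @return Logical vector.
#' @export
#' @examples
#' is_endometriosis_code(c("617.1", "N80.3", "616.1"),
#'                       c("ICD9", "ICD10", "ICD9"))
is_endometriosis_code <- function(code, code_system) {
  stopifnot(all(nzchar(code)))
  norm <- normalize_code(code)
  n <- max(length(code), length(code_system))
  norm <- rep_len(norm, n)
  code_system <- rep_len(code_system, n)
  (code_system == "ICD9" & startsWith(norm, "617")) |
    (code_system == "ICD10" & startsWith(norm, "N80"))
}

#' Map an endometriosis code to its subtype set
#'
#' Longest-prefix match of the (normalized) code against the configured code
#' map. Codes with no subtype-specific entry — or any code under an empty
#' map — return a `nos_only` subtype set: they support the overall diagnosis
#' but no specific subtype.
#'
#' @param code A single endometriosis code (calling this on a
#'   non-endometriosis code is an error).
#' @param code_map A code map as produced by [default_code_map()].
#' @return A `subtype_set`.
#' @export
map_code_to_subtype <- function(code, code_map = default_code_map()) {
  stopifnot(length(code) == 1L)
  norm <- normalize_code(code)
  system <- if (startsWith(norm, "N80")) "ICD10" else "ICD9"
  if (!is_endometriosis_code(code, system)) {
    stop(sprintf("'%s' is not an endometriosis (617.x / N80.x) code", code))
  }
  keys <- names(code_map)
  if (length(keys)) {
    nkeys <- normalize_code(keys)
    hit <- which(vapply(nkeys, function(k) startsWith(norm, k), TRUE))
    if (length(hit)) {
      best <- hit[which.max(nchar(nkeys[hit]))]
      subs <- code_map[[best]]
      if (length(subs)) {
        return(subtype_set(SE = "SE" %in% subs, OE = "OE" %in% subs,
                           DE = "DE" %in% subs))
      }
      return(subtype_set(nos_only = TRUE))
    }
  }
  subtype_set(nos_only = TRUE)
}

as_surgery_dates <- function(surgery_dates) {
  if (is.data.frame(surgery_dates)) {
    stats::setNames(surgery_dates$surgery_date, surgery_dates$participant_id)
  } else {
    stopifnot(!is.null(names(surgery_dates)))
    surgery_dates
  }
}

#' Restrict claims to the study period and post-surgery window
#'
#' A claim is retained iff `study_start <= service_date <= min(study_end,
#' surgery_date + window_days)` — i.e. diagnoses dated more than
#' `window_days` (default 30, "one month") after the participant's surgery
#' are removed, as are claims outside the study period. The boundary is
#' inclusive: a claim dated exactly `surgery_date + window_days` is
#' retained. Claims before surgery but within the study period are kept.
#' The output is a subset of the input with order preserved, so the filter
#' is idempotent.
#'
#' @param claims A `claims_table`.
#' @param surgery_dates A named `Date` vector (participant id to surgery
#'   date) or a `surgical_table`.
#' @param config A [run_config()].
#' @return The retained claims, same class and column layout.
#' @export
filter_claims_window <- function(claims, surgery_dates, config = run_config()) {
  surgery_dates <- as_surgery_dates(surgery_dates)
  unknown <- setdiff(unique(claims$participant_id), names(surgery_dates))
  if (length(unknown)) {
    stop(sprintf("claims reference participant(s) absent from the surgical table: %s",
                 paste(unknown, collapse = ", ")))
  }
  if (nrow(claims) == 0L) return(claims)
  sdate <- surgery_dates[claims$participant_id]
  upper <- pmin(config$study_end, sdate + config$window_days)
  keep <- claims$service_date >= config$study_start & claims$service_date <= upper
  claims[keep, , drop = FALSE]
}

#' Test-method labels from claims
#'
#' Applies the window filter, then derives per-participant administrative
#' labels: `overall` is `TRUE` iff any retained endometriosis code exists;
#' each subtype flag is `TRUE` iff any retained code maps to that subtype
#' under the configured code map; `nos` records the presence of a retained
#' endometriosis code with no subtype-specific mapping. Participants with no
#' (retained) claims get all-`FALSE` labels, so a subtype flag always
#' implies the overall flag. Labels are invariant to claim row order and
#' duplication.
#'
#' @param claims A `claims_table` (raw; filtering is applied internally).
#' @inheritParams filter_claims_window
#' @return A data frame with columns `participant_id`, `overall`, `SE`,
#'   `OE`, `DE`, `nos` (logical), one row per participant in
#'   `surgery_dates`, in that order.
#' @export
test_labels <- function(claims, surgery_dates, config = run_config()) {
  surgery_dates <- as_surgery_dates(surgery_dates)
  retained <- filter_claims_window(claims, surgery_dates, config)
  ids <- names(surgery_dates)
  out <- data.frame(participant_id = ids, overall = FALSE, SE = FALSE,
                    OE = FALSE, DE = FALSE, nos = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(retained)) {
    endo <- is_endometriosis_code(retained$code, retained$code_system)
    endo_claims <- retained[endo, , drop = FALSE]
    # map each distinct code once, then aggregate per participant
    codes <- unique(endo_claims$code)
    sets <- lapply(codes, map_code_to_subtype, code_map = config$code_map)
    names(sets) <- codes
    for (i in seq_len(nrow(endo_claims))) {
      j <- match(endo_claims$participant_id[i], out$participant_id)
      s <- sets[[endo_claims$code[i]]]
      out$overall[j] <- TRUE
      out$SE[j] <- out$SE[j] || s$SE
      out$OE[j] <- out$OE[j] || s$OE
      out$DE[j] <- out$DE[j] || s$DE
      out$nos[j] <- out$nos[j] || s$nos_only
    }
  }
  out
}
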