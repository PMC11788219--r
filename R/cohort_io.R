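# Domain tables, CSV readers/writers and the run configuration.
#
# The surgical reference table and the administrative claims table are plain
# data frames with validated, typed columns; one row is one record. Lesions
# are kept in their CSV encoding (a pipe-delimited "site:depth" token string,
# mirroring the one-form-per-surgery structure of the rASRM operative report)
# and parsed on demand with parse_lesions().

SURGICAL_COLUMNS <- c(
  "participant_id", "surgery_date", "endometriosis_confirmed", "rasrm_stage",
  "lesions", "culdesac_obliteration", "lesion_info_available", "race_group",
  "hispanic"
)
CLAIMS_COLUMNS <- c("participant_id", "code_system", "code", "service_date",
                    "source")

new_surgical_table <- function(df) {
  structure(df, class = c("surgical_table", "data.frame"))
}

new_claims_table <- function(df) {
  structure(df, class = c("claims_table", "data.frame"))
}

#' Parse a lesion token string
#'
#' Lesion lists are serialized as pipe-delimited `site:depth` tokens, e.g.
#' `"ovary:superficial|peritoneum:deep"`. Sites are `ovary`, `peritoneum` or
#' `cul_de_sac`; depth classes are `superficial` or `deep` (deep corresponds
#' to >5 mm invasion for peritoneal lesions).
#'
#' @param x A single token string (may be `""` for no recorded lesions).
#' @return A data frame with columns `site` and `depth_class`, zero rows for
#'   an empty string.
#' @export
#' @examples
#' parse_lesions("ovary:superficial|peritoneum:deep")
parse_lesions <- function(x) {
  stopifnot(length(x) == 1L)
  if (is.na(x) || !nzchar(trimws(x))) {
    return(data.frame(site = character(), depth_class = character(),
                      stringsAsFactors = FALSE))
  }
  tokens <- strsplit(trimws(x), "|", fixed = TRUE)[[1L]]
  parts <- strsplit(tokens, ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop(sprintf("malformed lesion token '%s' (expected site:depth)",
                 tokens[bad][1L]), call. = FALSE)
  }
  site <- trimws(vapply(parts, `[[`, "", 1L))
  depth <- trimws(vapply(parts, `[[`, "", 2L))
  if (any(!site %in% LESION_SITES)) {
    stop(sprintf("unknown lesion site '%s'", site[!site %in% LESION_SITES][1L]),
         call. = FALSE)
  }
  if (any(!depth %in% DEPTH_CLASSES)) {
    stop(sprintf("unknown depth class '%s'",
                 depth[!depth %in% DEPTH_CLASSES][1L]), call. = FALSE)
  }
  data.frame(site = site, depth_class = depth, stringsAsFactors = FALSE)
}

deparse_lesions <- function(site, depth_class) {
  if (length(site) == 0L) return("")
  paste(paste(site, depth_class, sep = ":"), collapse = "|")
}

check_header <- function(df, expected, path) {
  missing <- setdiff(expected, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[expected]
}

#' Read the surgical reference table
#'
#' Reads and validates the per-participant surgical reference data: surgery
#' date, surgically visualized endometriosis status (the reference method),
#' the recorded lesion list, rASRM stage and demographics. Every row is
#' validated; a malformed date, unknown enumeration value or duplicated
#' participant id is a hard error naming the offending row. Rows are never
#' silently dropped.
#'
#' Invariants enforced at read time: a participant without surgically
#' confirmed endometriosis has no lesions and stage `none`; a participant
#' flagged as having no lesion information has an empty lesion list.
#'
#' @param path Path to a CSV file with columns `participant_id`,
#'   `surgery_date`, `endometriosis_confirmed`, `rasrm_stage`, `lesions`,
#'   `culdesac_obliteration`, `lesion_info_available`, `race_group`,
#'   `hispanic`. Dates are ISO 8601 (`YYYY-MM-DD`).
#' @return A `surgical_table` data frame, one row per participant.
#' @seealso [write_surgical_table()], [read_claims_table()]
#' @export
read_surgical_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  raw <- check_header(raw, SURGICAL_COLUMNS, path)
  n <- nrow(raw)
  if (n == 0L) {
    df <- data.frame(
      participant_id = character(), surgery_date = as.Date(character()),
      endometriosis_confirmed = logical(), rasrm_stage = character(),
      lesions = character(), culdesac_obliteration = logical(),
      lesion_info_available = logical(), race_group = character(),
      hispanic = character(), stringsAsFactors = FALSE)
    return(new_surgical_table(df))
  }

  id <- trimws(raw$participant_id)
  if (any(!nzchar(id))) stop_row(path, which(!nzchar(id))[1L], "empty participant_id")
  dup <- duplicated(id)
  if (any(dup)) {
    stop_row(path, which(dup)[1L],
             sprintf("duplicate participant_id '%s'", id[dup][1L]))
  }

  sdate <- parse_iso_date(raw$surgery_date)
  if (anyNA(sdate)) {
    i <- which(is.na(sdate))[1L]
    stop_row(path, i, sprintf("malformed surgery_date '%s'", raw$surgery_date[i]))
  }
  check_enum <- function(col, levels, what) {
    v <- trimws(raw[[col]])
    bad <- !v %in% levels
    if (any(bad)) {
      stop_row(path, which(bad)[1L],
               sprintf("unknown %s '%s'", what, v[bad][1L]))
    }
    v
  }
  check_bool <- function(col) {
    v <- parse_logical_strict(raw[[col]])
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop_row(path, i, sprintf("malformed logical in %s: '%s'", col, raw[[col]][i]))
    }
    v
  }

  confirmed <- check_bool("endometriosis_confirmed")
  oblit <- check_bool("culdesac_obliteration")
  info <- check_bool("lesion_info_available")
  stage <- check_enum("rasrm_stage", RASRM_STAGES, "rasrm_stage")
  race <- check_enum("race_group", RACE_GROUPS, "race_group")
  hisp <- check_enum("hispanic", HISPANIC_LEVELS, "hispanic value")

  lesions <- trimws(raw$lesions)
  for (i in seq_len(n)) {
    les <- tryCatch(parse_lesions(lesions[i]),
                    error = function(e) stop_row(path, i, conditionMessage(e)))
    if (!confirmed[i] && (nrow(les) > 0L || oblit[i] || stage[i] != "none")) {
      stop_row(path, i,
               "participant without confirmed endometriosis has lesions, cul-de-sac obliteration, or a non-'none' stage")
    }
    if (!info[i] && nrow(les) > 0L) {
      stop_row(path, i, "lesion_info_available is FALSE but lesions are recorded")
    }
  }

  df <- data.frame(
    participant_id = id, surgery_date = sdate,
    endometriosis_confirmed = confirmed, rasrm_stage = stage,
    lesions = lesions, culdesac_obliteration = oblit,
    lesion_info_available = info, race_group = race, hispanic = hisp,
    stringsAsFactors = FALSE)
  new_surgical_table(df)
}

#' Read the administrative claims table
#'
#' Reads ICD-coded diagnosis claims (the test method). All rows are retained
#' in file order; no filtering happens at read time — the study-period and
#' post-surgery window restrictions are applied later by
#' [filter_claims_window()]. Claims referencing participants absent from the
#' surgical table are retained here and flagged by the pipeline.
#'
#' @param path Path to a CSV file with columns `participant_id`,
#'   `code_system` (`ICD9`/`ICD10`), `code` (dotted or undotted, e.g.
#'   `"617.1"` or `"N801"`), `service_date` (ISO 8601) and `source`
#'   (`inpatient`/`ambulatory`/`ehr`).
#' @return A `claims_table` data frame, one row per claim.
#' @export
read_claims_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  raw <- check_header(raw, CLAIMS_COLUMNS, path)
  n <- nrow(raw)
  if (n == 0L) {
    df <- data.frame(
      participant_id = character(), code_system = character(),
      code = character(), service_date = as.Date(character()),
      source = character(), stringsAsFactors = FALSE)
    return(new_claims_table(df))
  }
  id <- trimws(raw$participant_id)
  if (any(!nzchar(id))) stop_row(path, which(!nzchar(id))[1L], "empty participant_id")
  system <- trimws(raw$code_system)
  bad <- !system %in% CODE_SYSTEMS
  if (any(bad)) {
    stop_row(path, which(bad)[1L], sprintf("unknown code_system '%s'", system[bad][1L]))
  }
  code <- trimws(raw$code)
  if (any(!nzchar(code))) stop_row(path, which(!nzchar(code))[1L], "empty code")
  sdate <- parse_iso_date(raw$service_date)
  if (anyNA(sdate)) {
    i <- which(is.na(sdate))[1L]
    stop_row(path, i, sprintf("malformed service_date '%s'", raw$service_date[i]))
  }
  src <- trimws(raw$source)
  bad <- !src %in% CLAIM_SOURCES
  if (any(bad)) stop_row(path, which(bad)[1L], sprintf("unknown source '%s'", src[bad][1L]))

  df <- data.frame(participant_id = id, code_system = system, code = code,
                   service_date = sdate, source = src, stringsAsFactors = FALSE)
  new_claims_table(df)
}

#' Write the surgical or claims table
#'
#' Inverse of the readers: writing then reading reproduces the table exactly
#' (dates, lesion token strings, enumeration values).
#'
#' @param x A `surgical_table` or `claims_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_surgical_table <- function(x, path) {
  df <- as.data.frame(x)
  df$surgery_date <- format(df$surgery_date, "%Y-%m-%d")
  utils::write.csv(df[SURGICAL_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surgical_table
#' @export
write_claims_table <- function(x, path) {
  df <- as.data.frame(x)
  df$service_date <- format(df$service_date, "%Y-%m-%d")
  utils::write.csv(df[CLAIMS_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the analysis parameters: the post-surgery claim window, the study
#' period the claims are restricted to, bootstrap settings, the ICD
#' code-to-subtype map, the false-negative code vocabulary and the subgroup
#' switches.
#'
#' @param window_days Claims dated more than this many days after surgery are
#'   removed ("1 month" operationalized as 30 days, inclusive at the
#'   boundary).
#' @param study_start,study_end Study period (`Date` or ISO strings); claims
#'   outside it are removed.
#' @param bootstrap_reps Number of bootstrap resamples for confidence
#'   intervals (default 1000).
#' @param ci_level Confidence level, strictly between 0 and 1 (default 0.95).
#' @param rng_seed Integer seed for all randomized steps.
#' @param code_map Named list mapping an ICD code prefix to a character
#'   vector of subtypes (`"SE"`, `"OE"`, `"DE"`; `character(0)` for
#'   endometriosis not otherwise specified). See [default_code_map()].
#' @param unknown_race_to_woc If `TRUE` (default) participants with unknown
#'   race join the Women of Color stratum in the subgroup analysis; if
#'   `FALSE` they are excluded from the race contrast.
#' @param fn_vocab Named list mapping an error-analysis category to a vector
#'   of ICD code prefixes; see [default_fn_vocab()].
#' @return A `run_config` object (a validated list).
#' @seealso [load_config()]
#' @export
run_config <- function(window_days = 30L,
                       study_start = as.Date("2007-01-01"),
                       study_end = as.Date("2009-12-31"),
                       bootstrap_reps = 1000L,
                       ci_level = 0.95,
                       rng_seed = 20070101L,
                       code_map = default_code_map(),
                       unknown_race_to_woc = TRUE,
                       fn_vocab = default_fn_vocab()) {
  window_days <- as.integer(window_days)
  bootstrap_reps <- as.integer(bootstrap_reps)
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (is.na(window_days) || window_days <= 0L) stop("window_days must be a positive integer")
  if (is.na(bootstrap_reps) || bootstrap_reps <= 0L) stop("bootstrap_reps must be a positive integer")
  if (!is.numeric(ci_level) || is.na(ci_level) || ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must be strictly between 0 and 1")
  }
  if (is.na(study_start) || is.na(study_end) || study_start >= study_end) {
    stop("study_start must precede study_end")
  }
  validate_code_map(code_map)
  validate_fn_vocab(fn_vocab)
  structure(list(
    window_days = window_days, study_start = study_start,
    study_end = study_end, bootstrap_reps = bootstrap_reps,
    ci_level = ci_level, rng_seed = as.integer(rng_seed),
    code_map = code_map,
    unknown_race_to_woc = isTRUE(unknown_race_to_woc),
    fn_vocab = fn_vocab
  ), class = "run_config")
}

validate_code_map <- function(code_map) {
  if (!is.list(code_map)) stop("code_map must be a named list")
  if (length(code_map) && (is.null(names(code_map)) || any(!nzchar(names(code_map))))) {
    stop("code_map entries must be named by code prefix")
  }
  for (key in names(code_map)) {
    v <- code_map[[key]]
    if (!is.character(v) || any(!v %in% SUBTYPES)) {
      stop(sprintf("malformed code_map entry '%s': subtypes must be among %s (or empty for NOS)",
                   key, paste(SUBTYPES, collapse = ", ")))
    }
  }
  invisible(code_map)
}

validate_fn_vocab <- function(vocab) {
  if (!is.list(vocab)) stop("fn_vocab must be a named list of code-prefix vectors")
  if (length(vocab) && (is.null(names(vocab)) || any(!nzchar(names(vocab))))) {
    stop("fn_vocab categories must be named")
  }
  invisible(vocab)
}

#' Load a run configuration from a flat key/value file
#'
#' The format is a minimal YAML-like flat file: one `key: value` pair per
#' line, `#` comments and blank lines ignored, all keys optional. Scalar keys
#' are the arguments of [run_config()]. A code map is given as `map.<prefix>`
#' keys whose value is a comma-separated subtype list (`SE`, `OE`, `DE`) or
#' `NOS`; if any `map.*` key is present the default map is replaced entirely.
#' Likewise `vocab.<category>` keys (comma-separated code prefixes) replace
#' the default false-negative vocabulary.
#'
#' @param path Path to the config file.
#' @return A `run_config` with unspecified fields at their documented
#'   defaults.
#' @export
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("window_days: 30", "bootstrap_reps: 200",
#'              "map.617.1: OE", "map.N80.9: NOS"), cfg)
#' load_config(cfg)$bootstrap_reps
load_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  args <- list()
  map <- list()
  vocab <- list()
  for (line in lines) {
    m <- regmatches(line, regexec("^([^:]+):(.*)$", line))[[1L]]
    if (length(m) != 3L) stop(sprintf("malformed config line: '%s'", line))
    key <- trimws(m[2L])
    value <- trimws(m[3L])
    if (startsWith(key, "map.")) {
      prefix <- substring(key, 5L)
      subtypes <- toupper(trimws(strsplit(value, ",", fixed = TRUE)[[1L]]))
      if (identical(subtypes, "NOS")) subtypes <- character(0)
      if (any(!subtypes %in% SUBTYPES)) {
        stop(sprintf("malformed code_map entry '%s': '%s'", key, value))
      }
      map[[prefix]] <- subtypes
    } else if (startsWith(key, "vocab.")) {
      vocab[[substring(key, 7L)]] <- trimws(strsplit(value, ",", fixed = TRUE)[[1L]])
    } else {
      args[[key]] <- switch(key,
        window_days = , bootstrap_reps = , rng_seed = as.integer(value),
        ci_level = as.numeric(value),
        study_start = , study_end = {
          d <- parse_iso_date(value)
          if (is.na(d)) stop(sprintf("malformed date for '%s': '%s'", key, value))
          d
        },
        unknown_race_to_woc = {
          b <- parse_logical_strict(value)
          if (is.na(b)) stop(sprintf("malformed logical for '%s': '%s'", key, value))
          b
        },
        stop(sprintf("unknown config key '%s'", key))
      )
    }
  }
  if (length(map)) args$code_map <- map
  if (length(vocab)) args$fn_vocab <- vocab
  do.call(run_config, args)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat(sprintf("  study period   : %s .. %s\n", x$study_start, x$study_end))
  cat(sprintf("  claim window   : surgery + %d days (inclusive)\n", x$window_days))
  cat(sprintf("  bootstrap      : %d reps, %.0f%% percentile CI, seed %d\n",
              x$bootstrap_reps, 100 * x$ci_level, x$rng_seed))
  cat(sprintf("  code map       : %d prefixes\n", length(x$code_map)))
  cat(sprintf("  unknown race -> WoC stratum: %s\n", x$unknown_race_to_woc))
  invisible(x)
}
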