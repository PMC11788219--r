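# Internal helpers shared across modules.

SUBTYPES <- c("SE", "OE", "DE")
RASRM_STAGES <- c("I", "II", "III", "IV", "none")
LESION_SITES <- c("ovary", "peritoneum", "cul_de_sac")
DEPTH_CLASSES <- c("superficial", "deep")
RACE_GROUPS <- c("white", "woc", "unknown")
HISPANIC_LEVELS <- c("yes", "no", "missing")
CODE_SYSTEMS <- c("ICD9", "ICD10")
CLAIM_SOURCES <- c("inpatient", "ambulatory", "ehr")
COMPARISONS <- c("overall", SUBTYPES)

# Strict ISO-8601 calendar-date parser; returns Date, NA for anything that
# does not parse (including impossible months/days).
parse_iso_date <- function(x) {
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out <- rep(as.Date(NA), length(x))
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

parse_logical_strict <- function(x) {
  low <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[low %in% c("true", "t", "1")] <- TRUE
  out[low %in% c("false", "f", "0")] <- FALSE
  out
}

# Evaluate `code` under a temporary RNG state so package functions are
# reproducible without clobbering the caller's random stream.
with_rng_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Codes are compared case-insensitively with the dot optional
# ("N801" is equivalent to "N80.1").
normalize_code <- function(code) {
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_row <- function(file, row, msg) {
  stop(sprintf("%s: row %d: %s", file, row, msg), call. = FALSE)
}
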