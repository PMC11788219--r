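# Reference method: subtype classification from the rASRM lesion records.

#' Construct a subtype set
#'
#' A non-exclusive set of endometriosis subtypes: superficial (SE), ovarian
#' endometrioma (OE) and deep infiltrating (DE). `nos_only` marks an
#' administrative-side diagnosis whose codes carry no subtype information
#' (endometriosis not otherwise specified); it is never set on the surgical
#' reference side and is incompatible with any specific subtype.
#'
#' @param SE,OE,DE,nos_only Logical flags.
#' @return A `subtype_set` object.
#' @export
subtype_set <- function(SE = FALSE, OE = FALSE, DE = FALSE, nos_only = FALSE) {
  stopifnot(is.logical(SE), is.logical(OE), is.logical(DE), is.logical(nos_only))
  if (nos_only && (SE || OE || DE)) {
    stop("nos_only is incompatible with a specific subtype flag")
  }
  structure(list(SE = SE, OE = OE, DE = DE, nos_only = nos_only),
            class = "subtype_set")
}

#' @export
print.subtype_set <- function(x, ...) {
  flags <- SUBTYPES[unlist(x[SUBTYPES])]
  if (x$nos_only) flags <- "NOS"
  if (!length(flags)) flags <- "(none)"
  cat("subtype set: {", paste(flags, collapse = ", "), "}\n")
  invisible(x)
}

#' @export
format.subtype_set <- function(x, ...) {
  flags <- SUBTYPES[unlist(x[SUBTYPES])]
  if (x$nos_only) flags <- "NOS"
  paste(flags, collapse = "+")
}

#' Classify a surgically confirmed case into subtypes
#'
#' Applies the lesion-based typology rules to one surgical record:
#' \itemize{
#'   \item DE (deep infiltrating): any deep lesion of the peritoneum or
#'     cul-de-sac (>5 mm invasion), or obliteration of the posterior
#'     cul-de-sac.
#'   \item OE (ovarian endometrioma): any deep ovarian lesion, of any size.
#'   \item SE (superficial): only superficial lesions on the ovary or
#'     peritoneum — strictly exclusive, so a record with any DE/OE trigger
#'     reports `SE = FALSE` even when superficial lesions are also present.
#'   \item A case without lesion information (`lesion_info_available =
#'     FALSE`) is assumed SE, as is a degenerate confirmed case whose form
#'     records neither lesions nor obliteration.
#' }
#' Every confirmed case therefore receives a non-empty subtype set.
#' Superficial cul-de-sac lesions are treated as pelvic-peritoneum
#' superficial lesions (SE-eligible); only deep ones trigger DE.
#'
#' @param record A one-row `surgical_table` (or a list with fields
#'   `endometriosis_confirmed`, `lesions`, `culdesac_obliteration`,
#'   `lesion_info_available`). Must be a confirmed case.
#' @return A `subtype_set` with `nos_only = FALSE`.
#' @export
#' @examples
#' rec <- list(endometriosis_confirmed = TRUE, lesions = "ovary:deep|peritoneum:deep",
#'             culdesac_obliteration = FALSE, lesion_info_available = TRUE)
#' classify_surgical_subtypes(rec)  # OE + DE
classify_surgical_subtypes <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  if (!isTRUE(record$endometriosis_confirmed)) {
    stop("classify_surgical_subtypes() requires a surgically confirmed case")
  }
  if (!isTRUE(record$lesion_info_available)) {
    return(subtype_set(SE = TRUE))
  }
  les <- parse_lesions(record$lesions %||% "")
  deep <- les$depth_class == "deep"
  has_OE <- any(deep & les$site == "ovary")
  has_DE <- any(deep & les$site %in% c("peritoneum", "cul_de_sac")) ||
    isTRUE(record$culdesac_obliteration)
  has_SE <- !has_OE && !has_DE
  subtype_set(SE = has_SE, OE = has_OE, DE = has_DE)
}

#' Reference-method labels for a cohort
#'
#' Builds the per-participant reference label map: `overall` is the surgical
#' confirmation flag; the subtype flags come from
#' [classify_surgical_subtypes()] for cases and are all `FALSE` for
#' non-cases.
#'
#' @param records A `surgical_table`.
#' @return A data frame with columns `participant_id`, `overall`, `SE`,
#'   `OE`, `DE` (logical).
#' @export
reference_labels <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  out <- data.frame(
    participant_id = records$participant_id,
    overall = records$endometriosis_confirmed,
    SE = logical(n), OE = logical(n), DE = logical(n),
    stringsAsFactors = FALSE)
  for (i in which(records$endometriosis_confirmed)) {
    s <- classify_surgical_subtypes(records[i, , drop = FALSE])
    out$SE[i] <- s$SE
    out$OE[i] <- s$OE
    out$DE[i] <- s$DE
  }
  out
}
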