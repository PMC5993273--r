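#' Parse a string of repeated lead observations
#'
#' A focal animal's repeated side observations are recorded as a compact
#' string of `L` and `R` characters in chronological order (oldest first).
#' `parse_lead_sequence()` turns one such string into a character vector of
#' single leads, validating every symbol.
#'
#' @param text A single character string of `L`/`R` symbols (case
#'   insensitive). Whitespace is stripped before parsing.
#'
#' @return A character vector of `"L"`/`"R"` values, one per observation,
#'   in input order.
#'
#' @examples
#' parse_lead_sequence("RRLR")
#' length(parse_lead_sequence("RRRRLRRRRRLRLRRRRRLRRLRLRRLL"))
#' @export
parse_lead_sequence <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    abort("`text` must be a single character string.")
  }
  stripped <- gsub("\\s", "", text)
  if (nchar(stripped) == 0) {
    abort("empty sequence: no lead observations found.")
  }
  leads <- toupper(strsplit(stripped, "", fixed = TRUE)[[1]])
  bad <- which(!leads %in% c("L", "R"))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid lead symbol '%s' at position %d (only L and R are admitted).",
      leads[bad[1]], bad[1]
    ))
  }
  leads
}

#' Render a vector of leads back into a sequence string
#'
#' Inverse of [parse_lead_sequence()]: `parse -> render -> parse` is the
#' identity on valid sequences.
#'
#' @param leads Character vector of `"L"`/`"R"` values.
#' @return A single string.
#' @export
render_lead_sequence <- function(leads) {
  if (length(leads) == 0) abort("empty sequence: nothing to render.")
  if (!all(leads %in% c("L", "R"))) abort("leads must all be 'L' or 'R'.")
  paste(leads, collapse = "")
}

# Counts of L and R in a sequence string; used throughout.
count_leads <- function(sequence) {
  leads <- parse_lead_sequence(sequence)
  c(n_left = sum(leads == "L"), n_right = sum(leads == "R"))
}
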