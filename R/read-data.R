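#' Read a table of race-start observations
#'
#' Reads one-row-per-horse-per-start observation tables: which foreleg led
#' the first gallop stride out of the starting stalls, plus covariates.
#' The canonical schema has columns `race_id`, `direction` (`C` clockwise /
#' `AC` anti-clockwise), `horse_id`, `lead` (`L`/`R`), `stall_position`
#' (1 = nearest the inside rail), `age` (years), `sex`
#' (`mare`/`gelding`/`stallion`) and `finish_position`; `course_name` is
#' optional. Files using other column names or lead codes are accommodated
#' through `col_map` and `lead_map`.
#'
#' Rows are validated: leads must normalise to `L`/`R`, directions to
#' `C`/`AC`, and a `(race_id, stall_position)` pair may occur only once.
#' Rows failing numeric coercion are reported with their line numbers.
#'
#' @param source Path to a CSV file (or a connection readable by
#'   [readr::read_csv()]).
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(lead = "leading_leg")`.
#' @param lead_map Optional named character vector mapping raw lead codes to
#'   `"L"`/`"R"`, e.g. `c(left = "L", right = "R")`. Matching is case
#'   insensitive. By default `L`/`R` (any case) are accepted.
#'
#' @return A tibble of typed race-start observations with an added logical
#'   `is_winner` column (`finish_position == 1`).
#'
#' @seealso [deduplicate_horses()], [population_proportion_test()]
#' @export
read_race_starts <- function(source, col_map = NULL, lead_map = NULL) {
  raw <- readr::read_csv(source, show_col_types = FALSE,
                         progress = FALSE, col_types = readr::cols(.default = "c"))
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(raw)) {
        abort(sprintf("schema error: mapped column '%s' (for '%s') not found.",
                      col_map[[canon]], canon))
      }
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  required <- c("race_id", "direction", "horse_id", "lead",
                "stall_position", "age", "sex", "finish_position")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("schema error: missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (!"course_name" %in% names(raw)) raw$course_name <- NA_character_

  lead_raw <- tolower(trimws(raw$lead))
  if (is.null(lead_map)) {
    lead <- toupper(lead_raw)
  } else {
    lm <- setNames(toupper(lead_map), tolower(names(lead_map)))
    lead <- unname(lm[lead_raw])
    lead[is.na(lead)] <- toupper(lead_raw[is.na(lead)])
  }
  bad_lead <- which(!lead %in% c("L", "R"))
  if (length(bad_lead) > 0) {
    abort(sprintf("invalid lead value(s) on line(s) %s (after header).",
                  paste(head(bad_lead, 5), collapse = ", ")))
  }

  direction <- toupper(trimws(raw$direction))
  direction[direction %in% c("CLOCKWISE", "CW")] <- "C"
  direction[direction %in% c("ANTICLOCKWISE", "ANTI-CLOCKWISE", "ACW", "CCW")] <- "AC"
  bad_dir <- which(!direction %in% c("C", "AC"))
  if (length(bad_dir) > 0) {
    abort(sprintf("invalid direction value(s) on line(s) %s: expected C or AC.",
                  paste(head(bad_dir, 5), collapse = ", ")))
  }

  to_int <- function(x, what) {
    out <- suppressWarnings(as.integer(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad) > 0) {
      abort(sprintf("type error: non-integer %s on line(s) %s.",
                    what, paste(head(bad, 5), collapse = ", ")))
    }
    out
  }

  out <- tibble::tibble(
    race_id = as.character(raw$race_id),
    course_name = as.character(raw$course_name),
    direction = direction,
    horse_id = as.character(raw$horse_id),
    lead = lead,
    stall_position = to_int(raw$stall_position, "stall_position"),
    age = to_int(raw$age, "age"),
    sex = tolower(trimws(raw$sex)),
    finish_position = to_int(raw$finish_position, "finish_position")
  )
  bad_sex <- which(!out$sex %in% c("mare", "gelding", "stallion"))
  if (length(bad_sex) > 0) {
    abort(sprintf("invalid sex value(s) on line(s) %s: expected mare, gelding or stallion.",
                  paste(head(bad_sex, 5), collapse = ", ")))
  }
  dup <- duplicated(out[, c("race_id", "stall_position")])
  if (any(dup)) {
    abort(sprintf("integrity error: duplicate (race_id, stall_position) on line(s) %s.",
                  paste(head(which(dup), 5), collapse = ", ")))
  }
  out$is_winner <- out$finish_position == 1L
  out
}

#' Read focal-horse repeated-measures records
#'
#' Reads one-row-per-horse tables holding an identifier, the sex, and the
#' chronological string of repeated lead observations (see
#' [parse_lead_sequence()] for the sequence format).
#'
#' @param source Path to a CSV file with columns `horse_id`, `sex`,
#'   `sequence`.
#' @return A tibble with columns `horse_id`, `sex`, `sequence`.
#' @export
read_focal_records <- function(source) {
  raw <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("horse_id", "sex", "sequence")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("schema error: missing required column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  sex <- tolower(trimws(raw$sex))
  bad_sex <- which(!sex %in% c("mare", "gelding", "stallion"))
  if (length(bad_sex) > 0) {
    abort(sprintf("invalid sex value(s) on line(s) %s.",
                  paste(head(bad_sex, 5), collapse = ", ")))
  }
  # validate every sequence up front so failures carry the row number
  for (i in seq_len(nrow(raw))) {
    tryCatch(parse_lead_sequence(raw$sequence[i]),
             error = function(e) abort(sprintf("row %d: %s", i, conditionMessage(e))))
  }
  tibble::tibble(horse_id = as.character(raw$horse_id), sex = sex,
                 sequence = gsub("\\s", "", toupper(raw$sequence)))
}

#' Drop repeat observations of the same horse
#'
#' Population-level analyses use at most one race start per horse. For each
#' `horse_id` the chronologically first record (first in input order) is
#' kept. The operation is idempotent.
#'
#' @param starts A race-start tibble, as from [read_race_starts()].
#' @return The tibble restricted to each horse's first observation.
#' @export
deduplicate_horses <- function(starts) {
  if (!"horse_id" %in% names(starts)) abort("`starts` must have a horse_id column.")
  dplyr::distinct(starts, .data$horse_id, .keep_all = TRUE)
}

#' Focal-horse fixture: 44 racehorses with repeated gallop-lead observations
#'
#' Loads the embedded repeated-measures dataset of 44 Thoroughbred focal
#' horses (11 geldings `A`-`K`, 22 mares `L`-`AG`, 11 stallions `AH`-`AR`),
#' each with 5 to 47 chronological gallop leading-leg observations taken
#' from race videos. This is the dataset behind the per-horse laterality
#' table and all group-structure analyses.
#'
#' @return A tibble with columns `horse_id`, `sex`, `sequence`.
#' @examples
#' focal_horses()
#' @export
focal_horses <- function() {
  path <- system.file("extdata", "focal_horses.csv", package = "lateralize",
                      mustWork = TRUE)
  read_focal_records(path)
}
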