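#' Read a long-format table of clinician CTCAE toxicity records
#'
#' Expects a UTF-8 CSV with a header row and columns
#' `patient_id,arm,timepoint,domain,grade`. One row per patient, treatment
#' arm, assessment time point and symptom domain; `grade` is the CTCAE
#' grade 0-4 or empty for missing. Sentinel missing codes (9, 99, -1, ...)
#' are rejected, not silently treated as missing.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble with columns `patient_id` (character),
#'   `arm` (factor A/B), `timepoint` (factor mid/end), `domain` (factor),
#'   `grade` (integer 0-4 or `NA`).
#' @seealso [read_eortc()], [validate_ctcae()]
#' @export
read_ctcae <- function(path) {
  df <- read_long_csv(path, c("patient_id", "arm", "timepoint", "domain", "grade"))
  validate_ctcae(df)
}

#' Read a long-format table of patient EORTC item responses
#'
#' Expects a UTF-8 CSV with a header row and columns
#' `patient_id,timepoint,item_id,response`. One row per patient, time point
#' and questionnaire item; `response` is the 4-point Likert answer
#' (1 "not at all" ... 4 "very much") or empty for missing.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble with columns `patient_id`, `timepoint`,
#'   `item_id`, `response` (integer 1-4 or `NA`).
#' @export
read_eortc <- function(path) {
  df <- read_long_csv(path, c("patient_id", "timepoint", "item_id", "response"))
  validate_eortc(df)
}

read_long_csv <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  df[required]
}

parse_bounded_int <- function(x, lo, hi, what) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  num <- suppressWarnings(as.numeric(x))
  bad_fmt <- !is.na(x) & is.na(num)
  bad_int <- !is.na(num) & (num != round(num))
  bad_rng <- !is.na(num) & num == round(num) & (num < lo | num > hi)
  bad <- bad_fmt | bad_int | bad_rng
  if (any(bad)) {
    rows <- which(bad)
    abort(sprintf("invalid %s %s in row(s) %s (must be an integer in %d-%d or empty)",
                  what, paste(unique(x[bad]), collapse = ", "),
                  paste(head(rows, 5L), collapse = ", "), lo, hi))
  }
  as.integer(num)
}

assert_unique <- function(df, keys, what) {
  dup <- duplicated(df[keys])
  if (any(dup)) {
    abort(sprintf("duplicate %s record(s) for %s in row(s) %s",
                  what,
                  paste(do.call(paste, c(df[dup, keys, drop = FALSE], sep = "/")),
                        collapse = "; "),
                  paste(head(which(dup), 5L), collapse = ", ")))
  }
  invisible(df)
}

#' Validate an in-memory table of CTCAE records
#'
#' Applies the same contract as [read_ctcae()]: known arm / time point /
#' domain labels, grades as integers 0-4 or `NA`, and at most one record
#' per patient, time point and domain (duplicates are a hard error).
#'
#' @param df A data frame with columns `patient_id`, `arm`, `timepoint`,
#'   `domain`, `grade`.
#' @return The validated tibble with typed columns.
#' @export
validate_ctcae <- function(df) {
  df <- as_tibble(df)
  assert_known(as.character(df$arm), arm_levels(), "arm")
  assert_known(as.character(df$timepoint), timepoint_levels(), "timepoint")
  assert_known(as.character(df$domain), domain_levels(), "domain")
  out <- tibble::tibble(
    patient_id = as.character(df$patient_id),
    arm = factor(as.character(df$arm), levels = arm_levels()),
    timepoint = factor(as.character(df$timepoint), levels = timepoint_levels()),
    domain = factor(as.character(df$domain), levels = domain_levels()),
    grade = parse_bounded_int(df$grade, 0L, 4L, "CTCAE grade")
  )
  # keep any extra columns (e.g. country) for downstream stratification
  extras <- setdiff(names(df), names(out))
  if (length(extras)) out <- dplyr::bind_cols(out, df[extras])
  if (anyNA(out$patient_id) || any(trimws(out$patient_id) == "")) {
    abort("patient_id must be non-empty for every CTCAE record")
  }
  assert_unique(out, c("patient_id", "timepoint", "domain"), "CTCAE")
  out
}

#' Validate an in-memory table of EORTC item responses
#'
#' Same contract as [read_eortc()]: known item identifiers (see
#' [domain_items()]), responses as integers 1-4 or `NA`, one record per
#' patient, time point and item.
#'
#' @param df A data frame with columns `patient_id`, `timepoint`,
#'   `item_id`, `response`.
#' @return The validated tibble with typed columns.
#' @export
validate_eortc <- function(df) {
  df <- as_tibble(df)
  assert_known(as.character(df$timepoint), timepoint_levels(), "timepoint")
  assert_known(as.character(df$item_id), domain_items()$item_id, "item_id")
  out <- tibble::tibble(
    patient_id = as.character(df$patient_id),
    timepoint = factor(as.character(df$timepoint), levels = timepoint_levels()),
    item_id = as.character(df$item_id),
    response = parse_bounded_int(df$response, 1L, 4L, "EORTC response")
  )
  if (anyNA(out$patient_id) || any(trimws(out$patient_id) == "")) {
    abort("patient_id must be non-empty for every EORTC response")
  }
  assert_unique(out, c("patient_id", "timepoint", "item_id"), "EORTC")
  out
}

#' Write CTCAE records or EORTC responses back to CSV
#'
#' Inverse of the readers: missing grades/responses become empty cells so
#' that a write/read round trip reproduces the input exactly.
#'
#' @param df A validated tibble from [read_ctcae()] / [validate_ctcae()]
#'   (for `write_ctcae`) or [read_eortc()] / [validate_eortc()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ctcae <- function(df, path) {
  readr::write_csv(validate_ctcae(df), path, na = "")
  invisible(path)
}

#' @rdname write_ctcae
#' @export
write_eortc <- function(df, path) {
  readr::write_csv(validate_eortc(df), path, na = "")
  invisible(path)
}
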