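#' Severity of a single-item symptom scale
#'
#' Single EORTC symptom items are already on the four-level severity scale,
#' so scoring is the identity map 1..4 with missing passed through.
#'
#' @param response Integer vector of Likert responses 1-4 or `NA`.
#' @return Integer severity levels 1-4 (or `NA`).
#' @export
#' @examples
#' score_single_item(c(1L, 4L, NA))
score_single_item <- function(response) {
  bad <- !is.na(response) & !(response %in% 1:4)
  if (any(bad)) abort("single-item responses must be integers 1-4 or NA")
  as.integer(response)
}

#' Raw score of a multi-item symptom scale under the EORTC half-rule
#'
#' The raw scale score is the arithmetic mean of the answered items,
#' provided at least half of the scale's items were answered; otherwise the
#' score is missing. (Averaging the answered items is algebraically
#' identical to imputing each missing item with that mean and averaging all
#' items, which is the form the EORTC scoring manual states the rule in.)
#'
#' @param responses Numeric vector of one respondent's item answers
#'   (1-4 or `NA`), of length `n_items`.
#' @param n_items Number of items in the scale (2 for pain, 3 for fatigue).
#' @return A one-row tibble: `raw_mean` (in \[1,4\] or `NA`), `n_answered`,
#'   `n_items`.
#' @export
#' @examples
#' score_multi_item_scale(c(2, 3, 3), 3)   # fatigue, fully answered
#' score_multi_item_scale(c(2, NA), 2)     # pain, half-rule boundary
score_multi_item_scale <- function(responses, n_items) {
  if (length(responses) != n_items) {
    abort(sprintf("expected %d responses, got %d", n_items, length(responses)))
  }
  if (!(n_items %in% 2:3)) abort("multi-item scales here have 2 or 3 items")
  bad <- !is.na(responses) & !(responses %in% 1:4)
  if (any(bad)) abort("item responses must be 1-4 or NA")
  n_answered <- sum(!is.na(responses))
  raw_mean <- if (n_answered >= ceiling(n_items / 2)) mean(responses, na.rm = TRUE) else NA_real_
  tibble::tibble(raw_mean = raw_mean, n_answered = n_answered, n_items = as.integer(n_items))
}

#' Linear 0-100 transformation of a raw symptom-scale score
#'
#' Symptom scales are transformed so that raw mean 1 maps to 0 and raw
#' mean 4 maps to 100: `(raw - 1) / 3 * 100`. Missing propagates.
#'
#' @param raw_mean Numeric vector of raw means in \[1,4\] or `NA`.
#' @return Numeric vector of transformed scores in \[0,100\].
#' @export
#' @examples
#' transform_symptom_scale(c(1, 8 / 3, 4))
transform_symptom_scale <- function(raw_mean) {
  bad <- !is.na(raw_mean) & (raw_mean < 1 | raw_mean > 4)
  if (any(bad)) abort("raw scale means must lie in [1, 4]")
  (raw_mean - 1) / 3 * 100
}

#' Categorize a 0-100 symptom score into four severity levels
#'
#' Multi-item scale scores are mapped back onto the four-level severity
#' scale of the single items by assigning each score to the nearest of the
#' four anchor scores 0, 33.33, 66.67, 100 (the images of severities
#' 1-4). Midpoint ties -- which arise only for 2-item scales, at raw means
#' 1.5, 2.5, 3.5 -- go to the higher severity by default, conservatively
#' toward the patient-reported burden. Equivalently, the raw 1-4 mean is
#' rounded half-up to the nearest integer; the computation is carried out
#' on the raw-mean scale to avoid floating-point artifacts at the 0-100
#' midpoints.
#'
#' @param score Numeric vector of transformed scores in \[0,100\] or `NA`.
#' @param tie Direction for exact midpoint ties: `"higher"` (default) or
#'   `"lower"`.
#' @return Integer severity levels 1-4 (or `NA`).
#' @export
#' @examples
#' categorize_severity(c(0, 50, 55.56, 100))
categorize_severity <- function(score, tie = c("higher", "lower")) {
  tie <- match.arg(tie)
  bad <- !is.na(score) & (score < 0 | score > 100)
  if (any(bad)) abort("transformed scores must lie in [0, 100]")
  severity_from_raw_mean(score * 3 / 100 + 1, tie = tie)
}

# Round a raw 1-4 mean half-up (or half-down) to an integer severity.
# eps absorbs float error from the 0-100 round trip; attainable raw means
# are multiples of 1/6 so 1e-9 is far below the grid spacing.
severity_from_raw_mean <- function(raw_mean, tie = "higher") {
  eps <- 1e-9
  lev <- if (tie == "higher") floor(raw_mean + 0.5 + eps) else ceiling(raw_mean - 0.5 - eps)
  as.integer(pmin(4, pmax(1, lev)))
}

#' Per-patient EORTC symptom severities for every domain
#'
#' Scores validated item responses into one severity level 1-4 per patient,
#' time point and symptom domain: single items via the identity map,
#' multi-item scales (pain, fatigue) via the half-rule mean, 0-100
#' transformation and four-level categorization. Items never answered by a
#' patient at a time point count as missing for the half-rule.
#'
#' @param eortc A validated tibble of item responses
#'   ([read_eortc()] / [validate_eortc()]).
#' @param tie Tie direction passed to [categorize_severity()].
#' @return A tibble with columns `patient_id`, `timepoint`, `domain`,
#'   `severity` (integer 1-4 or `NA` when the half-rule fails).
#' @export
score_eortc <- function(eortc, tie = c("higher", "lower")) {
  tie <- match.arg(tie)
  eortc <- validate_eortc(eortc)
  items <- domain_items()
  doms <- symptom_domains()

  # complete the item grid per patient/timepoint so unanswered items are
  # explicit NAs (they count against the half-rule denominator)
  visits <- dplyr::distinct(eortc, .data$patient_id, .data$timepoint)
  full <- tidyr::crossing(visits, items) |>
    dplyr::left_join(eortc, by = c("patient_id", "timepoint", "item_id"))

  scored <- full |>
    dplyr::group_by(.data$patient_id, .data$timepoint, .data$domain) |>
    dplyr::summarise(
      n_items = dplyr::n(),
      n_answered = sum(!is.na(.data$response)),
      raw_mean = dplyr::if_else(
        .data$n_answered >= ceiling(.data$n_items / 2),
        mean(.data$response, na.rm = TRUE),
        NA_real_
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      severity = dplyr::if_else(
        is.na(.data$raw_mean), NA_integer_,
        severity_from_raw_mean(.data$raw_mean, tie = tie)
      ),
      domain = factor(.data$domain, levels = domain_levels())
    )

  scored |>
    dplyr::select("patient_id", "timepoint", "domain", "severity") |>
    dplyr::arrange(.data$patient_id, .data$timepoint, .data$domain)
}
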