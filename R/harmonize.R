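#' Collapse CTCAE grades onto the common four-level scale
#'
#' Grades 3 (severe) and 4 (life-threatening) are combined, giving the
#' collapsed scale 0-3 that pairs one-to-one with patient severities 1-4.
#'
#' @param grade Integer vector of CTCAE grades 0-4.
#' @return Integer vector of collapsed grades 0-3.
#' @export
#' @examples
#' collapse_ctcae_grade(0:4)
collapse_ctcae_grade <- function(grade) {
  bad <- !is.na(grade) & !(grade %in% 0:4)
  if (any(bad)) abort("CTCAE grades must be integers 0-4")
  as.integer(pmin(grade, 3L))
}

#' Classify matched clinician/patient pairs
#'
#' A pair is in *agreement* when it matches one of the four anchor pairs
#' (grade 0 with severity 1, 1 with 2, 2 with 3, and 3/4 combined with 4);
#' *underreport* when the clinician's collapsed grade sits below the
#' patient severity; *overestimate* when it sits above. Because the
#' comparison uses the collapsed grade, grade 4 versus severity 4 is
#' agreement, never overestimation.
#'
#' @param grade Integer vector of CTCAE grades 0-4 (no missing).
#' @param severity Integer vector of patient severities 1-4 (no missing).
#' @return A factor with levels `agreement`, `underreport`, `overestimate`.
#' @export
#' @examples
#' classify_concordance(c(2L, 0L, 3L, 1L), c(3L, 3L, 4L, 1L))
classify_concordance <- function(grade, severity) {
  check_pair(grade, severity)
  g <- collapse_ctcae_grade(grade)
  cls <- dplyr::case_when(
    severity == g + 1L ~ "agreement",
    severity >  g + 1L ~ "underreport",
    TRUE               ~ "overestimate"
  )
  factor(cls, levels = c("agreement", "underreport", "overestimate"))
}

#' Binary any-versus-none recoding of matched pairs
#'
#' Recodes CTCAE as none (grade 0) versus any grade (>= 1), and patient
#' severity as none (1, "not at all") versus any (2-4), and classifies each
#' pair into the 2x2 cells "reported by neither", "reported only by
#' clinician", "reported only by patient", "reported by both".
#'
#' @inheritParams classify_concordance
#' @return A tibble with logical columns `clinician_any`, `patient_any` and
#'   a factor `cell` with levels `neither`, `clinician_only`,
#'   `patient_only`, `both`.
#' @export
#' @examples
#' binarize_pair(c(0L, 1L, 0L, 2L), c(1L, 1L, 4L, 3L))
binarize_pair <- function(grade, severity) {
  check_pair(grade, severity)
  clinician_any <- grade >= 1L
  patient_any <- severity >= 2L
  cell <- dplyr::case_when(
    !clinician_any & !patient_any ~ "neither",
    clinician_any & !patient_any ~ "clinician_only",
    !clinician_any & patient_any ~ "patient_only",
    TRUE ~ "both"
  )
  tibble::tibble(
    clinician_any = clinician_any,
    patient_any = patient_any,
    cell = factor(cell, levels = c("neither", "clinician_only", "patient_only", "both"))
  )
}

check_pair <- function(grade, severity) {
  if (length(grade) != length(severity)) abort("grade and severity must have equal length")
  if (anyNA(grade) || anyNA(severity)) abort("matched pairs must be complete (no NA)")
  if (any(!(grade %in% 0:4))) abort("CTCAE grades must be integers 0-4")
  if (any(!(severity %in% 1:4))) abort("patient severities must be integers 1-4")
  invisible(NULL)
}

#' Match clinician records with patient severities
#'
#' Joins CTCAE records with scored EORTC severities on patient, time point
#' and domain, keeping only pairwise-complete pairs (both the grade and the
#' severity present). Deletion is pairwise per domain, so the matched `n`
#' differs across domains within the same arm and time point.
#'
#' @param ctcae A validated CTCAE tibble ([read_ctcae()]).
#' @param severities A severity tibble from [score_eortc()].
#' @return A tibble of matched observations: `patient_id`, `arm`,
#'   `timepoint`, `domain`, `ctcae_grade`, `eortc_severity`, plus the
#'   derived `concordance` class and binary `cell`.
#' @export
match_observations <- function(ctcae, severities) {
  ctcae <- validate_ctcae(ctcae)
  matched <- ctcae |>
    dplyr::inner_join(severities, by = c("patient_id", "timepoint", "domain")) |>
    dplyr::filter(!is.na(.data$grade), !is.na(.data$severity)) |>
    dplyr::rename(ctcae_grade = "grade", eortc_severity = "severity")
  matched |>
    dplyr::mutate(
      concordance = classify_concordance(.data$ctcae_grade, .data$eortc_severity),
      cell = binarize_pair(.data$ctcae_grade, .data$eortc_severity)$cell
    ) |>
    dplyr::arrange(.data$arm, .data$timepoint, .data$domain, .data$patient_id)
}
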