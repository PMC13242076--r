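#' Symptom domains shared by CTCAE grading and the EORTC questionnaires
#'
#' The six symptomatic adverse-event domains with direct conceptual overlap
#' between clinician CTCAE grading and patient-reported EORTC QLQ-C30/BR23
#' items: diarrhea, nausea, vomiting, mucositis (assessed via the dry-mouth
#' item), pain (2 items) and fatigue (3 items). Pain and fatigue are
#' multi-item symptom scales; the other four are single items.
#'
#' @return A tibble with one row per domain: `domain` (character),
#'   `n_items` (integer), `multi_item` (logical), and `ctcae_term`
#'   (the matching CTCAE toxicity term).
#' @seealso [domain_items()] for the item-level map.
#' @export
#' @examples
#' symptom_domains()
symptom_domains <- function() {
  tibble::tibble(
    domain = c("diarrhea", "nausea", "vomiting", "mucositis", "pain", "fatigue"),
    n_items = c(1L, 1L, 1L, 1L, 2L, 3L),
    multi_item = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    ctcae_term = c("diarrhea", "nausea", "vomiting", "mucositis", "pain", "fatigue")
  )
}

#' Map of EORTC items to symptom domains
#'
#' One row per questionnaire item used in the concordance analysis. Item
#' identifiers name the question content: `pain` / `pain_interference` for
#' the two pain items, `rest` / `weak` / `tired` for the three fatigue
#' items, and `dry_mouth` for the mucositis proxy.
#'
#' @return A tibble with columns `domain` and `item_id`.
#' @export
#' @examples
#' domain_items()
domain_items <- function() {
  tibble::tibble(
    domain = c("diarrhea", "nausea", "vomiting", "mucositis",
               "pain", "pain", "fatigue", "fatigue", "fatigue"),
    item_id = c("diarrhea", "nausea", "vomiting", "dry_mouth",
                "pain", "pain_interference", "rest", "weak", "tired")
  )
}

domain_levels <- function() symptom_domains()$domain
arm_levels <- function() c("A", "B")
timepoint_levels <- function() c("mid", "end")

assert_known <- function(x, allowed, what) {
  bad <- !is.na(x) & !(x %in% allowed)
  if (any(bad)) {
    rows <- which(bad)
    abort(sprintf(
      "unknown %s %s in row(s) %s; allowed: %s",
      what, paste(unique(x[bad]), collapse = ", "),
      paste(head(rows, 5L), collapse = ", "),
      paste(allowed, collapse = ", ")
    ))
  }
  invisible(x)
}
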