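#' Published binary concordance counts from the PANTHER trial analysis
#'
#' The 2 x 2 any-versus-none cross-classification of clinician-reported
#' CTCAE toxicity against patient-reported EORTC symptom severity, as
#' published for the PANTHER adjuvant breast-cancer trial: one row per
#' treatment arm (A tailored dose-dense, B standard-interval), time point
#' and symptom domain, with the four cell counts ("reported by neither",
#' "only by clinician", "only by patient", "by both"), the matched `n`,
#' and the reported unweighted Cohen's kappa (2 dp). Useful for verifying
#' that [cohen_kappa()] reproduces the reported coefficients from the
#' reported counts.
#'
#' @return A tibble with 24 rows.
#' @export
#' @examples
#' counts <- published_binary_concordance()
#' row <- counts[1, ]
#' cohen_kappa(binary_table(row$neither, row$clinician_only,
#'                          row$patient_only, row$both), "unweighted")
published_binary_concordance <- function() {
  path <- system.file("extdata", "published_binary_concordance.csv",
                      package = "toxconcord", mustWork = TRUE)
  readr::read_csv(path, col_types = "ccciiiiid", progress = FALSE)
}
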