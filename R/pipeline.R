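#' Analysis configuration
#'
#' Options controlling a full concordance analysis run.
#'
#' @param alpha Significance threshold for the predominance tests
#'   (default 0.004, a Bonferroni allowance for the 12 symptom-by-time
#'   strata of a six-domain, two-time-point design).
#' @param extra_strata Extra grouping columns (e.g. `"country"`) present
#'   in the CTCAE table, applied on top of arm and time point.
#' @param change_type Which discordance the mid-to-end change tracks:
#'   `"underreport"` (default) or `"any"`.
#' @param mcnemar McNemar variant, see [mcnemar_paired_change()].
#' @param tie Tie direction for severity categorization, see
#'   [categorize_severity()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.004, extra_strata = character(),
                            change_type = c("underreport", "any"),
                            mcnemar = c("auto", "cc", "exact"),
                            tie = c("higher", "lower")) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1)) {
    abort("alpha must be a single number in (0, 1)")
  }
  structure(
    list(alpha = alpha, extra_strata = extra_strata,
         change_type = match.arg(change_type), mcnemar = match.arg(mcnemar),
         tie = match.arg(tie)),
    class = "analysis_config"
  )
}

strata_cols <- function(config, with_time = TRUE) {
  c("arm", if (with_time) "timepoint", config$extra_strata, "domain")
}

#' Four-level agreement table (weighted kappa per stratum)
#'
#' One row per arm, time point and domain (plus any extra strata): the
#' matched `n`, the quadratic-weighted Cohen's kappa (2 dp), its
#' asymptotic null p-value and interpretation band. Strata with
#' degenerate margins get `NA` kappa.
#'
#' @param matched Matched observations from [match_observations()].
#' @param config An [analysis_config()].
#' @return A tibble.
#' @export
agreement_table <- function(matched, config = analysis_config()) {
  matched |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata_cols(config)))) |>
    dplyr::group_modify(function(df, key) {
      res <- tryCatch(
        cohen_kappa(build_contingency_table(df, "ordinal4"), "quadratic"),
        error = function(e) NULL
      )
      if (is.null(res)) {
        tibble::tibble(n = nrow(df), kappa = NA_real_, p_value = NA_real_,
                       label = NA_character_)
      } else {
        tibble::tibble(n = res$n, kappa = round(res$kappa, 2),
                       p_value = res$p_value, label = res$label)
      }
    }) |>
    dplyr::ungroup()
}

#' Binary concordance table (2 x 2 cells and unweighted kappa per stratum)
#'
#' One row per stratum with the four any-versus-none cells as counts and
#' percentages (1 dp) of the stratum-specific matched `n`, and the
#' unweighted kappa (2 dp).
#'
#' @inheritParams agreement_table
#' @return A tibble.
#' @export
binary_concordance_table <- function(matched, config = analysis_config()) {
  matched |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata_cols(config)))) |>
    dplyr::group_modify(function(df, key) binary_concordance_summary(df)) |>
    dplyr::ungroup()
}

#' Underreport-rate matrix (heatmap analog)
#'
#' Per stratum: the matched `n`, counts of agreement / underreport /
#' overestimate on the four-level scale, and the underreport and
#' overestimate percentages (1 dp).
#'
#' @inheritParams agreement_table
#' @return A tibble.
#' @export
underreport_table <- function(matched, config = analysis_config()) {
  matched |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata_cols(config)))) |>
    dplyr::group_modify(function(df, key) discordance_summary(df)) |>
    dplyr::ungroup() |>
    dplyr::mutate(pct_under = round(100 * .data$rate_under, 1),
                  pct_over = round(100 * .data$rate_over, 1))
}

#' Mid-to-end change in discordance per arm and domain
#'
#' Restricted to patients with complete pairs at both time points within
#' each arm and domain: discordance rates at mid and end, the change in
#' percentage points, and the McNemar test.
#'
#' @inheritParams agreement_table
#' @return A tibble.
#' @export
change_table <- function(matched, config = analysis_config()) {
  matched |>
    dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(strata_cols(config), "timepoint")))) |>
    dplyr::group_modify(function(df, key) {
      mid <- dplyr::filter(df, .data$timepoint == "mid")
      end <- dplyr::filter(df, .data$timepoint == "end")
      if (nrow(mid) == 0L || nrow(end) == 0L ||
          !any(mid$patient_id %in% end$patient_id)) {
        return(tibble::tibble(n_paired = 0L, rate_mid = NA_real_, rate_end = NA_real_,
                              delta_pct = NA_real_, b = NA_integer_, c = NA_integer_,
                              statistic = NA_real_, p_value = NA_real_,
                              method = "no_overlap"))
      }
      discordance_change(mid, end, type = config$change_type, method = config$mcnemar)
    }) |>
    dplyr::ungroup()
}

#' Predominance of clinician underreporting per stratum
#'
#' The exact binomial test on discordant pairs in every stratum; strata
#' without discordant pairs are flagged rather than dropped.
#'
#' @inheritParams agreement_table
#' @return A tibble.
#' @export
predominance_table <- function(matched, config = analysis_config()) {
  matched |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata_cols(config)))) |>
    dplyr::group_modify(function(df, key) {
      s <- discordance_summary(df)
      if (s$n_under + s$n_over == 0L) {
        return(tibble::tibble(n_discordant = 0L, prop_under = NA_real_,
                              p_value = NA_real_, significant = NA,
                              alpha = config$alpha))
      }
      exact_binomial_predominance(s$n_under, s$n_over, alpha = config$alpha)
    }) |>
    dplyr::ungroup()
}

#' Between-arm comparison of underreport rates
#'
#' Two-sample pooled-variance z-tests comparing the underreport
#' proportion between the arms within each domain and time point.
#'
#' @inheritParams agreement_table
#' @return A tibble with one row per domain and time point.
#' @export
arm_comparison_table <- function(matched, config = analysis_config()) {
  rates <- matched |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata_cols(config)))) |>
    dplyr::group_modify(function(df, key) discordance_summary(df)) |>
    dplyr::ungroup()
  wide <- rates |>
    dplyr::select(dplyr::all_of(strata_cols(config)), "n", "n_under") |>
    tidyr::pivot_wider(names_from = "arm", values_from = c("n", "n_under"))
  for (col in c("n_A", "n_B", "n_under_A", "n_under_B")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_integer_
  }
  wide |>
    dplyr::rowwise() |>
    dplyr::mutate(
      if (anyNA(c(.data$n_A, .data$n_B))) {
        tibble::tibble(estimate1 = NA_real_, estimate2 = NA_real_, z = NA_real_,
                       p_value = NA_real_, degenerate = NA)
      } else {
        two_proportion_test(.data$n_under_A, .data$n_A, .data$n_under_B, .data$n_B)
      }
    ) |>
    dplyr::ungroup()
}

#' Run the full concordance analysis
#'
#' Orchestrates scoring, matching, harmonization and all agreement and
#' discordance statistics: EORTC responses are scored into four-level
#' severities, joined with CTCAE grades into pairwise-complete matched
#' observations, and summarized per arm, time point and domain. The
#' output is deterministic for fixed inputs.
#'
#' @param ctcae CTCAE records: a file path (see [read_ctcae()]) or a
#'   data frame ([validate_ctcae()]).
#' @param eortc EORTC responses: a file path or data frame.
#' @param config An [analysis_config()].
#' @return An object of class `report_bundle`: tibbles `agreement`,
#'   `binary`, `underreport`, `change`, `predominance`,
#'   `arm_comparison`, the `matched` observations, and a `manifest`.
#' @export
#' @examples
#' cohort <- generate_cohort(trial_config(n_per_arm = 60, seed = 7))
#' bundle <- run_analysis(cohort$ctcae, cohort$eortc)
#' bundle$agreement
run_analysis <- function(ctcae, eortc, config = analysis_config()) {
  ctcae <- if (is.character(ctcae)) read_ctcae(ctcae) else validate_ctcae(ctcae)
  eortc <- if (is.character(eortc)) read_eortc(eortc) else validate_eortc(eortc)
  severities <- score_eortc(eortc, tie = config$tie)
  matched <- match_observations(ctcae, severities)
  if (nrow(matched) == 0L) abort("no matched clinician-patient pairs after scoring")

  bundle <- list(
    agreement = agreement_table(matched, config),
    binary = binary_concordance_table(matched, config),
    underreport = underreport_table(matched, config),
    change = change_table(matched, config),
    predominance = predominance_table(matched, config),
    arm_comparison = arm_comparison_table(matched, config),
    matched = matched,
    manifest = tibble::tibble(
      package = "toxconcord",
      version = as.character(utils::packageVersion("toxconcord")),
      alpha = config$alpha,
      change_type = config$change_type,
      n_ctcae = nrow(ctcae),
      n_eortc = nrow(eortc),
      n_matched = nrow(matched),
      input_hash = rlang::hash(list(ctcae, eortc, unclass(config)))
    )
  )
  structure(bundle, class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("concordance report bundle: %d matched pairs across %d strata\n",
              x$manifest$n_matched, nrow(x$agreement)))
  cat(sprintf("  weighted kappa range: %.2f to %.2f\n",
              min(x$agreement$kappa, na.rm = TRUE), max(x$agreement$kappa, na.rm = TRUE)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits every table of the bundle as CSV and/or JSON into `dir`, plus
#' `manifest.json`. Output is byte-identical across runs on identical
#' inputs.
#'
#' @param bundle A `report_bundle` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json")`.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir, formats = c("csv", "json")) {
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("agreement", "binary", "underreport", "change",
              "predominance", "arm_comparison", "matched")
  for (nm in tables) {
    if ("csv" %in% formats) {
      readr::write_csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")), na = "")
    }
    if ("json" %in% formats) {
      jsonlite::write_json(bundle[[nm]], file.path(dir, paste0(nm, ".json")),
                           dataframe = "rows", na = "null", digits = NA, pretty = TRUE)
    }
  }
  jsonlite::write_json(as.list(bundle$manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
tidy.report_bundle <- function(x, ...) x$agreement

#' @export
glance.report_bundle <- function(x, ...) {
  tibble::tibble(
    n_matched = x$manifest$n_matched,
    n_strata = nrow(x$agreement),
    kappa_min = min(x$agreement$kappa, na.rm = TRUE),
    kappa_max = max(x$agreement$kappa, na.rm = TRUE),
    rate_under = sum(x$underreport$n_under) / sum(x$underreport$n),
    rate_over = sum(x$underreport$n_over) / sum(x$underreport$n)
  )
}
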