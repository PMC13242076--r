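#' Heatmap of clinician underreport rates
#'
#' Tile plot of the percentage of matched pairs in which the clinician
#' graded below the patient-reported severity, by domain (rows) and
#' arm-by-time-point stratum (columns).
#'
#' @param underreport A tibble from [underreport_table()] (or the
#'   `underreport` element of a [run_analysis()] bundle).
#' @return A ggplot object.
#' @export
plot_underreport_matrix <- function(underreport) {
  underreport |>
    dplyr::mutate(stratum = paste0("arm ", .data$arm, ", ", .data$timepoint)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$stratum, y = .data$domain,
                                 fill = .data$pct_under)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$pct_under)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "#fff5f0", high = "#a50f15",
                                 name = "% underreport") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Clinician underreporting of patient-reported symptoms") +
    ggplot2::theme_minimal()
}

#' Bar chart of the mid-to-end change in discordance
#'
#' Percentage-point change in the discordance rate from mid- to
#' end-of-treatment per domain and arm, computed on patients with paired
#' data; bars above zero indicate increasing clinician underreporting,
#' asterisks mark McNemar p below the given threshold.
#'
#' @param change A tibble from [change_table()].
#' @param alpha Threshold for the significance marker (default 0.05).
#' @return A ggplot object.
#' @export
plot_discordance_change <- function(change, alpha = 0.05) {
  change |>
    dplyr::mutate(sig = dplyr::if_else(!is.na(.data$p_value) & .data$p_value < alpha,
                                       "*", "")) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$domain, y = .data$delta_pct,
                                 fill = .data$arm)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig,
                                    group = .data$arm),
                       position = ggplot2::position_dodge(width = 0.8),
                       vjust = -0.2, size = 5) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Change in discordance (percentage points)",
                  fill = "Arm",
                  title = "Change in discordance from mid- to end-of-treatment") +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
autoplot.report_bundle <- function(object, which = c("underreport", "change"), ...) {
  which <- match.arg(which)
  if (which == "underreport") plot_underreport_matrix(object$underreport)
  else plot_discordance_change(object$change, ...)
}
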