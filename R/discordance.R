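#' Summarize discordance in a set of matched pairs
#'
#' Counts agreement, clinician underreport and clinician overestimate
#' among matched pairs, with rates on the matched `n`.
#'
#' @param pairs A tibble of matched observations (with `ctcae_grade` and
#'   `eortc_severity`).
#' @return A one-row tibble: `n`, `n_agree`, `n_under`, `n_over`,
#'   `rate_under`, `rate_over`.
#' @export
discordance_summary <- function(pairs) {
  if (nrow(pairs) == 0L) abort("no matched pairs to summarize")
  cls <- classify_concordance(pairs$ctcae_grade, pairs$eortc_severity)
  n <- length(cls)
  tibble::tibble(
    n = n,
    n_agree = sum(cls == "agreement"),
    n_under = sum(cls == "underreport"),
    n_over = sum(cls == "overestimate"),
    rate_under = .data$n_under / n,
    rate_over = .data$n_over / n
  )
}

#' Exact binomial test for predominance of clinician underreporting
#'
#' Among the discordant pairs only, tests `H0: P(underreport) = 0.5`
#' against the two-sided alternative with the exact binomial test
#' (two-sided p as the total probability of all outcomes no more likely
#' than the observed one). The default significance threshold of 0.004
#' reflects a Bonferroni allowance for the twelve symptom-by-time strata
#' in a two-arm, two-time-point, six-domain analysis; override `alpha` for
#' other designs.
#'
#' @param n_under,n_over Counts of underreporting and overestimating pairs.
#' @param alpha Significance threshold (default 0.004).
#' @return A one-row tibble: `n_discordant`, `prop_under`, `p_value`,
#'   `significant`, `alpha`.
#' @export
#' @examples
#' exact_binomial_predominance(10, 0)
exact_binomial_predominance <- function(n_under, n_over, alpha = 0.004) {
  if (n_under < 0 || n_over < 0) abort("counts must be non-negative")
  n <- n_under + n_over
  if (n < 1) abort("at least one discordant pair is required")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1)")
  p <- binom.test(n_under, n, p = 0.5)$p.value
  tibble::tibble(
    n_discordant = as.integer(n),
    prop_under = n_under / n,
    p_value = p,
    significant = p < alpha,
    alpha = alpha
  )
}

#' McNemar test for a paired change in discordance status
#'
#' Tests whether the probability of being discordant changes between two
#' occasions, using only patients observed at both. With switch counts
#' `b` (discordant at the first occasion only) and `c` (second only), the
#' continuity-corrected chi-square statistic is
#' `(|b - c| - 1)^2 / (b + c)` on 1 df. For few switchers (`b + c < 25`)
#' the exact binomial version of the test is used instead (the default
#' `method = "auto"`); both variants are selectable explicitly.
#'
#' @param paired A tibble with logical columns `discordant_mid` and
#'   `discordant_end`, one row per patient with complete pairs at both
#'   time points.
#' @param method `"auto"` (exact when `b + c < 25`), `"cc"`
#'   (continuity-corrected chi-square), or `"exact"`.
#' @return A one-row tibble: `b`, `c`, `statistic` (`NA` for the exact
#'   variant), `p_value`, `method`, `degenerate` (`TRUE` when `b + c = 0`,
#'   where `p = 1`).
#' @export
mcnemar_paired_change <- function(paired, method = c("auto", "cc", "exact")) {
  method <- match.arg(method)
  if (anyNA(paired$discordant_mid) || anyNA(paired$discordant_end)) {
    abort("paired statuses must be complete; restrict to patients with both time points")
  }
  b <- sum(paired$discordant_mid & !paired$discordant_end)
  cc <- sum(!paired$discordant_mid & paired$discordant_end)
  if (b + cc == 0L) {
    return(tibble::tibble(b = b, c = cc, statistic = NA_real_, p_value = 1,
                          method = "degenerate", degenerate = TRUE))
  }
  use_exact <- method == "exact" || (method == "auto" && (b + cc) < 25)
  if (use_exact) {
    p <- binom.test(b, b + cc, p = 0.5)$p.value
    tibble::tibble(b = b, c = cc, statistic = NA_real_, p_value = p,
                   method = "exact", degenerate = FALSE)
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    tibble::tibble(b = b, c = cc, statistic = stat, p_value = p,
                   method = "cc", degenerate = FALSE)
  }
}

#' Two-sample test for proportions (pooled z)
#'
#' Compares `x1/n1` with `x2/n2` using the pooled-variance z statistic
#' without continuity correction, so that `z^2` equals the Pearson
#' chi-square of the 2 x 2 table exactly; a Yates-corrected variant is
#' available via `correct = TRUE`.
#'
#' @param x1,n1,x2,n2 Successes and totals in the two groups.
#' @param correct Apply the continuity correction? (default `FALSE`)
#' @return A one-row tibble: `estimate1`, `estimate2`, `z`, `p_value`,
#'   `degenerate` (`TRUE` with `p = 1` when the pooled proportion is 0
#'   or 1).
#' @export
two_proportion_test <- function(x1, n1, x2, n2, correct = FALSE) {
  if (n1 < 1 || n2 < 1) abort("group sizes must be at least 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) abort("successes must lie in [0, n]")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) {
    return(tibble::tibble(estimate1 = p1, estimate2 = p2, z = 0, p_value = 1,
                          degenerate = TRUE))
  }
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  diff <- p1 - p2
  if (correct) {
    adj <- min(abs(diff), 0.5 * (1 / n1 + 1 / n2))
    diff <- sign(diff) * (abs(diff) - adj)
  }
  z <- diff / se
  tibble::tibble(estimate1 = p1, estimate2 = p2, z = z,
                 p_value = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Paired discordance status at the two assessment time points
#'
#' Restricts to patients with complete matched pairs at both mid- and
#' end-of-treatment and records whether each was discordant at each time
#' point. `type = "underreport"` (default) counts only pairs where the
#' clinician graded below the patient; `"any"` counts any disagreement.
#'
#' @param mid_pairs,end_pairs Matched observations at the two time points
#'   for one stratum (one arm and domain).
#' @param type `"underreport"` or `"any"`.
#' @return A tibble: `patient_id`, `discordant_mid`, `discordant_end`.
#' @export
paired_discordance <- function(mid_pairs, end_pairs, type = c("underreport", "any")) {
  type <- match.arg(type)
  flag <- function(df) {
    cls <- classify_concordance(df$ctcae_grade, df$eortc_severity)
    if (type == "underreport") cls == "underreport" else cls != "agreement"
  }
  mid <- tibble::tibble(patient_id = mid_pairs$patient_id, discordant_mid = flag(mid_pairs))
  end <- tibble::tibble(patient_id = end_pairs$patient_id, discordant_end = flag(end_pairs))
  dplyr::inner_join(mid, end, by = "patient_id")
}

#' Change in discordance from mid- to end-of-treatment
#'
#' Computes, on the paired subset (patients with complete pairs at both
#' time points), the discordance rate at each time point, the change in
#' percentage points (positive when discordance increases toward the end
#' of treatment), and the McNemar test of the change. Both the rates and
#' the test use the paired subset.
#'
#' @inheritParams paired_discordance
#' @param method McNemar variant, see [mcnemar_paired_change()].
#' @return A one-row tibble: `n_paired`, `rate_mid`, `rate_end`,
#'   `delta_pct` (percentage points), `b`, `c`, `statistic`, `p_value`,
#'   `method`.
#' @export
discordance_change <- function(mid_pairs, end_pairs, type = c("underreport", "any"),
                               method = c("auto", "cc", "exact")) {
  paired <- paired_discordance(mid_pairs, end_pairs, type = type)
  if (nrow(paired) == 0L) abort("no patients with matched pairs at both time points")
  mc <- mcnemar_paired_change(paired, method = method)
  rate_mid <- mean(paired$discordant_mid)
  rate_end <- mean(paired$discordant_end)
  tibble::tibble(
    n_paired = nrow(paired),
    rate_mid = rate_mid,
    rate_end = rate_end,
    delta_pct = 100 * (rate_end - rate_mid),
    b = mc$b, c = mc$c, statistic = mc$statistic,
    p_value = mc$p_value, method = mc$method
  )
}
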