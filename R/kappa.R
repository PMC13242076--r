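#' Cross-classify matched pairs into a contingency table
#'
#' Builds the k x k table of clinician level (rows) by patient level
#' (columns). In `ordinal4` mode the collapsed grade 0-3 is crossed with
#' severity 1-4, aligned so that the diagonal holds the four agreement
#' pairs; in `binary` mode the any-versus-none recoding gives a 2 x 2
#' table whose off-diagonal cells are "clinician only" and "patient only".
#'
#' @param pairs A tibble of matched observations with columns
#'   `ctcae_grade` and `eortc_severity` (see [match_observations()]).
#' @param mode `"ordinal4"` or `"binary"`.
#' @return An integer matrix with class `concordance_table`, dimnames
#'   naming the clinician and patient levels, and attribute `n`.
#' @export
build_contingency_table <- function(pairs, mode = c("ordinal4", "binary")) {
  mode <- match.arg(mode)
  if (nrow(pairs) == 0L) abort("cannot build a contingency table from zero matched pairs")
  check_pair(pairs$ctcae_grade, pairs$eortc_severity)
  if (mode == "ordinal4") {
    g <- factor(collapse_ctcae_grade(pairs$ctcae_grade), levels = 0:3)
    s <- factor(pairs$eortc_severity, levels = 1:4)
    counts <- table(clinician = g, patient = s)
  } else {
    b <- binarize_pair(pairs$ctcae_grade, pairs$eortc_severity)
    counts <- table(
      clinician = factor(ifelse(b$clinician_any, "any", "none"), levels = c("none", "any")),
      patient = factor(ifelse(b$patient_any, "any", "none"), levels = c("none", "any"))
    )
  }
  new_concordance_table(unclass(counts))
}

new_concordance_table <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  structure(m, class = c("concordance_table", "matrix", "array"), n = sum(m))
}

#' Build a 2 x 2 concordance table directly from the four cell counts
#'
#' Convenience constructor for published binary concordance tables, taking
#' the cells in the order they are usually reported.
#'
#' @param neither,clinician_only,patient_only,both Non-negative counts.
#' @return A `concordance_table` (see [build_contingency_table()]).
#' @export
#' @examples
#' binary_table(495, 27, 95, 49)
binary_table <- function(neither, clinician_only, patient_only, both) {
  m <- matrix(c(neither, patient_only, clinician_only, both), nrow = 2, byrow = TRUE,
              dimnames = list(clinician = c("none", "any"), patient = c("none", "any")))
  new_concordance_table(m)
}

kappa_weights <- function(k, scheme) {
  idx <- seq_len(k) - 1
  if (scheme == "unweighted") {
    1 - diag(k)
  } else {
    outer(idx, idx, function(i, j) (i - j)^2) / (k - 1)^2
  }
}

#' Cohen's kappa for a concordance table
#'
#' Chance-corrected agreement in disagreement-weight form:
#' `kappa = 1 - sum(d * o) / sum(d * e)`, with observed cell proportions
#' `o`, expected-under-independence proportions `e`, and disagreement
#' weights `d` that are 0/1 for the unweighted statistic or
#' `(i - j)^2 / (k - 1)^2` for quadratic weights. On a 2 x 2 table the two
#' schemes coincide exactly. The p-value tests `H0: kappa = 0` with the
#' large-sample standard error of weighted kappa under the null
#' (Fleiss-Cohen-Everitt) against a normal reference, two-sided.
#'
#' @param table A `concordance_table` or plain square count matrix.
#' @param scheme `"quadratic"` (default, the four-level analysis) or
#'   `"unweighted"` (the binary analysis).
#' @param p_value Compute the asymptotic null p-value? (`TRUE` by default.)
#' @return An object of class `kappa_result`: fields `kappa`, `scheme`,
#'   `n`, `p_value`, `z`, `label` (see [interpret_kappa()]), `small_n`
#'   (flag, `n < 30`). Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' cohen_kappa(binary_table(495, 27, 95, 49), scheme = "unweighted")
cohen_kappa <- function(table, scheme = c("quadratic", "unweighted"), p_value = TRUE) {
  scheme <- match.arg(scheme)
  m <- unclass(as.matrix(table))
  if (nrow(m) != ncol(m)) abort("contingency table must be square")
  if (any(m < 0) || sum(m) < 1) abort("counts must be non-negative with a positive total")
  k <- nrow(m)
  n <- sum(m)
  o <- m / n
  r <- rowSums(o)
  c_ <- colSums(o)
  e <- outer(r, c_)
  d <- kappa_weights(k, scheme)
  denom <- sum(d * e)
  if (denom <= .Machine$double.eps) {
    abort("kappa is undefined: expected agreement is 1 (degenerate marginals)")
  }
  kap <- 1 - sum(d * o) / denom

  pv <- NA_real_
  z <- NA_real_
  if (isTRUE(p_value)) {
    # null SE of weighted kappa (agreement weights w = 1 - d)
    w <- 1 - d
    pe_w <- sum(e * w)
    wbar_row <- as.vector(w %*% c_)   # row-wise expected weight, length k
    wbar_col <- as.vector(r %*% w)    # col-wise expected weight, length k
    var0 <- (sum(e * (w - outer(wbar_row, rep(1, k)) - outer(rep(1, k), wbar_col))^2) -
               pe_w^2) / (n * (1 - pe_w)^2)
    if (var0 > 0) {
      z <- kap / sqrt(var0)
      pv <- 2 * pnorm(-abs(z))
    } else {
      z <- 0
      pv <- 1
    }
  }

  structure(
    list(kappa = kap, scheme = scheme, n = n, p_value = pv, z = z,
         label = interpret_kappa(kap), small_n = n < 30),
    class = "kappa_result"
  )
}

#' Asymptotic null p-value for a kappa statistic
#'
#' @inheritParams cohen_kappa
#' @return The two-sided p-value (warns when `n < 30`, where the normal
#'   approximation is unreliable).
#' @export
kappa_p_value <- function(table, scheme = c("quadratic", "unweighted")) {
  res <- cohen_kappa(table, scheme = match.arg(scheme), p_value = TRUE)
  if (res$small_n) warn(sprintf("n = %d is small for the asymptotic kappa test", res$n))
  res$p_value
}

#' Interpretation band for a kappa value
#'
#' Conventional thresholds: below 0.21 "no agreement" (negatives
#' included), 0.21-0.39 "minimal", 0.40-0.59 "weak", 0.60-0.79 "moderate",
#' 0.80-0.90 "strong", above 0.90 "almost perfect". The value is rounded
#' to two decimals before banding, matching how kappas are reported.
#'
#' @param kappa Numeric vector in \[-1, 1\].
#' @return Character vector of band labels.
#' @export
#' @examples
#' interpret_kappa(c(0.07, 0.35, 0.95))
interpret_kappa <- function(kappa) {
  if (any(!is.na(kappa) & (kappa < -1 | kappa > 1))) abort("kappa must lie in [-1, 1]")
  k2 <- round(kappa, 2)
  dplyr::case_when(
    is.na(k2) ~ NA_character_,
    k2 <= 0.20 ~ "no agreement",
    k2 <= 0.39 ~ "minimal",
    k2 <= 0.59 ~ "weak",
    k2 <= 0.79 ~ "moderate",
    k2 <= 0.90 ~ "strong",
    TRUE ~ "almost perfect"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa (%s): %.2f on n = %d pairs (%s)\n",
              x$scheme, x$kappa, x$n, x$label))
  if (!is.na(x$p_value)) cat(sprintf("  H0 kappa = 0: z = %.2f, p = %.3g\n", x$z, x$p_value))
  invisible(x)
}

#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$kappa, scheme = x$scheme, statistic = x$z,
    p.value = x$p_value, label = x$label, n = x$n
  )
}

#' @export
glance.kappa_result <- function(x, ...) tidy.kappa_result(x)

#' Binary concordance summary row
#'
#' Summarizes matched pairs in the any-versus-none recoding into the four
#' cells with counts and percentages of the domain-specific `n` (one
#' decimal place), plus the unweighted kappa rounded to two decimals.
#'
#' @param pairs A tibble of matched observations.
#' @return A one-row tibble: `n`, count and percent per cell, `kappa`.
#' @export
binary_concordance_summary <- function(pairs) {
  tab <- build_contingency_table(pairs, mode = "binary")
  # all mass in one cell makes kappa undefined; report NA rather than fail
  kap <- tryCatch(cohen_kappa(tab, scheme = "unweighted", p_value = FALSE)$kappa,
                  error = function(e) NA_real_)
  n <- attr(tab, "n")
  tibble::tibble(
    n = n,
    neither = tab["none", "none"],
    clinician_only = tab["any", "none"],
    patient_only = tab["none", "any"],
    both = tab["any", "any"],
    pct_neither = round(100 * tab["none", "none"] / n, 1),
    pct_clinician_only = round(100 * tab["any", "none"] / n, 1),
    pct_patient_only = round(100 * tab["none", "any"] / n, 1),
    pct_both = round(100 * tab["any", "any"] / n, 1),
    kappa = round(kap, 2)
  )
}
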