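test_that("discordance summary counts classes and matches a brute-force oracle", {
  s <- discordance_summary(pairs_tbl(c(0, 0, 1), c(2, 3, 2)))
  expect_equal(s$n_under, 2L)
  expect_equal(s$n_agree, 1L)
  expect_equal(s$n_over, 0L)

  all_agree <- discordance_summary(pairs_tbl(0:3, 1:4))
  expect_equal(all_agree$rate_under, 0)

  set.seed(14)
  g <- sample(0:4, 500, replace = TRUE)
  sev <- sample(1:4, 500, replace = TRUE)
  s2 <- discordance_summary(pairs_tbl(g, sev))
  n_under <- 0L; n_over <- 0L; n_agree <- 0L
  for (i in 1:500) {
    gc <- min(g[i], 3)
    if (sev[i] == gc + 1) n_agree <- n_agree + 1L
    else if (sev[i] > gc + 1) n_under <- n_under + 1L
    else n_over <- n_over + 1L
  }
  expect_equal(c(s2$n_agree, s2$n_under, s2$n_over), c(n_agree, n_under, n_over))
  expect_equal(s2$n_agree + s2$n_under + s2$n_over, s2$n)
  expect_error(discordance_summary(pairs_tbl(integer(), integer())), "no matched")
})

test_that("exact binomial predominance test matches direct pmf summation", {
  expect_equal(exact_binomial_predominance(5, 5)$p_value, 1)
  r <- exact_binomial_predominance(10, 0)
  expect_equal(r$p_value, 2 * 0.5^10)
  expect_true(r$significant) # 0.00195 < 0.004

  # symmetry under argument swap
  expect_equal(exact_binomial_predominance(13, 4)$p_value,
               exact_binomial_predominance(4, 13)$p_value)

  # full oracle equivalence for all (n_under, n_over) with n <= 30
  for (n in 1:30) {
    for (x in 0:n) {
      expect_equal(exact_binomial_predominance(x, n - x)$p_value,
                   binom_two_sided_oracle(x, n), tolerance = 1e-12)
    }
  }
  expect_error(exact_binomial_predominance(0, 0), "at least one")
})

test_that("alpha threshold is respected and validated", {
  r <- exact_binomial_predominance(10, 0, alpha = 0.001)
  expect_false(r$significant)
  expect_error(exact_binomial_predominance(1, 0, alpha = 0), "alpha")
})

test_that("McNemar continuity-corrected statistic matches the hand formula and stats::mcnemar.test", {
  paired <- function(b, c, keep = 20) {
    tibble::tibble(
      discordant_mid = c(rep(TRUE, b), rep(FALSE, c), rep(TRUE, keep), rep(FALSE, keep)),
      discordant_end = c(rep(FALSE, b), rep(TRUE, c), rep(TRUE, keep), rep(FALSE, keep))
    )
  }
  r <- mcnemar_paired_change(paired(10, 2), method = "cc")
  expect_equal(r$statistic, (abs(10 - 2) - 1)^2 / 12)
  expect_equal(r$p_value, pchisq(49 / 12, df = 1, lower.tail = FALSE))
  ref <- stats::mcnemar.test(matrix(c(20, 2, 10, 20), 2, 2), correct = TRUE)
  expect_equal(r$statistic, unname(ref$statistic))
  expect_equal(r$p_value, ref$p.value)

  # symmetric switches: near-zero statistic, p about 1
  r2 <- mcnemar_paired_change(paired(7, 7), method = "cc")
  expect_equal(r2$statistic, 1 / 14)
  expect_gt(r2$p_value, 0.7)

  # auto switches to the exact binomial variant for few switchers
  r3 <- mcnemar_paired_change(paired(10, 2), method = "auto")
  expect_equal(r3$method, "exact")
  expect_equal(r3$p_value, binom_two_sided_oracle(10, 12))

  # no switches at all
  r4 <- mcnemar_paired_change(paired(0, 0))
  expect_true(r4$degenerate)
  expect_equal(r4$p_value, 1)

  # unchanged patients leave b and c untouched
  r5 <- mcnemar_paired_change(paired(10, 2, keep = 500), method = "cc")
  expect_equal(c(r5$b, r5$c), c(r$b, r$c))
  expect_equal(r5$statistic, r$statistic)
})

test_that("two-proportion z-test satisfies the chi-square identity", {
  r <- two_proportion_test(50, 100, 50, 100)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)

  # z^2 equals the Pearson chi-square without correction
  set.seed(17)
  for (rep in 1:100) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    r <- two_proportion_test(x1, n1, x2, n2)
    ref <- suppressWarnings(prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
    expect_equal(r$z^2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  }

  # p decreases monotonically in the difference at fixed n
  ps <- sapply(seq(50, 90, by = 10), function(x1) two_proportion_test(x1, 100, 50, 100)$p_value)
  expect_true(all(diff(ps) < 0))

  expect_true(two_proportion_test(0, 50, 0, 60)$degenerate)
  expect_equal(two_proportion_test(50, 50, 60, 60)$p_value, 1)
})

test_that("discordance change uses the paired subset and recovers injected changes", {
  mk <- function(ids, grade, sev) {
    tibble::tibble(patient_id = ids, ctcae_grade = as.integer(grade),
                   eortc_severity = as.integer(sev))
  }
  ids <- sprintf("P%02d", 1:40)
  mid <- mk(ids, rep(0, 40), rep(c(1, 3), each = 20))  # 20 agree, 20 underreport
  end_same <- mid
  expect_equal(discordance_change(mid, end_same)$delta_pct, 0)
  expect_equal(discordance_change(mid, end_same)$p_value, 1)

  # every agreeing patient becomes discordant at end
  end_all <- mk(ids, rep(0, 40), rep(3, 40))
  ch <- discordance_change(mid, end_all)
  expect_equal(ch$delta_pct, 100 - 100 * ch$rate_mid)
  expect_equal(ch$rate_end, 1)

  # only the paired overlap is used for rates and the test
  mid_extra <- dplyr::bind_rows(mid, mk("EXTRA", 0, 4))
  ch2 <- discordance_change(mid_extra, end_same)
  expect_equal(ch2$n_paired, 40L)
  expect_equal(ch2$delta_pct, 0)

  expect_error(discordance_change(mid, mk("Q1", 0, 1)), "both time points")
})

test_that("a generated end-of-treatment underreport increase is recovered", {
  # two cohorts sharing the patient panel; underreporting only at end
  cfg_mid <- perfect_config(n = 400, seed = 61)
  cfg_end <- trial_config(n_per_arm = 400, underreport_prob = 0.3,
                          overestimate_prob = 0, item_noise = 0,
                          missing_item_prob = 0, missing_visit_prob = 0, seed = 62)
  mid_c <- generate_cohort(cfg_mid)
  end_c <- generate_cohort(cfg_end)
  dom <- "fatigue"
  pick <- function(cohort, tp) {
    m <- match_observations(cohort$ctcae, score_eortc(cohort$eortc))
    dplyr::filter(m, .data$domain == dom, .data$timepoint == tp, .data$arm == "A")
  }
  mid_pairs <- pick(mid_c, "mid")
  end_pairs <- pick(end_c, "mid") # same visit label; serves as the later occasion
  ch <- discordance_change(mid_pairs, end_pairs)
  # true increase: u * P(latent severity >= 2 downgraded visibly); bound loosely
  expect_gt(ch$delta_pct, 10)
  expect_lt(ch$p_value, 0.001)
  tp <- true_parameters(cfg_end)
  expected <- 100 * tp$rate_under[tp$arm == "A" & tp$domain == dom & tp$timepoint == "mid"]
  se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / ch$n_paired)
  expect_lt(abs(ch$delta_pct - expected), 4 * se)
})
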