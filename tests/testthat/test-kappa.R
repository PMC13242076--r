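test_that("contingency tables cross-tabulate matched pairs correctly", {
  p <- pairs_tbl(c(0, 0, 0), c(1, 1, 1))
  tab <- build_contingency_table(p, "binary")
  expect_equal(unclass(tab)[,], matrix(c(3L, 0L, 0L, 0L), 2, 2,
                                       dimnames = dimnames(tab)))

  p4 <- pairs_tbl(0:3, 1:4)
  tab4 <- build_contingency_table(p4, "ordinal4")
  expect_equal(unname(diag(unclass(tab4))), rep(1L, 4))
  expect_equal(sum(tab4), 4L)

  # brute-force tally on random pairs
  set.seed(20)
  g <- sample(0:4, 200, replace = TRUE)
  s <- sample(1:4, 200, replace = TRUE)
  tab_m <- build_contingency_table(pairs_tbl(g, s), "ordinal4")
  for (i in 0:3) for (j in 1:4) {
    expect_equal(tab_m[i + 1, j], sum(pmin(g, 3) == i & s == j))
  }
  expect_error(build_contingency_table(pairs_tbl(integer(), integer())), "zero")
})

test_that("kappa reproduces a published binary row and the textbook anchors", {
  res <- cohen_kappa(binary_table(495, 27, 95, 49), "unweighted")
  expect_equal(round(res$kappa, 2), 0.35)
  expect_equal(res$n, 666L)
  expect_equal(res$label, "minimal")

  diag4 <- new_tab <- matrix(0L, 4, 4); diag(new_tab) <- c(5L, 3L, 2L, 1L)
  expect_equal(cohen_kappa(new_tab, "quadratic")$kappa, 1)
  expect_equal(cohen_kappa(new_tab, "unweighted")$kappa, 1)

  indep <- matrix(c(50, 50, 50, 50), 2, 2)
  expect_equal(cohen_kappa(indep, "unweighted")$kappa, 0)
  expect_equal(cohen_kappa(indep, "unweighted")$p_value, 1)
})

test_that("tridiagonal 4x4 quadratic kappa matches the frozen double-sum oracle value", {
  m <- matrix(c(2, 1, 0, 0, 1, 2, 1, 0, 0, 1, 2, 1, 0, 0, 1, 2), 4, 4, byrow = TRUE)
  expect_equal(cohen_kappa(m, "quadratic")$kappa, 0.806451612903226, tolerance = 1e-12)
  expect_equal(cohen_kappa(m, "unweighted")$kappa, 0.424657534246575, tolerance = 1e-12)
})

test_that("kappa agrees with the explicit double-loop oracle on 1000 random 4x4 tables", {
  set.seed(7)
  for (rep in 1:1000) {
    m <- random_table(4)
    for (scheme in c("unweighted", "quadratic")) {
      expect_lt(abs(cohen_kappa(m, scheme, p_value = FALSE)$kappa -
                      kappa_oracle(m, scheme)), 1e-12)
    }
  }
})

test_that("quadratic and unweighted kappa coincide on 1000 random 2x2 tables", {
  set.seed(8)
  for (rep in 1:1000) {
    m <- random_table(2, max_count = 50)
    expect_lt(abs(cohen_kappa(m, "quadratic", p_value = FALSE)$kappa -
                    cohen_kappa(m, "unweighted", p_value = FALSE)$kappa), 1e-12)
  }
})

test_that("kappa is scale invariant, bounded by 1, and transpose-stable on symmetric tables", {
  set.seed(9)
  for (rep in 1:200) {
    m <- random_table(4)
    for (scheme in c("unweighted", "quadratic")) {
      k1 <- cohen_kappa(m, scheme, p_value = FALSE)$kappa
      expect_equal(cohen_kappa(m * 7L, scheme, p_value = FALSE)$kappa, k1,
                   tolerance = 1e-12)
      expect_lte(k1, 1)
      sym <- m + t(m)
      expect_equal(cohen_kappa(sym, scheme, p_value = FALSE)$kappa,
                   cohen_kappa(t(sym), scheme, p_value = FALSE)$kappa,
                   tolerance = 1e-12)
    }
  }
  # kappa == 1 iff all mass diagonal
  m <- random_table(4)
  off <- m; diag(off) <- 0L
  if (sum(off) > 0) expect_lt(cohen_kappa(m, "quadratic", p_value = FALSE)$kappa, 1)
})

test_that("degenerate margins raise an explicit undefined-kappa error", {
  m <- matrix(0L, 2, 2); m[1, 1] <- 10L
  expect_error(cohen_kappa(m, "unweighted"), "undefined")
  expect_error(cohen_kappa(m, "quadratic"), "undefined")
})

test_that("asymptotic kappa p-value behaves at its anchors and at trial scale", {
  expect_equal(kappa_p_value(matrix(c(50, 50, 50, 50), 2, 2), "unweighted"), 1)
  # published-size binary table: p far below 0.001
  expect_lt(kappa_p_value(binary_table(495, 27, 95, 49), "unweighted"), 0.001)
  expect_warning(kappa_p_value(matrix(c(3, 1, 1, 3), 2, 2), "unweighted"), "small")
})

test_that("asymptotic p is consistent with a permutation test at n about 200", {
  set.seed(31)
  g <- sample(1:4, 240, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  s <- ifelse(runif(240) < 0.5, g, sample(1:4, 240, replace = TRUE))
  tab <- table(factor(g, levels = 1:4), factor(s, levels = 1:4))
  for (scheme in c("unweighted", "quadratic")) {
    asym <- cohen_kappa(unclass(tab), scheme)$p_value
    perm <- kappa_permutation_p(g, s, scheme, 4, n_perm = 4000)
    # both near zero, or both in the same neighborhood
    if (perm > 5 / 4000) {
      expect_equal(asym, perm, tolerance = 4 * sqrt(perm * (1 - perm) / 4000) + 0.01)
    } else {
      expect_lt(asym, 0.01)
    }
  }
  # and under the null (independent margins) they agree too
  s0 <- sample(1:4, 240, replace = TRUE)
  tab0 <- table(factor(g, levels = 1:4), factor(s0, levels = 1:4))
  asym0 <- cohen_kappa(unclass(tab0), "quadratic")$p_value
  perm0 <- kappa_permutation_p(g, s0, "quadratic", 4, n_perm = 4000)
  expect_equal(asym0, perm0, tolerance = 4 * sqrt(perm0 * (1 - perm0) / 4000) + 0.01)
})

test_that("interpretation bands follow the conventional thresholds after rounding", {
  expect_equal(interpret_kappa(0.35), "minimal")
  expect_equal(interpret_kappa(0.07), "no agreement")
  expect_equal(interpret_kappa(-0.2), "no agreement")
  expect_equal(interpret_kappa(0.204), "no agreement") # rounds to 0.20
  expect_equal(interpret_kappa(0.206), "minimal")      # rounds to 0.21
  expect_equal(interpret_kappa(c(0.45, 0.65, 0.85, 0.95)),
               c("weak", "moderate", "strong", "almost perfect"))
  expect_error(interpret_kappa(1.2), "\\[-1, 1\\]")
})

test_that("binary concordance summary reports cells, 1-dp percentages and 2-dp kappa", {
  # reconstruct per-pair data from a published mucositis row
  p <- pairs_tbl(
    c(rep(0, 95), rep(1, 37), rep(0, 265), rep(1, 267)),
    c(rep(1, 95), rep(1, 37), rep(3, 265), rep(3, 267))
  )
  s <- binary_concordance_summary(p)
  expect_equal(s$n, 664L)
  expect_equal(s$pct_patient_only, 39.9)
  expect_equal(s$pct_both, 40.2)
  expect_equal(s$kappa, 0.13)

  one_cell <- binary_concordance_summary(pairs_tbl(rep(3, 10), rep(4, 10)))
  expect_equal(one_cell$pct_both, 100)
  expect_equal(one_cell$pct_neither, 0)
  expect_true(is.na(one_cell$kappa)) # degenerate margins: kappa undefined
})

test_that("kappa results expose broom-style tidiers", {
  td <- tidy(cohen_kappa(binary_table(495, 27, 95, 49), "unweighted"))
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("estimate", "scheme", "statistic", "p.value", "label", "n"))
})
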