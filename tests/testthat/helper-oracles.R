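# Independent oracles used across the suite. These deliberately use plain
# loops / direct tail sums, not the package's vectorized implementations.

# explicit double-loop kappa in disagreement-weight form
kappa_oracle <- function(m, scheme) {
  k <- nrow(m)
  n <- sum(m)
  num <- 0
  den <- 0
  for (i in 1:k) {
    for (j in 1:k) {
      d <- if (scheme == "unweighted") as.numeric(i != j) else (i - j)^2 / (k - 1)^2
      num <- num + d * m[i, j] / n
      den <- den + d * (sum(m[i, ]) / n) * (sum(m[, j]) / n)
    }
  }
  1 - num / den
}

# exact two-sided binomial p at p0 = 0.5: total probability of outcomes no
# more probable than the observed one
binom_two_sided_oracle <- function(x, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# permutation p-value for kappa: shuffle one margin, two-sided on |kappa|
kappa_permutation_p <- function(pairs_g, pairs_s, scheme, k, n_perm = 10000) {
  tab <- function(g, s) table(factor(g, levels = seq_len(k)),
                              factor(s, levels = seq_len(k)))
  obs <- abs(kappa_oracle(unclass(tab(pairs_g, pairs_s)), scheme))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- abs(kappa_oracle(unclass(tab(pairs_g, sample(pairs_s))), scheme))
    if (perm >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

random_table <- function(k, max_count = 20) {
  repeat {
    m <- matrix(sample(0:max_count, k * k, replace = TRUE), k, k)
    # need both margins non-degenerate for kappa to be defined
    if (sum(rowSums(m) > 0) >= 2 && sum(colSums(m) > 0) >= 2) return(m)
  }
}

# matched-pair tibble shortcut for the statistics modules
pairs_tbl <- function(grade, severity) {
  tibble::tibble(ctcae_grade = as.integer(grade),
                 eortc_severity = as.integer(severity))
}

# noiseless, fully concordant generator settings
perfect_config <- function(n = 80, seed = 42) {
  trial_config(
    n_per_arm = n, underreport_prob = 0, overestimate_prob = 0,
    item_noise = 0, missing_item_prob = 0, missing_visit_prob = 0,
    seed = seed
  )
}
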