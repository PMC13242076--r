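# Exact expectations under the synthetic-trial mechanism, obtained by
# enumerating the finite outcome space (latent severity x clinician
# mechanism x item-noise pattern x item-missingness pattern). These are
# the ground truth the pipeline's estimates are checked against.

kappa_stat <- function(o, scheme) {
  k <- nrow(o)
  e <- outer(rowSums(o), colSums(o))
  d <- kappa_weights(k, scheme)
  denom <- sum(d * e)
  if (denom <= .Machine$double.eps) return(NA_real_)
  1 - sum(d * o) / denom
}

# distribution of the scored patient severity given latent s, conditional
# on the scale being non-missing; also returns P(scale scored)
severity_dist_given_s <- function(s, n_items, noise, miss) {
  half <- ceiling(n_items / 2)
  p_delta <- c(noise / 2, 1 - noise, noise / 2)  # -1, 0, +1
  dist <- numeric(4)
  p_match <- 0
  answered_patterns <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), n_items)))
  for (r in seq_len(nrow(answered_patterns))) {
    a <- answered_patterns[r, ]
    k <- sum(a)
    p_a <- prod(ifelse(a, 1 - miss, miss))
    if (k < half) next
    p_match <- p_match + p_a
    deltas <- as.matrix(expand.grid(rep(list(-1:1), k)))
    for (q in seq_len(nrow(deltas))) {
      dd <- deltas[q, ]
      p_d <- prod(p_delta[dd + 2])
      vals <- pmin(4, pmax(1, s + dd))
      t <- severity_from_raw_mean(mean(vals))
      dist[t] <- dist[t] + p_a * p_d
    }
  }
  list(dist = dist / p_match, p_match = p_match)
}

# distribution of the clinician grade 0-4 given latent s
grade_dist_given_s <- function(s, u, v, depth_probs) {
  g <- numeric(5)
  g[(s - 1) + 1] <- g[(s - 1) + 1] + (1 - u - v)
  for (d in 1:3) {
    gd <- max(0, (s - 1) - d)
    g[gd + 1] <- g[gd + 1] + u * depth_probs[d]
  }
  go <- min(4, s)
  g[go + 1] <- g[go + 1] + v
  g
}

#' Closed-form expectations under the synthetic-trial mechanism
#'
#' For every stratum of the severity marginals (arm x domain x time
#' point), marginalizes the latent severity, the clinician mechanism, the
#' item-noise pattern and the item-missingness pattern by exact
#' enumeration of the finite outcome space, and returns the expected
#' agreement/underreport/overestimate rates among matched pairs, the
#' binary 2 x 2 cell probabilities, the probability that a pair is
#' matched, and the expected quadratic-weighted and unweighted kappas.
#' These serve as the oracle for parameter-recovery checks of the whole
#' pipeline.
#'
#' @param config A [trial_config()].
#' @return A tibble with one row per arm, domain and time point. The
#'   `degenerate` column flags strata whose expected margins make kappa
#'   undefined (kappa columns are `NA` there).
#' @export
true_parameters <- function(config) {
  validate_trial_config(config)
  marg <- marginals_by_arm(config)
  doms <- symptom_domains()
  u <- config$underreport_prob
  v <- config$overestimate_prob

  purrr::pmap_dfr(marg, function(arm, domain, timepoint, p1, p2, p3, p4, ...) {
    ps <- c(p1, p2, p3, p4)
    n_items <- doms$n_items[doms$domain == domain]
    joint <- matrix(0, 4, 4)        # collapsed grade (rows 0-3) x severity 1-4
    joint_bin <- matrix(0, 2, 2)    # clinician none/any x patient none/any
    p_match <- 0
    for (s in 1:4) {
      if (ps[s] == 0) next
      sev <- severity_dist_given_s(s, n_items, config$item_noise,
                                   config$missing_item_prob)
      gd <- grade_dist_given_s(s, u, v, config$underreport_depth)
      p_match <- p_match + ps[s] * sev$p_match
      for (g in 0:4) {
        if (gd[g + 1] == 0) next
        gc <- min(g, 3)
        for (t in 1:4) {
          pr <- ps[s] * gd[g + 1] * sev$dist[t]
          joint[gc + 1, t] <- joint[gc + 1, t] + pr
          joint_bin[(g >= 1) + 1, (t >= 2) + 1] <-
            joint_bin[(g >= 1) + 1, (t >= 2) + 1] + pr
        }
      }
    }
    agree <- sum(diag(joint))
    under <- sum(joint[upper.tri(joint)])
    over <- sum(joint[lower.tri(joint)])
    kq <- kappa_stat(joint, "quadratic")
    kb <- kappa_stat(joint_bin, "unweighted")
    tibble::tibble(
      arm = arm, domain = domain, timepoint = timepoint,
      p_match = p_match * (1 - config$missing_visit_prob),
      rate_agree = agree, rate_under = under, rate_over = over,
      p_neither = joint_bin[1, 1], p_clinician_only = joint_bin[2, 1],
      p_patient_only = joint_bin[1, 2], p_both = joint_bin[2, 2],
      kappa_quadratic = kq, kappa_binary = kb,
      degenerate = is.na(kq)
    )
  })
}

#' Pool expected rates across strata
#'
#' Combines per-stratum expectations from [true_parameters()] into
#' overall expected rates, weighting each stratum by its probability of
#' yielding a matched pair (strata contribute in proportion to their
#' expected matched `n` when the same number of patients is assessed in
#' each).
#'
#' @param truth A tibble from [true_parameters()].
#' @return A one-row tibble with pooled `rate_agree`, `rate_under`,
#'   `rate_over`.
#' @export
pooled_true_rates <- function(truth) {
  w <- truth$p_match / sum(truth$p_match)
  tibble::tibble(
    rate_agree = sum(w * truth$rate_agree),
    rate_under = sum(w * truth$rate_under),
    rate_over = sum(w * truth$rate_over)
  )
}
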