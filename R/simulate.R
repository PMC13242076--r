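#' Default latent severity marginals for the synthetic trial
#'
#' Per-domain, per-time-point probabilities over latent severities 1-4,
#' shared by both arms. The defaults emulate the symptom mix of a two-arm
#' adjuvant breast-cancer chemotherapy trial: high symptom prevalence for
#' mucositis/dry mouth and fatigue, moderate for nausea and pain, low for
#' diarrhea and vomiting, with burden drifting upward from mid- to
#' end-of-treatment for all domains except nausea and vomiting (which
#' subside as emetogenic cycles end).
#'
#' @return A tibble with columns `domain`, `timepoint`, `p1`..`p4`.
#' @export
default_severity_marginals <- function() {
  tibble::tribble(
    ~domain,     ~timepoint, ~p1,  ~p2,  ~p3,   ~p4,
    "diarrhea",  "mid",      0.78, 0.14, 0.06,  0.02,
    "diarrhea",  "end",      0.60, 0.24, 0.11,  0.05,
    "nausea",    "mid",      0.34, 0.38, 0.20,  0.08,
    "nausea",    "end",      0.70, 0.19, 0.08,  0.03,
    "vomiting",  "mid",      0.86, 0.09, 0.04,  0.01,
    "vomiting",  "end",      0.95, 0.03, 0.015, 0.005,
    "mucositis", "mid",      0.20, 0.40, 0.28,  0.12,
    "mucositis", "end",      0.12, 0.38, 0.33,  0.17,
    "fatigue",   "mid",      0.17, 0.38, 0.30,  0.15,
    "fatigue",   "end",      0.12, 0.35, 0.33,  0.20,
    "pain",      "mid",      0.61, 0.22, 0.12,  0.05,
    "pain",      "end",      0.35, 0.32, 0.22,  0.11
  )
}

#' Configuration for the synthetic two-arm trial generator
#'
#' Defines the generative mechanism: per patient, domain and time point a
#' latent severity `s` in 1-4 is drawn from `severity_marginals`; the
#' patient's questionnaire items equal `s` perturbed by symmetric +/-1
#' item noise (clamped to 1-4); the clinician grade is `s - 1` (perfect
#' concordance on the collapsed scale) except that with probability
#' `underreport_prob` it is downgraded by a depth drawn from
#' `underreport_depth`, and with probability `overestimate_prob` upgraded
#' by one. Item-level and whole-visit missingness thin the questionnaire
#' data, exercising the half-rule downstream.
#'
#' @param n_per_arm Patients per arm (default 700, the per-arm matched
#'   cohort size of a large adjuvant trial).
#' @param severity_marginals Tibble of latent severity probabilities, see
#'   [default_severity_marginals()]; an optional `arm` column makes them
#'   arm-specific.
#' @param underreport_prob Probability a clinician downgrades an
#'   assessment (default 0.55; together with the depth mix and the
#'   severity marginals this yields underreport rates of roughly 12-49%
#'   across domains and no-to-weak expected concordance, the regime
#'   reported for clinician-patient toxicity comparisons).
#' @param underreport_depth Probabilities of downgrade depths 1, 2, 3
#'   (default `c(0.5, 0.3, 0.2)`).
#' @param overestimate_prob Probability a clinician upgrades by one
#'   (default 0.01; clinician overestimation is rare, under 5% of pairs
#'   including the apparent overestimation induced by item noise).
#' @param item_noise Probability a questionnaire item deviates by +/-1
#'   from the latent severity (default 0.20; split equally between
#'   directions).
#' @param missing_item_prob Per-item missingness (default 0.02).
#' @param missing_visit_prob Probability a whole questionnaire is missing
#'   at a visit (default 0.05).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated object of class `trial_config`.
#' @export
trial_config <- function(n_per_arm = 700L,
                         severity_marginals = default_severity_marginals(),
                         underreport_prob = 0.55,
                         underreport_depth = c(0.5, 0.3, 0.2),
                         overestimate_prob = 0.01,
                         item_noise = 0.20,
                         missing_item_prob = 0.02,
                         missing_visit_prob = 0.05,
                         seed = 1L) {
  cfg <- list(
    n_per_arm = as.integer(n_per_arm),
    severity_marginals = as_tibble(severity_marginals),
    underreport_prob = underreport_prob,
    underreport_depth = underreport_depth,
    overestimate_prob = overestimate_prob,
    item_noise = item_noise,
    missing_item_prob = missing_item_prob,
    missing_visit_prob = missing_visit_prob,
    seed = as.integer(seed)
  )
  validate_trial_config(cfg)
  structure(cfg, class = "trial_config")
}

validate_trial_config <- function(cfg) {
  m <- cfg$severity_marginals
  need <- c("domain", "timepoint", "p1", "p2", "p3", "p4")
  if (!all(need %in% names(m))) {
    abort(sprintf("severity_marginals needs columns %s", paste(need, collapse = ", ")))
  }
  probs <- as.matrix(m[c("p1", "p2", "p3", "p4")])
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-8)) {
    abort("each severity marginal must be a probability vector summing to 1")
  }
  key <- c(intersect("arm", names(m)), "domain", "timepoint")
  if (anyDuplicated(m[key])) abort("duplicate severity-marginal rows")
  grid_needed <- tidyr::crossing(domain = domain_levels(), timepoint = timepoint_levels())
  have <- dplyr::distinct(m, .data$domain, .data$timepoint)
  if (nrow(dplyr::anti_join(grid_needed, have, by = c("domain", "timepoint")))) {
    abort("severity_marginals must cover every domain and time point")
  }
  for (p in c("underreport_prob", "overestimate_prob", "item_noise",
              "missing_item_prob", "missing_visit_prob")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      abort(sprintf("%s must be a single probability in [0, 1]", p))
    }
  }
  if (cfg$underreport_prob + cfg$overestimate_prob > 1) {
    abort("underreport_prob + overestimate_prob must not exceed 1")
  }
  d <- cfg$underreport_depth
  if (length(d) != 3 || any(d < 0) || abs(sum(d) - 1) > 1e-8) {
    abort("underreport_depth must be 3 probabilities (depths 1-3) summing to 1")
  }
  if (cfg$n_per_arm < 1) abort("n_per_arm must be positive")
  invisible(cfg)
}

#' @export
print.trial_config <- function(x, ...) {
  cat(sprintf(
    "synthetic trial config: %d patients/arm, u = %.2f, v = %.2f, noise = %.2f, seed = %d\n",
    x$n_per_arm, x$underreport_prob, x$overestimate_prob, x$item_noise, x$seed))
  invisible(x)
}

marginals_by_arm <- function(cfg) {
  m <- cfg$severity_marginals
  if (!"arm" %in% names(m)) {
    m <- tidyr::crossing(arm = arm_levels(), m)
  }
  m
}

with_preserved_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic two-arm trial cohort
#'
#' Draws a full cohort under the mechanism described in [trial_config()]:
#' clinician CTCAE records, patient EORTC item responses, and the hidden
#' truth table recording the latent severity and the mechanism applied to
#' every patient-domain-time-point cell. All randomness flows from the
#' single seed in the config through one generator stream in a fixed
#' order (severities, mechanisms, depths, item noise, missingness), so a
#' given config always yields a byte-identical cohort.
#'
#' @param config A [trial_config()].
#' @return An object of class `synthetic_cohort`: a list with tibbles
#'   `ctcae` (readable by [validate_ctcae()]), `eortc`
#'   ([validate_eortc()]) and `truth`.
#' @export
generate_cohort <- function(config) {
  validate_trial_config(config)
  with_preserved_rng(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  marg <- marginals_by_arm(cfg)
  pts <- tidyr::crossing(arm = arm_levels(), idx = seq_len(cfg$n_per_arm)) |>
    dplyr::mutate(patient_id = sprintf("%s%04d", .data$arm, .data$idx))
  grid <- tidyr::crossing(
    dplyr::select(pts, "arm", "patient_id"),
    timepoint = timepoint_levels(),
    domain = domain_levels()
  ) |>
    dplyr::arrange(.data$arm, .data$patient_id, .data$timepoint, .data$domain) |>
    dplyr::left_join(marg, by = c("arm", "domain", "timepoint"))

  n <- nrow(grid)
  # latent severity via inverse-CDF on the per-row marginal
  u_sev <- runif(n)
  s <- 1L + (u_sev > grid$p1) + (u_sev > grid$p1 + grid$p2) +
    (u_sev > grid$p1 + grid$p2 + grid$p3)

  # clinician mechanism
  u_mech <- runif(n)
  mech <- dplyr::case_when(
    u_mech < cfg$underreport_prob ~ "underreport",
    u_mech < cfg$underreport_prob + cfg$overestimate_prob ~ "overestimate",
    TRUE ~ "none"
  )
  u_depth <- runif(n)
  dp <- cfg$underreport_depth
  depth <- 1L + (u_depth > dp[1]) + (u_depth > dp[1] + dp[2])
  depth[mech != "underreport"] <- NA_integer_
  grade <- dplyr::case_when(
    mech == "underreport" ~ pmax(0L, (s - 1L) - depth),
    mech == "overestimate" ~ pmin(4L, s),
    TRUE ~ s - 1L
  )

  truth <- grid |>
    dplyr::select("patient_id", "arm", "timepoint", "domain") |>
    dplyr::mutate(latent_severity = as.integer(s), mechanism = mech,
                  depth = depth, ctcae_grade = as.integer(grade))

  ctcae <- truth |>
    dplyr::select("patient_id", "arm", "timepoint", "domain", grade = "ctcae_grade")

  # patient items: latent severity perturbed by symmetric +/-1 noise
  items <- grid |>
    dplyr::select("patient_id", "timepoint", "domain") |>
    dplyr::mutate(latent = as.integer(s)) |>
    dplyr::inner_join(domain_items(), by = "domain",
                      relationship = "many-to-many") |>
    dplyr::arrange(.data$patient_id, .data$timepoint, .data$domain, .data$item_id)
  u_noise <- runif(nrow(items))
  delta <- integer(nrow(items))
  delta[u_noise < cfg$item_noise / 2] <- -1L
  delta[u_noise >= cfg$item_noise / 2 & u_noise < cfg$item_noise] <- 1L
  items$response <- pmin(4L, pmax(1L, items$latent + delta))

  # item-level missingness, then whole-visit missingness
  drop_item <- runif(nrow(items)) < cfg$missing_item_prob
  visits <- dplyr::distinct(items, .data$patient_id, .data$timepoint)
  visits$drop_visit <- runif(nrow(visits)) < cfg$missing_visit_prob
  items <- items |>
    dplyr::mutate(response = dplyr::if_else(drop_item, NA_integer_, .data$response)) |>
    dplyr::left_join(visits, by = c("patient_id", "timepoint")) |>
    dplyr::filter(!.data$drop_visit)

  eortc <- items |> dplyr::select("patient_id", "timepoint", "item_id", "response")

  structure(
    list(ctcae = validate_ctcae(ctcae), eortc = validate_eortc(eortc),
         truth = truth, config = cfg),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d CTCAE records, %d EORTC responses (seed %d)\n",
              nrow(x$ctcae), nrow(x$eortc), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to long-format CSV files
#'
#' Emits `ctcae.csv` and `eortc.csv` in the layouts consumed by
#' [read_ctcae()] / [read_eortc()], plus `truth.csv` with the latent
#' state, into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ctcae(cohort$ctcae, file.path(dir, "ctcae.csv"))
  write_eortc(cohort$eortc, file.path(dir, "eortc.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}
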