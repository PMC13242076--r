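---
title: "Methods: clinician-patient toxicity concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clinician-patient toxicity concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxconcord)
```

This vignette documents the statistical model and procedure implemented
by `toxconcord`, the conventions and numerical choices the package
commits to, the meaning and defaults of every tunable parameter, what
the synthetic-trial generator emulates (and what it cannot), and known
limitations. It is the reference companion to the worked example in the
README.

## 1. Data model

Two instruments observe the same underlying symptomatic toxicity of a
patient at a visit:

* **CTCAE** (clinician): one integer grade 0–4 per patient, time point
  and symptom domain.
* **EORTC QLQ-C30/BR23 symptom items** (patient): integer responses
  1–4 ("not at all" … "very much") per item. Six domains are covered:
  diarrhea, nausea, vomiting and mucositis (dry mouth proxy) by one
  item each; pain by two items (pain, pain interference); fatigue by
  three items (need to rest, weakness, tiredness). `symptom_domains()`
  and `domain_items()` expose this structure.

The trial design is two arms (A, B) and two assessment time points
(mid-treatment, end-of-treatment). Input CSVs are read with strict
integer parsing: out-of-range values, sentinels such as `99` or `-1`,
and non-integers are rejected with an error naming the offending rows;
genuinely empty cells become `NA` (item-level missingness).

## 2. Scoring patient responses

Single-item domains use the response directly. Multi-item domains use
the EORTC scoring convention:

* **Half-rule**: a scale is scored if at least half its items (rounded
  up) are answered — 1 of 2 for pain, 2 of 3 for fatigue — as the mean
  of the answered items. Otherwise the visit's score is missing. This
  is algebraically identical to mean-imputing the missing items with
  the scale mean and averaging all items.
* **0–100 transform**: `score = (raw_mean − 1) / 3 × 100`.
* **Categorization to four levels**: the raw item mean is rounded to
  the nearest anchor 1, 2, 3, 4, i.e. `floor(raw + 0.5 + 1e-9)`
  clamped to 1–4.

Two conventions here are the package's own, stated explicitly because
the source instruments do not fix them:

* **Tie direction.** A raw mean exactly half-way between anchors
  (possible for the 2-item pain scale, e.g. 2.5) is assigned to the
  *higher* severity by default (`tie = "higher"`), on the rationale
  that resolving ambiguity toward the patient-reported symptom being
  present is the conservative choice for a safety analysis. The
  3-item fatigue scale can never tie (means are multiples of 1/3).
  `tie = "lower"` is available throughout.
* **Numerical guard.** The `1e-9` epsilon in the rounding prevents
  floating-point representations of exact anchors (e.g. a mean of
  `0.1 * 30` style artifacts) from being rounded down spuriously. It
  changes no attainable rational score.

## 3. Harmonization and matching

CTCAE grades 3 and 4 are collapsed (`min(g, 3)`), giving both scales
four levels. A matched pair with collapsed grade `g'` and severity `s`
is classified as:

* **agreement** if `s = g' + 1`,
* **underreport** (clinician lower than patient) if `s > g' + 1`,
* **overestimate** if `s < g' + 1`.

The binary ("any toxicity") recoding takes clinician-positive as grade
≥ 1 and patient-positive as severity ≥ 2, yielding the cells
*neither*, *clinician only*, *patient only*, *both*.

Matching is **pairwise-complete per stratum**: a clinician record and a
scored patient severity must both be non-missing for the same patient,
time point and domain. No imputation is done beyond the half-rule;
visits or domains missing on either side simply drop from that
stratum's `n`. A consequence worth noting: under independent per-item
missingness with probability *p*, the half-rule makes multi-item
domains *more* robust than single-item ones — the probability a score
survives is `1 − p` for a single item, `1 − p²` for pain, and
`(1−p)³ + 3p(1−p)²` for fatigue, all ≥ `1 − p`. The test suite checks
these closed forms against the generator's enumeration.

## 4. Agreement statistics

For a k×k cross-classification with observed proportions $o_{ij}$,
independence-expected proportions $e_{ij}$ (outer product of margins)
and disagreement weights $d_{ij}$,

$$\kappa = 1 - \frac{\sum_{ij} d_{ij} o_{ij}}{\sum_{ij} d_{ij} e_{ij}}.$$

* **Four-level analysis**: quadratic weights
  $d_{ij} = (i-j)^2/(k-1)^2$ on the 4×4 table of collapsed grade
  versus severity.
* **Binary analysis**: $d_{ij} = \mathbf{1}[i \ne j]$ (plain Cohen's
  kappa) on the 2×2 table. On 2×2 tables the two schemes coincide
  exactly, which the test suite verifies on thousands of random
  tables.

**Null test.** The hypothesis κ = 0 is tested with the
Fleiss–Cohen–Everitt asymptotic null variance. Writing agreement
weights $w_{ij} = 1 - d_{ij}$, $p_e = \sum w_{ij} e_{ij}$, and
$\bar w_{i\cdot}, \bar w_{\cdot j}$ for the margin-weighted row/column
means of $w$,

$$\operatorname{var}_0(\hat\kappa) =
  \frac{\sum_{ij} e_{ij}\,(w_{ij} - \bar w_{i\cdot} - \bar w_{\cdot j})^2 - p_e^2}
       {n\,(1 - p_e)^2},$$

and the p-value is two-sided normal. **All p-values in the package are
two-sided**; a one-sided hypothesis was never pre-registered for any
of these tests, and two-sided is the conservative default. The
asymptotic p is checked against a permutation test at n ≈ 240 in the
suite; a warning is emitted below n = 30. Tables with a degenerate
margin (all mass in one row or column category) have no defined kappa
and raise an explicit error; pipeline tables convert that to `NA`
rather than dropping the stratum.

**Interpretation bands** (applied after rounding kappa to 2 decimals,
matching the reporting resolution): ≤ 0.20 no agreement, 0.21–0.39
minimal, 0.40–0.59 weak, 0.60–0.79 moderate, 0.80–0.90 strong,
\> 0.90 almost perfect.

## 5. Discordance tests

* **Predominance of underreporting** (per stratum): among discordant
  pairs, an exact two-sided binomial test of the underreport count
  against p = 1/2, using the minimum-likelihood two-sided rule (sum
  of outcome probabilities no greater than the observed outcome's).
  Default α = 0.004, a Bonferroni allowance for the 12
  domain-by-time-point strata of the six-domain, two-time-point
  design. Strata with zero discordant pairs are flagged, not dropped.
* **Mid-to-end change in discordance** (per arm and domain): restricted
  to patients with matched pairs at *both* time points — the same
  paired subset is used for the rates and the test, so the reported
  change is internally consistent. The default McNemar variant is
  `"auto"`: the continuity-corrected chi-square
  $(|b-c|-1)^2/(b+c)$ on 1 df when the discordant count $b+c \ge 25$,
  and the exact binomial version below that; $b+c = 0$ gives p = 1.
  The tracked discordance defaults to underreporting only
  (`change_type = "underreport"`); `"any"` tracks all discordance.
* **Between-arm comparison** (per domain and time point): pooled
  two-sample z-test of the underreport proportions, without continuity
  correction (its square is the Pearson chi-square, checked against
  `prop.test(correct = FALSE)` in the suite).

## 6. The synthetic-trial generator

`generate_cohort(trial_config(...))` simulates a full cohort with
known ground truth, in a fixed draw order from a single seed (the
caller's RNG state is saved and restored). Per patient, domain and
time point:

1. A latent four-level severity *s* is drawn from the domain- and
   time-point-specific marginal distribution.
2. The clinician grade is `s − 1` (perfect concordance), except:
   with probability `underreport_prob` it is downgraded by a depth
   drawn from `underreport_depth` (floored at 0), and with probability
   `overestimate_prob` upgraded to `min(4, s)`.
3. Each questionnaire item equals *s* perturbed by ±1 with total
   probability `item_noise` (symmetric, half each direction), clamped
   to 1–4.
4. Items go missing independently with `missing_item_prob`; whole
   patient-visits go missing with `missing_visit_prob`.

### Parameters, defaults, and why

| parameter | default | meaning |
|---|---|---|
| `n_per_arm` | 700 | patients per arm; 1,400 total matches the scale of a large adjuvant trial |
| `severity_marginals` | `default_severity_marginals()` | P(s = 1..4) per domain × time point |
| `underreport_prob` | 0.55 | probability the clinician misses/downgrades a symptomatic assessment |
| `underreport_depth` | (0.5, 0.3, 0.2) | mix of downgrade depths 1–3 |
| `overestimate_prob` | 0.01 | probability of clinician upgrade |
| `item_noise` | 0.20 | probability an item deviates ±1 from the latent severity |
| `missing_item_prob` | 0.02 | independent item-level missingness |
| `missing_visit_prob` | 0.05 | whole-visit missingness |
| `seed` | 1 | RNG seed |

The defaults were chosen once, from the published ranges of the
motivating trial (per-domain patient-reported prevalences of roughly
20–80% with nausea/vomiting subsiding by end-of-treatment; binary
kappas clustering in the 0.1–0.5 band; clinician underreporting the
strongly dominant discordance direction, with overestimation under
5%), and are treated as *the* study conditions: tests and the
acceptance script consume them, never the other way around.

### Ground truth by enumeration

`true_parameters()` computes, per stratum, the exact expected
agreement/underreport/overestimate rates, binary cell probabilities,
and the kappas of the *expected* contingency table, by enumerating the
finite outcome space (latent severity × clinician mechanism × item
noise pattern × answered-item subset), conditioned on the pair
matching. `pooled_true_rates()` weights strata by their matching
probability. The test suite validates the generator against this
enumeration per stratum by Monte Carlo, and validates parameter
recovery (pooled underreport rate within 3 standard errors across 20
seeds at 2,000 patients per arm, mean absolute bias below 0.01).

### What the generator does and does not emulate

It emulates: domain- and time-specific symptom prevalence (including
the emetic symptoms subsiding at end-of-treatment), a dominant
clinician-underreporting mechanism of variable depth, patient
measurement noise, and realistic missingness at item and visit level.
Time trends are expressed **only** through the time-point-specific
severity marginals; the under/overestimation mechanism is
time-constant.

It does **not** reach the most extreme published discordance: with
overestimation capped below 5%, this single-mechanism generator cannot
push expected binary kappas down to the 0.03–0.09 values published for
the worst domains while keeping the other strata realistic. Strata
where clinician-only positives are effectively absent drive kappa down
through missed cases only, and this mechanism bottoms out near
κ ≈ 0.25 at the default noise level. Reproducing the most discordant
published strata would need a second mechanism (e.g. clinician
assessments statistically independent of the latent severity for a
fraction of visits), which is out of scope.

## 7. Pipeline conventions and reporting

`run_analysis()` returns a `report_bundle` whose tables round kappa to
2 decimals and percentages to 1 decimal — the resolutions at which
such results are conventionally reported — while p-values are kept at
full precision. The bundle is deterministic for fixed inputs
(`write_report_bundle()` output is byte-identical across runs; the
manifest records an input hash rather than a timestamp). Extra
stratification columns present in the CTCAE table (e.g. country) can
be added via `analysis_config(extra_strata = ...)`.

Design decisions left *upstream* of this package:

* **Per-cycle CTCAE aggregation.** The package consumes one grade per
  patient × time point × domain. If the trial recorded grades per
  treatment cycle, how to summarize them into the two assessment
  windows (worst grade, window-matched cycle, …) must be decided
  before the data enter `read_ctcae()`; the concordance machinery is
  agnostic to that choice.
* **Severity cut points.** The four-level categorization via
  nearest-anchor rounding of the raw item mean is this package's
  convention; alternative cut points on the 0–100 scale would shift
  the four-level results (and, through the severity ≥ 2 threshold,
  the binary ones) and can be explored by re-categorizing upstream.

## 8. Known limitations

* Asymptotic kappa p-values are unreliable below n ≈ 30 (a warning is
  emitted); a permutation test is the fallback at small n.
* Degenerate strata (a margin concentrated in one category) have
  undefined kappa; they are reported as `NA`, not zero.
* The generator's item noise is symmetric and ±1 only; real response
  styles (extreme responding, acquiescence) are not modeled.
* Missingness is completely at random; informative missingness (sicker
  patients skipping questionnaires) would bias observed concordance in
  ways the ground-truth enumeration does not cover.
* The published dataset bundled with the package contains only the
  binary 2×2 counts; per-patient four-level tables were not published,
  so the ordinal-kappa machinery is validated against independent
  oracles and known-truth simulation rather than printed values.
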