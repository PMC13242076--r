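# toxconcord

Concordance analysis between clinician-graded and patient-reported
chemotherapy toxicity.

## The scientific problem

In oncology trials, treatment toxicity is conventionally recorded by
clinicians using the Common Terminology Criteria for Adverse Events
(CTCAE, grades 0–4). Patients experience those same toxicities and can
report them directly through validated questionnaires such as the EORTC
QLQ-C30 and QLQ-BR23, whose symptom items use a four-point severity
scale ("not at all" to "very much"). The two sources routinely
disagree, and the direction of disagreement matters clinically: when
clinicians record a lower grade than the severity the patient reports,
symptomatic toxicity is *underreported* in the trial record, which can
bias safety conclusions and deprive patients of supportive care.

`toxconcord` implements the full analysis pipeline for quantifying this
concordance in a two-arm trial with six symptom domains (diarrhea,
nausea, vomiting, mucositis, pain, fatigue) assessed at two time points
(mid-treatment and end-of-treatment):

1. **Scoring** patient questionnaire items into four-level severities,
   including multi-item scales (pain: 2 items; fatigue: 3 items) with
   the EORTC half-rule for partially missing items.
2. **Harmonization** of CTCAE grades (0–4, with 3–4 collapsed) against
   the four-level patient severities, classifying each matched pair as
   agreement, clinician underreport, or clinician overestimate.
3. **Agreement statistics**: quadratic-weighted Cohen's kappa on the
   full 4×4 cross-classification, and unweighted kappa on the binary
   ("any toxicity" vs none) 2×2 recoding, both with asymptotic tests of
   kappa = 0 and conventional interpretation bands.
4. **Discordance tests**: exact binomial tests for predominance of
   underreporting among discordant pairs, McNemar tests for change in
   discordance between time points in paired patients, and pooled
   two-proportion z-tests comparing arms.
5. **Synthetic data**: a generator with known ground truth (enumerated
   expected kappas and discordance rates) whose defaults mimic a large
   adjuvant breast-cancer trial, used to validate the whole pipeline by
   parameter recovery.

The package ships the published binary concordance table from the
PANTHER trial (24 strata of 2×2 counts with their published kappas) as
a bundled dataset; reproducing those kappas exactly from the counts is
part of the test suite.

Intended audience: biostatisticians and trialists analyzing paired
clinician/patient toxicity data, and methodologists studying
rater-agreement statistics for ordinal safety outcomes.

## The statistics, briefly

For a k×k table with observed cell proportions *o<sub>ij</sub>*,
expected-under-independence proportions *e<sub>ij</sub>*, and
disagreement weights *d<sub>ij</sub>*, weighted kappa is

> κ = 1 − Σ d<sub>ij</sub> o<sub>ij</sub> / Σ d<sub>ij</sub> e<sub>ij</sub>

with quadratic weights *d<sub>ij</sub>* = (i−j)²/(k−1)² for the
four-level analysis and *d<sub>ij</sub>* = 1[i≠j] (plain Cohen's kappa)
for the binary analysis; the two coincide exactly on 2×2 tables. The
test of κ = 0 uses the Fleiss–Cohen–Everitt asymptotic null variance.
Interpretation bands (applied to kappa rounded to 2 decimals):
≤ 0.20 no agreement, 0.21–0.39 minimal, 0.40–0.59 weak, 0.60–0.79
moderate, 0.80–0.90 strong, > 0.90 almost perfect.

Multi-item scales use the EORTC half-rule (score if at least half the
items are answered, as the mean of answered items) and the linear
0–100 transform; severities are recovered by rounding the raw item
mean to the nearest of the four anchors, half-way ties going to the
higher severity by default.

A matched pair with CTCAE grade *g* and patient severity *s* (1–4)
agrees when *s* = min(*g*, 3) + 1; *s* below that is clinician
overestimation, above it clinician underreporting. The binary recoding
uses grade ≥ 1 for the clinician and severity ≥ 2 for the patient.

## Worked example

Generate a synthetic two-arm trial at the default study conditions
(700 patients per arm) and run the full analysis:

```r
library(toxconcord)

cohort <- generate_cohort(trial_config(n_per_arm = 700, seed = 1))
cohort
#> synthetic cohort: 16800 CTCAE records, 23958 EORTC responses (seed 1)

bundle <- run_analysis(cohort$ctcae, cohort$eortc)
bundle
#> concordance report bundle: 15742 matched pairs across 24 strata
#>   weighted kappa range: 0.44 to 0.67

head(bundle$agreement, 4)
#> # A tibble: 4 × 7
#>   arm   timepoint domain        n kappa  p_value label
#>   <fct> <fct>     <fct>     <int> <dbl>    <dbl> <chr>
#> 1 A     mid       diarrhea    645  0.6  3.56e-63 moderate
#> 2 A     mid       nausea      650  0.58 9.81e-65 weak
#> 3 A     mid       vomiting    650  0.55 6.69e-60 weak
#> 4 A     mid       mucositis   646  0.5  1.24e-50 weak

glance(bundle)
#> # A tibble: 1 × 6
#>   n_matched n_strata kappa_min kappa_max rate_under rate_over
#>       <int>    <int>     <dbl>     <dbl>      <dbl>     <dbl>
#> 1     15742       24      0.44      0.67      0.341    0.0243
```

At the default generative parameters, about 34% of matched pairs show
clinician underreporting against 2.4% overestimation — underreporting
predominates in every stratum, as the generator's mechanism dictates,
and as `true_parameters()` predicts by exact enumeration.

Reproducing a published binary-concordance kappa from its 2×2 counts:

```r
pub <- published_binary_concordance()
row <- dplyr::filter(pub, arm == "A", timepoint == "mid", domain == "diarrhea")
cohen_kappa(binary_table(row$neither, row$clinician_only,
                         row$patient_only, row$both), "unweighted")
#> Cohen's kappa (unweighted): 0.35 on n = 666 pairs (minimal)
#>   H0 kappa = 0: z = 9.64, p = 5.34e-22
```

All 24 published rows reproduce exactly at the published 2-decimal
resolution.

A command-line entry point is installed at
`inst/scripts/toxconcord` (`simulate` and `analyze` subcommands), e.g.

```sh
Rscript inst/scripts/toxconcord simulate --out cohort/ --seed 7 --n_per_arm 100
Rscript inst/scripts/toxconcord analyze --ctcae cohort/ctcae.csv \
    --eortc cohort/eortc.csv --out report/
```

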