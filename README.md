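# copatterns

Congruence analysis of physical-activity and dietary lifestyle patterns.

## The problem

Epidemiologists who profile lifestyles with questionnaires usually analyze
physical activity and diet separately. A complementary question is whether
the *patterns* agree: do the item trees that hierarchical clustering finds
in men resemble those found in women, and does the activity-based grouping
of participants resemble their diet-based grouping? `copatterns` answers
this with the toolkit comparative biologists use for cophylogenies: facing
two dendrograms in a tanglegram, rotating branches to minimize entanglement,
and scoring agreement with Mantel, cophenetic, Baker's Gamma and
Fowlkes–Mallows statistics.

The package covers the full path from raw questionnaires to those
statistics, for cohorts measured with the long-form International Physical
Activity Questionnaire (IPAQ; 11 activity items in 4 domains plus sitting)
and a 16-item food-frequency instrument (QEB) with six ordinal consumption
categories, plus self-reported height, weight and body-fat percentage.

## What it computes

* **Scoring** — MET-min/week per item/domain/total with the protocol
  coefficients and low/moderate/high bands (600 and 3000 MET-min/week
  thresholds); times/day frequency coefficients (0, 0.06, 0.14, 0.5, 1, 2);
  two 8-item diet-quality indices on a 0–100 point scale with 0–33/34–66/
  67–100 bands; BMI, fat mass and fat mass index.
* **Preprocessing** — chained-equations imputation with predictive mean
  matching for missing diet responses (MCAR), Yeo–Johnson normalization
  with maximum-likelihood lambda, (0,1) min-max scaling, Euclidean
  distances over items or participants.
* **Trees and congruence** — Ward (`ward.D2`) dendrograms; tanglegrams with
  entanglement `sum(|Δposition|^L)` normalized by the full-reversal worst
  case (L = 1.5 by default); one- and two-sided greedy untangling with
  random restarts; Mantel permutation test; cophenetic correlation;
  Baker's Gamma; Fowlkes–Mallows B_k with permutation p-value and the
  closed-form null expectation `sqrt(Pk·Qk)/(n(n−1))`.
* **Subgroups and inference** — k-means (k-means++/Lloyd) with silhouette
  and elbow model selection; one-way ANOVA with Tukey HSD; Conover-style
  binomial median confidence intervals; a dummy-coded agreement regression
  testing intercept and slope equality of self-reported vs measured
  body-fat-on-weight lines; sex-stratified descriptive tables with
  Shapiro–Wilk-gated t / Mann–Whitney / chi-square comparisons.
* **Synthetic cohorts** — a seeded generator that plants latent participant
  classes, right-skewed activity minutes, ordinal diet categories, a
  calibrated between-sex item-congruence level, a diet effect on body fat,
  MCAR missingness and a measured validation subset, so the whole pipeline
  is testable without access to any real cohort.

## Worked example

```r
library(copatterns)
run <- run_pipeline(cohort_spec(seed = 1))
print(run)
```

```
Lifestyle-pattern congruence run: 107 participants

-- pa_sexes --
Dendrogram congruence report
  Mantel:          r = 0.588, p = 0.0002
  cophenetic c:    left 0.720, right 0.783
  Baker's Gamma:   0.242
  Fowlkes-Mallows: B2 = 0.546, p = 0.5205
  entanglement:    0.491 -> 0.051
-- diet_sexes --
Dendrogram congruence report
  Mantel:          r = 0.798, p = 0.0001
  ...

female subgroups (k = 4):
  bmi: F = 0.79, p = 0.503
  bfp: F = 3.74, p = 0.017
  fmi: F = 3.22, p = 0.030
```

Reading it: the male and female activity item trees correlate strongly
(Mantel r = 0.588 over the 66 item pairs, one-sided permutation
p = 0.0002 with 9999 permutations), and untangling reduced the tanglegram's
entanglement from 0.49 to 0.05 — visually, almost parallel connectors. The
diet trees agree even more (r = 0.798). In this synthetic cohort the
planted diet effect on body fat shows up in the female diet-index
subgroups (body-fat ANOVA F = 3.74, p = 0.017) but not in BMI — the
generator plants the effect on fat percentage, and BMI only inherits it
through the weight term.

`run_pipeline(..., output_dir = "run1")` additionally writes JSON
congruence/subgroup/agreement reports, Newick trees, tanglegram layouts
(CSV and SVG), heatmap matrices, the descriptive table and a manifest with
seeds and a config hash.

Individual stages are exported too: `score_ipaq()`, `convert_qeb_frequency()`,
`compute_hdi8()`, `impute_missing()`, `yeo_johnson()`, `ward_linkage()`,
`tanglegram()`/`untangle()`, `mantel_test()`, `bakers_gamma()`,
`fowlkes_mallows()`, `choose_k()`, `one_way_anova()`/`tukey_hsd()`,
`median_ci()`, `agreement_regression()`, `descriptive_table()`.

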