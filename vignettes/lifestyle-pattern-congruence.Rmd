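---
title: "Quantifying congruence between physical-activity and dietary lifestyle patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying congruence between physical-activity and dietary lifestyle patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

`copatterns` treats lifestyle questionnaires the way comparative biology
treats phylogenies. Per sex, the scored questionnaire items (12 weekly-minute
physical-activity items from the long-form IPAQ, 16 times/day food-group
frequencies from the QEB) are normalized and clustered into Ward dendrograms.
Two dendrograms over the same objects — the male and female item trees, or
the activity-based and diet-based participant trees — are then faced in a
tanglegram and their agreement is quantified with four complementary
statistics: the Mantel permutation correlation of the underlying distance
matrices, the cophenetic correlation of each tree with its own distances,
Baker's Gamma rank correlation of co-clustering levels, and the
Fowlkes–Mallows index of the cut partitions. Participant subgroups found by
k-means on the two diet-quality indices are finally tested for
body-composition differences (BMI, body-fat percentage, fat mass index) with
one-way ANOVA and Tukey HSD.

```{r, eval = FALSE}
library(copatterns)
run <- run_pipeline(cohort_spec(seed = 1))
print(run)
```

## Scoring model

**Activity.** Each of the 11 activity items is converted to MET-min/week by
multiplying weekly minutes by the long-form protocol coefficient (walking
3.3, transport cycling 6.0, moderate activities 4.0, vigorous 8.0, vigorous
yard work 5.5, moderate inside chores 3.0; `ipaq_items()`), summed into the
four domains (work/school, transport, domestic/garden, leisure) and a total.
Categorical levels are low (< 600 MET-min/week), moderate (600–2999), high
(≥ 3000); both boundaries belong to the upper band. Sitting minutes are
carried through unscored. The protocol's truncation rules are off by default
(`score_ipaq(truncate_minutes=)` enables a cap) because the analysis the
package replicates does not mention them.

**Diet.** The six ordinal consumption categories map to times/day as
never = 0, 1–3/month = 0.06, once/week = 0.14, several/week = 0.5,
daily = 1, several/day = 2 — exactly, since every downstream quantity is a
function of these printed constants. The two diet-quality indices each sum
eight item frequencies; the 0–100 point scale is `100 × sum / 16`, the
denominator being the largest possible sum (all eight items at 2), which is
the one scaling consistent with the published low/moderate/high bands
0–33 / 34–66 / 67–100. The eight pro-healthy items follow the instrument's
list; the eight non-healthy items are the instrument's non-healthy groups
collapsed to the 16-item minimal set.

**Body composition.** BMI = weight/height², fat mass = bfp/100 × weight,
FMI = fat mass/height² (kg, m). FMI ≤ BMI always.

## Preprocessing

Missing diet responses (assumed missing completely at random) are imputed by
chained equations with predictive mean matching on the times/day
coefficients: per incomplete column, a linear model on the other diet
columns predicts the missing cells and each is filled with the observed
value of one of the five nearest predictions. Five independent chains are
pooled by the modal value per cell (ties toward the smaller coefficient), so
every imputed value lies in the legal six-value codomain — a requirement of
the downstream index scoring, and the reason chains are pooled by mode
rather than averaged. Whether to impute before or after coefficient
conversion is not dictated by the replicated analysis; this package imputes
on the coefficients (the conversion is a fixed bijection, so the choice only
affects the numeric scale seen by the imputation model).

Skewed variables are brought toward normality with the Yeo–Johnson power
transform, defined on all reals, with lambda fitted by maximizing the
Gaussian profile log-likelihood (search on [−5, 5], tolerance 1e−6) on the
two sexes pooled — transforming per sex would make the sexes' item
geometries incomparable. Variables are then min-max normalized to [0, 1]
(within sex, since all clustering is sex-stratified) and Euclidean distances
are computed between columns (item trees) or rows (participant trees).
Constant variables are a hard error at the scaling step, named in the
message.

## Trees and congruence statistics

Ward linkage uses the `ward.D2` dialect — the criterion on squared
Euclidean distances with heights reported on the distance scale — because
that is the correct minimum-variance objective for Euclidean input; the
`ward.D` dialect remains available as a switch. Heights are monotone
nondecreasing, and the test suite checks the merge sequence against an
exhaustive agglomeration that recomputes the objective from raw coordinates
at every step.

A tanglegram's **entanglement** is `sum(|pos_left − pos_right|^L) /
worst case`, with positions the leaf ranks on each side and the worst case
the same sum under full reversal of one order; L defaults to 1.5, the
conventional exponent, and is exposed. Leaf order is canonicalized first
(the subtree containing the smaller original index goes left), and
**untangling** searches over internal-node rotations, which change leaf
order but never topology: `step1side` greedily flips nodes of one tree
until no single flip helps, `step2side` alternates sides to convergence and
restarts from 20 random rotation states (plus the incoming state, so the
result can never be worse than the input), `random` keeps the best of
seeded random states. On trees with up to six leaves the two-sided search
reproduces the global minimum found by enumerating all 2^(n−1) × 2^(n−1)
rotation assignments.

The **Mantel test** correlates lower triangles and permutes one matrix's
labels jointly over rows and columns; the p-value is one-sided
(congruence = positive association) with the add-one convention
`(1 + #{r* ≥ r}) / (n_perm + 1)`, so it can never be zero. Defaults are
9999 permutations (Mantel) and 1999 (Fowlkes–Mallows), both seeded and
reproducible bit for bit. **Baker's Gamma** assigns every leaf pair the
cluster-count level at which it first co-clusters (n − merge step) and is
the tie-aware Spearman correlation of the two pairwise vectors — invariant
under rotations by construction. The **Fowlkes–Mallows index** at level k is
`Tk / sqrt(Pk Qk)` from the pair-count contingency table of the two
k-cluster cuts; alongside the permutation p-value the closed-form null
expectation under fixed margins, `sqrt(Pk Qk) / (n(n−1))`, is reported, and
the two are cross-checked against each other in the tests. The cut level
defaults to the silhouette-recommended participant k for the corresponding
feature block (the smaller of the two sexes' recommendations), overridable.

Because the activity and diet item sets share no labels, the
activity-vs-diet comparison within a sex is performed on the **participant**
trees (activity-feature distances vs diet-feature distances over the same
people), where every congruence statistic is well defined. The item-level
activity-diet associations the tanglegram figures display are the
nearest-neighbor connectors, not a congruence statistic.

## Subgroups and inference

k-means uses k-means++ seeding with Lloyd iterations, best of 25 restarts
(cap 300 iterations); `choose_k` recommends the mean-silhouette-maximizing
k (ties toward smaller k) and attaches the within-cluster sum-of-squares
curve for elbow inspection. Body-composition contrasts across subgroups use
the classical fixed-effects F test with exact p-values, Tukey HSD
(Tukey–Kramer for unequal sizes) when k ≥ 3, and median confidence
intervals from binomial order statistics (the largest rank r with
`P(X < r) ≤ α/2`, X ~ Binomial(n, ½), giving conservative coverage).

The self-report validation regresses body fat on weight with a dummy-coded
source term and its interaction in a single model: the source coefficient
tests the vertical shift between the self-reported and measured lines, the
interaction tests a slope change. The weight covariate is centered so the
shift is evaluated at the mean weight rather than extrapolated to zero —
with the interaction in the model, the uncentered contrast would be nearly
powerless. The two-regression formulation and this single-model dummy
coding give identical fits; the single model yields both p-values jointly.
Student t comparisons default to equal variances (Welch is a flag), the
chi-square test defaults to no continuity correction (flag available), and
when a variable's kind is unspecified the Shapiro–Wilk test (α = 0.05,
per group) gates the t vs Mann–Whitney choice.

## The synthetic cohort generator

No participant-level data are distributed with the instrument papers, so
the generator manufactures cohorts with exactly the structure the analysis
assumes, making every downstream stage testable:

* **Design.** 52 males and 55 females (the study scale), each sex drawn
  from `k_clusters = 3` latent classes, honoring the 15-per-subgroup
  sample-size rule.
* **Latent structure.** Each participant has a q = 3 dimensional latent
  trait; items load on these traits through a loading matrix. The female
  loading matrix is `sqrt(w)` times the male matrix plus `sqrt(1−w)`
  independent noise, which makes the expected entrywise correlation of the
  sexes' squared item distances equal to `w`. The mapping from the
  user-facing `item_congruence_rho` to `w` is a fixed monotone calibration
  table measured once by Monte-Carlo (100 replicates per grid point) under
  the default design, because discretization, zero-censoring, min-max
  scaling and finite-sample noise attenuate the raw identity; the realized
  Mantel correlation between the sexes' item-distance matrices then matches
  the target (means ≈ 0.03 / 0.41 / 0.81 at targets 0 / 0.4 / 0.8).
  Congruence is measured per feature block (activity, diet) and averaged: a
  pooled 28-item distance matrix would carry deterministic activity-vs-diet
  block structure shared by both sexes and fake congruence at rho = 0.
* **Class separation.** `separation = 2` means each item's class means
  differ by two within-class SDs in expectation (the per-feature convention
  common in clustering simulations); the implied latent centroid distance
  is obtained in closed form from the loading distribution. Read instead as
  a latent centroid distance of two SDs, three-class mixtures overlap so
  strongly that mean-silhouette model selection prefers k = 2 — a known
  property of the silhouette criterion, not an implementation artifact —
  so the package adopts the per-item reading under which silhouette
  selection recovers the planted k = 3 in ≥ 90% of replicates.
* **Activity items** are exponentiated Gaussians around realistic weekly
  medians (log-scale SD 0.5), censored to zero below the 5th percentile of
  the item latent — right-skewed with a point mass at zero, which is what
  motivates the Yeo–Johnson step. **Diet items** threshold a standardized
  latent Gaussian at fixed cut points, giving every item the same realistic
  marginal over the six categories and preserving ordinality.
* **Diet-health axis.** Classes carry a diet-quality gradient: a
  participant-level unhealthy-diet score with class offsets (+1.6, 0,
  −1.6) loads weakly (0.1) on the diet items with sign + for non-healthy
  and − for pro-healthy groups. Body fat is `baseline(sex) +
  0.25 × (weight − mean) + diet_effect × SD × standardized score + noise`,
  with the residual scaled so the total SD stays at the sex baseline. The
  item loading is kept weak deliberately: the healthy/unhealthy sign
  pattern is identical in both sexes, and a strong loading would impose
  shared item structure that contradicts `item_congruence_rho = 0`.
* **Missingness** is MCAR over diet cells at rate 13/1712 (the study's
  missing-cell fraction). The **measured subset** marks ⌈fraction·n⌉
  participants (default 19/107) and adds Gaussian self-report error
  (default SD 1) plus an optional planted shift; shift 0 emulates the
  validated-agreement regime.

What the generator does **not** emulate: non-MCAR missingness, measurement
devices, reporting heaping (e.g., round-number minutes), item-specific
marginals, pandemic-era behavior shifts, or any correlation between
activity level and body composition (the planted body-composition signal is
diet-only by design). Tests passing on these cohorts therefore validate the
statistical machinery and the planted-structure recovery, not the
substantive findings one would obtain on real questionnaires.

## Numerical choices and problem sizes

All randomness is seed-controlled; the pipeline derives independent child
seeds from one root seed so single stages can be re-run in isolation.
Permutation p-values use the add-one convention. Flip searches treat
improvements below 1e−14 as ties. The test suite sizes its simulations to
run in minutes: permutation-size calibration uses 1000 datasets × 999
permutations, generator-recovery checks use 100 replicate cohorts per
condition, and the exhaustive oracles cap at 6–10 objects where full
enumeration is exact.

## Limitations

The acceptance of the pipeline is property-based: without the original
cohort, printed study statistics are not reproducible, and the synthetic
defaults only mirror the study's design parameters (sample sizes, class
count, missingness rate), not its data. The entanglement exponent, untangle
restart budget and permutation counts follow common convention rather than
a stated protocol. Sexes are analyzed separately end to end and compared
only at the tree level; a pooled mode is deliberately absent.
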