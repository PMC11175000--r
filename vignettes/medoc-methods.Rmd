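---
title: "Scoring model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medocr)
```

This vignette documents the scoring model implemented by `medocr`, the
places where the instrument's published description leaves room for
interpretation and how we resolved them, the calibration of the synthetic
cohort generator, and what the test suite does and does not demonstrate.

## The combined adherence model

The questionnaire records, per respondent: weekly consumption frequencies
for 39 food items (non-negative reals; half servings are allowed because
respondents report averages), an ordered portion category per item
(`small`/`standard`/`large`, serving multipliers 0.5/1/1.5), a set of
qualitative behaviour answers (seasonality, refinement, sourcing, breakfast
habits, meal time, dining out), and demographics. Intake enters every rule
as *servings/week* — frequency × portion multiplier, summed over the items
mapped to that rule.

The scoring matrix has 22 rows. Each row partitions the respondent's input
into a favourable branch (+1, intake inside the Mediterranean
recommendation) and an unfavourable branch (−1). Seven food rows carry a
behaviour modifier: +0.5 on the favourable branch when the paired behaviour
is also Mediterranean (e.g. ≥5 fruit/vegetable servings a day *and*
seasonal produce), −0.5 on the unfavourable branch when it is not. Item
points therefore take values in {−1.5, −1, +1, +1.5}; the sum of positive
points is the MD subscore, the sum of negative points the WD subscore, and
their sum the raw total. With 7 modifier rows and 15 plain rows, the raw
extrema are ±(7 × 1.5 + 15 × 1) = ±25.5.

The instrument's published scale is −20..+20. Since the literal branch sums
exceed that range, the package maps the raw total linearly onto it,
`normalized = raw × 20 / 25.5`, and reports *both* totals. The map is
order-preserving, fixes zero, and sends the two extremal profiles exactly
to ±20; no row is dropped or reweighted to force the printed range.

```{r extrema}
m <- medoc_matrix()
c(m$raw_min, m$raw_max)
score_profile(medoc_extremal_profile("favorable"))$normalized_total
```

### Reading decisions in the matrix

Some printed rows are ambiguous or internally inconsistent; the package
fixes one reading and keeps it configurable through the JSON matrix
serialization (`write_matrix()` / `read_matrix()`):

* **Daily-unit rows** (fruits/vegetables, cereals, dairy) state cut-offs
  per day; all frequency questions are weekly, so cut-offs are multiplied
  by 7.
* **Red meat** prints overlapping branches ("<2 servings/week" favourable,
  ">1 servings/week" unfavourable). Branches must partition intake, so we
  read favourable as servings < 2 and unfavourable as ≥ 2.
* **White meat** prints the same modifier answer in all four branches — an
  evident typesetting defect; the row has the same structure and point
  values as the fish and red-meat rows, so it follows their local-producer
  modifier pattern.
* **Exact-value branches** (dairy "2 servings/day", white meat
  "2 servings/week") are read literally: the favourable branch is the
  single point 14 (resp. 2) servings/week. Half-serving resolution makes
  the point attainable.
* **Interval ends** follow the printed inequality symbols; where a row
  prints only an "or" range (cereals "<3 or >6 servings/day"), the
  favourable interval is closed: [21, 42] servings/week.
* **Breakfast** treats "no breakfast" as an explicit answer distinct from a
  zero croissant-and-cappuccino frequency: skipping breakfast is
  unfavourable regardless of frequency.
* **Missing behaviour answers** leave a modifier at 0 and put
  behaviour-driven rows (olive oil, nibbling, spices) on the unfavourable
  branch; a missing portion answer counts as a standard portion and is
  surfaced as a validation warning, never imputed silently.
* Modifier behaviours (refinement, dairy fat, sweets type, ...) are asked
  once per score row, not per item.

Items with no matrix row (dried fruit, potatoes, french fries, focaccia,
pizza, the alcoholic drinks) are *informative-only*: validated and
available to the reference scorers, but contributing no combined-score
points.

## Reference scorers

Both reference scorers consume the same respondent profiles through
configurable aggregation maps.

**MedDietScore.** Eleven components, 0–5 each. The source instrument bins
consumption in times/month; since the published description does not print
the full bin table, the package uses monthly bins 0, (0,4], (4,8], (8,12],
(12,18], >18 mapped to 0–5 for pro-MD components and reversed for anti-MD
ones (weekly intakes × 4), with the potato and alcohol tables implemented
verbatim from their published descriptions. Potatoes at zero intake fall in
the "rare" bin (score 3), which also makes the component's stated examples
internally consistent (moving from 3 to 0 servings/week costs exactly 2
points). Two bridging choices were needed: the questionnaire asks olive oil
as a pattern (regular/frequent/occasional), mapped to component scores
5/4/1; and weekly drink frequencies are converted to glasses/day by
dividing by 7. Component intakes gated by a behaviour (non-refined cereals,
full-fat dairy) count only when the gating answer matches, because
refinement and fat content are asked once per category.

**MEDILITE.** Nine groups, 0–2 each; 2 points to the highest consumption
level of MD-typical groups, to the lowest level of non-MD groups, and to
the *middle* level for alcohol. The source instrument's cut points are not
printed in the validation paper, so the two cut points per group are
configuration (`extdata/medilite_rules.json`), defaulting to values in line
with the published instrument (e.g. fruit 1.5/2.5 servings/day). Olive oil
is treated as MD-typical with levels regular > frequent > occasional.

## Reliability toolkit

* Pearson and Spearman correlations use `stats::cor`; intervals are
  Fisher-z at level α (identical to `cor.test`'s interval for Pearson).
* The ICC is the two-way random-effects, absolute-agreement, single-measure
  form — ICC(2,1) — computed from the two-way ANOVA mean squares, with the
  F-based McGraw–Wong interval. This is the standard test–retest form; note
  that absolute agreement penalizes scale changes between administrations,
  so under multiplicative retest noise the ICC sits below the Pearson
  correlation by design, not by error. No R package in the declared
  dependency set provides this estimator, so it is implemented here and
  cross-checked in the tests against `aov`-style mean squares and `lme4`
  variance components.
* Cohen's kappa supports simple, linear and quadratic weights
  (`w_ij = (|i−j|/(k−1))^p`); with two categories all weightings coincide.
  Confidence intervals are a seeded nonparametric bootstrap (default
  B = 2000) rather than the asymptotic variance, to behave sensibly with
  sparse portion categories. Identical seeds give byte-identical intervals.
* Interpretation bands are step functions, closed on the left, open on the
  right, top band closed — the prose definitions ("greater than 0.8",
  "between 0.6 and 0.8") leave the edges ambiguous and this convention
  keeps the classification monotone and total on [−1, 1]. Three scales are
  provided: the reliability scale for correlations/ICC, Landis–Koch for
  kappa, and the 0.5–0.7 acceptable range used for FFQ reproducibility
  trials.
* `reliability_report()` mirrors the validation study's table layout:
  frequency questions get descriptives + Pearson (headline, matching the
  published tables) + Spearman (named in the methods text) + ICC;
  portion questions get weighted kappa (simple when only two levels occur).
  Respondents missing either administration are excluded first.

## The synthetic cohort generator

The generator defines the study conditions under which all stochastic
properties are tested; its defaults live in `extdata/archetypes.json`, not
in code.

* **Frequencies** are negative binomial at half-serving resolution: a draw
  is `rnbinom(mu = 2μ, size = 1/d) / 2`, so item variance is
  `μ/2 + d·μ²`. The default dispersion d = 0.5 puts the generated SD/mean
  ratios in the range shown by real FFQ frequency tables (SD of the order
  of the mean). `d = 0` degenerates to a point mass at the archetype means,
  which is the cleanest way to verify that the archetypes sit on their
  intended side of the scale.
* **Archetypes.** The `md` archetype's item means sit inside every
  favourable branch (mid-interval where the branch is an interval, e.g.
  cereals at 31 of [21, 42] weekly servings); the `wd` archetype at
  representative unfavourable values informed by the unhealthy-food
  magnitudes of published FFQ tables; `mixed` interpolates the two linearly
  (λ = 0.5 by default). Behaviour answers are favourable with probability
  0.9 (md) / 0.1 (wd), interpolated for mixed.
* **Demographics** reproduce the validation study's design: 213
  respondents split 145:68 across the age ≤ 30 / > 30 strata (ages
  N(22.9, 2.25) and N(56.3, 17.4), truncated), 70% female. An optional
  `age_md_bias` tilts older respondents toward the `md` archetype to
  emulate the nutrition-transition direction (older respondents more
  Mediterranean); only the direction is modelled, not published medians.
* **Retest noise.** T1 frequencies are T0 × a mean-one lognormal factor
  `exp(τZ − τ²/2)`, re-rounded to halves; portions switch to an adjacent
  category with probability 0.2; categorical behaviours flip with
  probability 0.1; numeric behaviours get a fixed 15% lognormal jitter.
  Rather than guessing τ, the default derives per-item τ from a target
  test–retest correlation by inverting the exact moment relation
  `ρ = σ / sqrt((σ² + μ²) e^{τ²} − μ²)` with μ, σ² the cohort's
  theoretical item moments. The default target is 0.6, the centre of the
  0.5–0.7 acceptability band — a deliberate synthetic calibration, not an
  estimate of the real instrument's noise. Half-rounding adds a small
  extra attenuation, well inside the tolerances the tests use.

### What the tests show — and what they cannot

All deterministic contracts (branch cut-offs, extrema, normalization,
component bins, band labels) are verified against independent oracles:
per-rule branch enumeration, literal bin tables evaluated by hand,
closed-form ICC and attenuation formulas, direct contingency-table
evaluation of kappa, and cross-checks against `lme4` and `e1071` where
those packages implement a comparable statistic.

The stochastic properties (ICC parameter recovery at σ²_b = 3, σ²_e = 1,
n = 500; kappa ≈ 0 under independence; mean item reliability within ±0.07
of a 0.7 target over 39 items at n = 300; md > mixed > wd score ordering
and a positive MD-subscore↔MDS correlation at n = 200) demonstrate that
the estimators and the generator are internally consistent. They do *not*
reproduce the real validation cohort's numbers: real item reliabilities,
the published validity correlations (≈0.63/0.54 by age stratum) and score
medians depend on the study data, which are not deposited. Synthetic
cohorts also lack realistic between-item covariance beyond the archetype
means, seasonal drift between administrations, and the portion-size
misreporting structure that made portion reproducibility the instrument's
weak spot.

### Problem sizes

Simulation sizes in the test suite are chosen to keep each property's
Monte-Carlo error comfortably below its assertion tolerance: n = 500
subject pairs for ICC recovery (tolerance 0.05), n = 1000 ratings for
kappa under independence (0.1), n = 300 respondents for attenuation
recovery (0.07), n = 200 per archetype for ordering tests (rank test at
p < 0.01), n = 5000 for the quadratic-kappa/latent-correlation
approximation (0.05 with seven categories).
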