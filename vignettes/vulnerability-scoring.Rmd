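---
title: "Methods: rubric scoring, reviewer concordance, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rubric scoring, reviewer concordance, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishvuln)
```

## The scoring model

`fishvuln` operationalizes a structured expert-elicitation instrument for
rating freshwater-fish vulnerability. The instrument is two modules of ten
ordinal metrics. Each metric has 3–6 ordered levels with strictly increasing
integer points starting at 1; higher points always mean *less* vulnerable.
Module totals are plain sums of best-estimate points:

- baseline vulnerability V~b~ ∈ [10, 42], current extinction risk
  independent of climate change;
- climate-change vulnerability V~c~ ∈ [10, 35], likelihood of climate-driven
  extinction by 2100.

Totals are mapped to categories through contiguous bands (four for V~b~,
five for V~c~, the fifth being "likely to benefit"). The method's key
assumptions are that expert-assigned ordinal levels are comparable across
species, that unweighted summation is an adequate aggregation (metrics are
deliberately retained even though some are correlated — see the
metric-redundancy matrix below), and that uncertainty can be carried as
(a) an optional alternate level per metric, giving per-species low/high total
bounds via per-metric min/max, and (b) a 1–3 certainty score per metric,
summed to a module certainty total in [10, 30].

### Point calibration

The instrument's published description lists level counts per baseline
metric that sum to 41 while the stated module maximum is 42; the per-level
point sheet itself was not published. The packaged default therefore scores
every level by its ordinal index *except* the top level of baseline metric
`b4` (long-term range trend, "increasing"), which carries 6 points. This is
the smallest edit that makes the module maximum 42 while keeping the minimum
at 10, and it places the extra weight on a metric where an expanding range
plausibly distinguishes the most secure species. It is a documented
convention, not a recovered fact: all points live in
`inst/extdata/default_rubric.yaml` and can be edited without touching code.
Similarly, the published climate band listing contains a typo (overlapping
"23–37" and "28–32" bands); the default uses 23–27 as the only contiguous
correction.

### Banding conventions

Single-reviewer totals are integers, but panel means are not, so bands are
defined on the real line: half-open `[lower, upper)` with the top band closed
at the module maximum. Panel means are banded **unrounded**; rounding to one
decimal (half away from zero) is display-only. Percentages likewise carry an
exact value plus an integer display value rounded half away from zero — the
convention that reconciles the instrument's published headline percentages
(61/121 → 50, 100/121 → 83, 8/43 → 19, 37/43 → 86). Totals outside the
attainable range are an error, never clamped; a missing metric score is an
error, never imputed.

## Reviewer concordance

A panel of k ≥ 2 reviewers yields per-reviewer totals. The consensus is the
band of the mean total, annotated `+` when at least one reviewer's total
bands less vulnerable than the consensus and `-` when one bands more
vulnerable (`+-` when both). Because banding is monotone in the total, the
annotation depends only on the extreme totals — which is why stored fixtures
need only (mean, min, max). The packaged Klamath fixture (20 taxa × 2
modules, four reviewers) is replayed by `concordance_regression()`: 39 of 40
printed ratings are reproduced mechanically. The one exception, the eulachon
baseline row, has a printed mean of 17.5 — below the critical/high cutpoint
of 18 — yet a printed rating of "2−"; no single banding convention can
produce that row while preserving the other 39, so the package asserts it as
a known discrepancy rather than special-casing it. Beyond the range
(`panel_spread()`), no inter-rater coefficient (kappa, ICC) is computed; the
instrument's own repeatability evidence is category agreement and spread.

## Stressor narrative

Baseline metric `b6` condenses a 13-category stressor narrative (each rated
high / intermediate / low) to three levels. No published formula exists for
that condensation, so the default is a transparent threshold rule: level 1
if ≥ 2 stressors are high; level 2 if any stressor is high or ≥ 4 are
intermediate; else level 3. Both thresholds are arguments, and the rule stays
monotone when they move.

## Correlation analyses

`rank_correlation()` is Spearman with average ranks for ties; p-values use
the t approximation by default, with an exact permutation option for
n ≤ 10. A constant vector leaves the coefficient undefined and is an error —
reporting 0 would fabricate evidence of independence. The test suite checks
the coefficient against an independent explicit-rank oracle to 1e-12,
including heavily tied data. The metric-redundancy analysis computes Pearson
matrices per module and pooled over all 20 metrics (the published account is
ambiguous about which was reported, so all three are labeled), with the
fraction of unordered off-diagonal pairs above configurable thresholds;
zero-variance metric columns are excluded with a warning rather than
propagating `NA`.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analyses assume,
so every stage is testable without the study's unpublished per-metric data.
Each species carries a latent vulnerability trait L ~ N(0, σ²~origin~). The
propensity feeding each metric is

    Z = δ(origin, module) + λ·L + sqrt(1 − λ²)·ε,   ε ~ N(0, 1)

and the best-estimate level is the ordered-threshold cut of Z at the
standard-normal K-quantiles of the metric's K levels (a proportional-odds
style mapping). This was chosen over independent uniform levels because every
downstream analysis — the V~b~–V~c~ correlation, native/alien separation,
and metric redundancy — requires *correlated* ordinal metrics, and λ (the
shared-factor loading) is the single dial controlling that coupling.

Defaults are the study conditions: 121 native and 43 alien species. The
location shifts δ were solved in closed form so expected module totals land
on the published origin means (baseline 25.7 native / 36.7 alien; climate
18.7 / 27.5): δ = 0 and 1.159 (baseline), −0.443 and 0.594 (climate). The
loading (0.6) and per-origin latent scales (0.9 native, 0.6 alien) were then
fixed once so simulated total dispersions and the V~b~–V~c~ rank correlation
sit near the published values (SDs of roughly 6/3 and 4/5 points; r~s~ ≈
0.84). Certainty scores are drawn independently of L with probabilities
(0.14, 0.44, 0.42) — expected module certainty total 22.8 — which reproduces
the published weak-to-absent certainty–score correlation; the true dependence
is unknown. Alternates appear with probability 0.8 on metrics whose certainty
is below 3 (a high-certainty best estimate gets no alternate, matching the
instrument's convention), one level away from the best estimate. Reviewer
panels perturb each metric's best level by ±1 (inward at the ends) with a
per-metric disagreement probability (default 0.15).

One caveat matters when interpreting simulator-based checks: the native/alien
location gap correlates V~b~ with V~c~ *by itself* (two shifted clusters),
so the property "λ near 1 ⇒ high correlation, λ = 0 ⇒ low" is verified
within the native cohort, where locations are constant and only the latent
coupling operates.

What the generator does **not** emulate: real metric-specific marginal
distributions (all metrics share the same latent mapping), family-level
phylogenetic clustering of vulnerability (families are sampled
exchangeably), anadromy-linked covariance, and any certainty–score
dependence. Passing tests therefore demonstrate that the scoring, consensus
and analysis machinery is correct and that the generator matches its own
calibration targets — not that the instrument would reproduce any particular
real fauna.

## Determinism and problem sizes

A single seed governs all randomness; the generator restores the caller's
RNG state and fixes the RNG kind explicitly, so equal specs give
bit-identical cohorts across sessions. The test suite's randomized checks
use fixed seeds throughout: band assignment is cross-checked against a
brute-force scan at 10,000 random totals per module; monotonicity and
bound-bracketing over dozens of random sheets; the Spearman oracle over
dozens of tied vectors; independence checks at 500 species; panel-spread
monotonicity at 50–60 replicate panels per disagreement level; and
parameter-recovery on 8 replicate cohorts of the default 164 species.

## Known limitations

- The per-level point values of the original instrument are a convention
  (see Point calibration); analyses sensitive to single points near band
  boundaries inherit that convention.
- The exact-permutation p-value enumerates all n! rank permutations and is
  deliberately capped at n ≤ 10.
- The stressor condensation rule is a stand-in for an unpublished procedure;
  users replicating a specific assessment should configure it.
- Family tables and anadromy roll-ups are generic tallies; no phylogenetic
  correction is attempted.
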