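# fishvuln

Expert-elicitation scoring of freshwater-fish vulnerability to extinction and
to climate change, for conservation scientists who need a rapid, repeatable
alternative to data-hungry population models.

Quantitative status data are missing for most fish species, so assessments
lean on structured expert judgment. `fishvuln` implements a 20-metric ordinal
rubric split into two modules:

* **Baseline vulnerability (V<sub>b</sub>)** — ten metrics on current status
  (population size and trends, range trends, non-climate stressors, life
  history, stochastic risk, dependence on management). Totals span **10–42**;
  lower totals mean higher current extinction risk. Four category bands:
  critically (<18), highly (18–25), less (26–33), least (34–42) vulnerable.
* **Climate-change vulnerability (V<sub>c</sub>)** — ten metrics on
  physiological tolerance, dispersal, habitat specialization and projected
  habitat change. Totals span **10–35** with five bands: critically (<17),
  highly (17–22), less (23–27), least (28–32) vulnerable, and likely to
  benefit (>32).

Each metric gets a *best-estimate* level, an optional *alternate* level
(their per-metric min/max generate low/high total bounds), and a certainty
score 1–3 (module certainty totals span 10–30). Panel scoring by several
independent reviewers is aggregated into a consensus mean/range/rating, with
a `+`/`−` annotation whenever a reviewer's total crosses into a less/more
vulnerable category than the consensus band. Faunal roll-ups provide category
tallies by origin (native vs alien) and family, headline percentages,
Spearman rank correlations (V<sub>b</sub>–V<sub>c</sub>, certainty vs score,
external status scores), and a Pearson metric-redundancy matrix. The rubric
itself — levels, points, bands — is YAML configuration, not code.

## Worked example

Score one declining cold-water salmonid and read back its assessment:

```r
library(fishvuln)
rubric <- default_rubric()
rubric
#> <vuln_rubric> schema 1
#>   baseline (Vb): 10 metrics, totals 10-42, 4 bands
#>   climate (Vc): 10 metrics, totals 10-35, 5 bands

sheet <- score_sheet("coho_SONCC", "R1", scores, rubric)  # 20-row data frame
assess_species(sheet, rubric)
#> <vuln_assessment> coho_SONCC (reviewer R1)
#>   Vb 21 [21-23] Highly vulnerable (certainty 25)
#>   Vc 15 [15-17] Critically vulnerable (certainty 27)
```

V<sub>b</sub> = 21 is the sum of the ten baseline best-estimate points; the
bracketed 21–23 are the low/high totals after folding in alternate scores;
certainty 25 of a possible 30 indicates well-supported judgments. The species
sits in the highly vulnerable band now and in the critically vulnerable band
once projected climate effects are scored.

Panel consensus uses the unrounded mean and flags category crossings:

```r
consensus_rating(34.0, c(31, 35), rubric, "baseline")
#> <vuln_consensus> Vb4-: mean 34.0 (31-35), Least vulnerable
```

The packaged regression fixture — four independent reviewers scoring 20 lower
Klamath River taxa on both modules — replays mechanically:

```r
reg <- concordance_regression(klamath_fixture(), rubric)
sum(reg$match)
#> [1] 39
subset(reg, !match)[, c("taxon", "module", "rating", "computed_rating")]
#>      taxon   module rating computed_rating
#> 7 Eulachon baseline     2-              1+
```

39 of the 40 printed consensus ratings are reproduced exactly; the one
mismatch (eulachon, baseline) is a documented inconsistency in the printed
record — its mean of 17.5 bands as critically vulnerable under any contiguous
banding — and is flagged, not patched.

A seeded synthetic cohort (121 native + 43 alien species, per-metric ordinal
scores driven by a species-level latent vulnerability trait) exercises every
analysis stage without field data; see `cohort_spec()` and the methods
vignette (`vignettes/vulnerability-scoring.Rmd`).

## Command line

```sh
inst/scripts/fishvuln simulate --seed 7 --out out/
inst/scripts/fishvuln assess --sheets out/sheets.csv --out out/
inst/scripts/fishvuln panel --fixture --out out/
inst/scripts/fishvuln summarize --sheets out/sheets.csv --metadata out/metadata.csv --out out/
```

All numeric results are also written as JSON stamped with the rubric's MD5
fingerprint, so reports stay auditable against a specific point calibration.

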