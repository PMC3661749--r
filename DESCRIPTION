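Package: fishvuln
Title: Climate-Change Vulnerability Scoring for Freshwater Fishes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A configuration-driven implementation of a 20-metric
    expert-elicitation rubric for rating the extinction vulnerability of
    freshwater fishes, split into a baseline (current status) module and a
    climate-change module. Provides per-species scoring with best/alternate
    score bounds and certainty totals, category-band assignment,
    multi-reviewer consensus ratings with category-crossing annotations,
    faunal roll-ups (tallies, percentages, family tables), rank-correlation
    analyses, a metric-redundancy correlation matrix, and a seeded synthetic
    cohort simulator so every analysis stage is testable without field data.
    A packaged fixture of four-reviewer panel scores for twenty lower
    Klamath River taxa supports a mechanical repeatability regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
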