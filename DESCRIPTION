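Package: mrdam
Title: Mendelian Randomisation and Drosophila Behavioural Assay Quantification
Version: 0.1.0
Authors@R:
    person("M.", "Dam", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit linking adiposity and sleep phenotypes across
    humans and flies. Provides a covariate-adjusted per-SNP linear association
    scan with Benjamini-Hochberg false-discovery-rate control; one- and
    two-sample Mendelian randomisation (Wald ratio, inverse-variance weighted,
    weighted median) with GWAS summary-statistic harmonization; Drosophila
    activity-monitor (DAM) sleep-bout scoring, rhythmicity-based exclusion and
    starvation death-calling; bench-assay quantification (counter-current
    climbing index, CAFE capillary feeding, comparative-Ct fold changes with
    replicate-CV exclusion, per-reference normalization); Kaplan-Meier survival
    estimation with two-group log-rank testing; and seeded synthetic-data
    generators with recorded ground truth so every stage is testable without
    access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    survival
Config/testthat/edition: 3
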