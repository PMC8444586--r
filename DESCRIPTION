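Package: metagage
Title: Functional Metagenomic Profiling and Relative Metagenomic Age Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal analysis of gut metagenome functional
    capacities in two-cohort infant studies. Implements fractional-count
    functional profiling (read-to-gene and gene-to-KO fractional assignment,
    single-copy marker normalization, support-based aggregation of KEGG
    orthology groups to modules and pathways), per-time-point differential
    abundance testing with Benjamini-Hochberg correction and temporal-pattern
    classification, and a replicate "metagenomic age" protocol: regularized
    random-forest age regression with balanced per-time-point train/test
    splits, smoothing-spline calibration, relative metagenomic age residuals,
    and signed-rank tests for cohort-wide developmental delay. Includes a
    synthetic two-cohort longitudinal data generator with a known, tunable
    developmental delay so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
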