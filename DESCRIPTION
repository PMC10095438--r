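Package: eqtmr
Title: Integrative DNA Methylation and Gene Expression (cis-eQTM) Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for expression quantitative trait
    methylation (eQTM) analysis in case/control cohorts: covariate-adjusted
    differential methylation at CpG and region level with Stouffer evidence
    combination, reference-based blood cell-fraction deconvolution, count
    filtering and surrogate differential expression, signed weighted
    co-expression networks with module eigengenes and hypergeometric
    overrepresentation, and the core engine correlating region-median
    methylation with log-transformed expression using percentile-bootstrap
    confidence intervals and permutation p-values. Ships a seeded synthetic
    cohort generator that plants known methylation and coupling effects for
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
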