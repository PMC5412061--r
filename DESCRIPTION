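Package: lcrt
Title: Internal-Standard Targeted RNA-Seq Simulation and a
    Cross-Validated Lung Cancer Risk Classifier
Version: 0.1.0
Authors@R:
    person("LCRT", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate, quantify and classify targeted competitive
    multiplex PCR amplicon sequencing experiments in which every assay is
    co-amplified with a synthetic internal standard (IS) spiked at known
    copy number.  The package generates synthetic cohorts with paired
    FASTQ output, demultiplexes reads by dual barcodes and primer sequence,
    classifies native-template versus internal-standard alleles by
    approximate string matching, converts NT/IS read ratios to absolute
    transcript abundance (molecules per million ACTB molecules), applies a
    closed-form stochastic-sampling coefficient-of-variation filter,
    performs multiple imputation by chained equations with predictive mean
    matching, and builds correlation-adjusted t-score ranked, vote-selected
    linear discriminant classifiers of cancer versus non-cancer subjects
    with cross-validated, Rubin's-rules-pooled performance estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
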