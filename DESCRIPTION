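Package: droughtmet
Title: Multifactorial Time-Course Metabolomics of Drought Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multifactorial GC-MS time-course
    metabolomics of drought stress in Arabidopsis: internal-standard and
    fresh-weight normalization, log transformation and quantile-based
    sample outlier QC, PCA diagnostics, pairwise genotype comparisons and
    paired shoot/root ratio analysis, polynomial-curve differential
    time-course dynamics with profile clustering, Dynamical Network
    Biomarker (DNB) composite-index critical-transition detection, and
    pathway-level metabolome-transcriptome integration via hypergeometric
    over-representation and Fisher's combined probability test. Includes a
    synthetic-data generator that emulates the 390-sample
    genotype x tissue x watering-regime x day x replicate design with
    planted osmoprotectant accumulation, a DNB cluster, and outlier
    samples, for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
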