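Package: paleomethyl
Title: Ancient-DNA Methylome Reconstruction and Differential Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs DNA methylation maps from patterns of post-mortem
    cytosine deamination in ancient genomes, detects differentially methylated
    regions (DMRs) between hominin methylomes with a binomial log-likelihood
    cumulative-sum detector, calibrates detection thresholds by simulation-based
    empirical false discovery rate, assigns DMRs to hominin lineages by parsimony
    against a chimpanzee outgroup, filters within-group variability, and provides
    the downstream density, correlation, and enrichment statistics used in
    comparative epigenomics. Includes a synthetic-data generator emulating the
    full study design so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
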