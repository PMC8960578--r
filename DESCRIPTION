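Package: methpairs
Title: Longitudinal Matched-Pair Differential DNA Methylation Analysis for
    Reduced Representation Bisulphite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential DNA methylation analysis for longitudinal matched
    case-control cohorts assayed by reduced representation bisulphite
    sequencing (RRBS). Per-CpG methylated/total read counts are modelled by a
    beta-binomial regression with matched-pair fixed effects and a
    likelihood-ratio test on the group term; differentially methylated CpGs
    (DMCs) are called at a joint FDR and coverage-corrected mean difference
    threshold, merged into differentially methylated regions (DMRs), annotated
    to promoters, exons, introns and enhancers, correlated with gene
    expression in cis TSS windows, and tested for gene-set over-representation.
    Includes pre-seroconversion cohort subsetting, pyrosequencing concordance
    checks, and a synthetic cohort generator with known ground truth for
    power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
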