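Package: smrtcall
Title: Base Modification Calling from Single-Molecule Sequencing Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects 5-methylcytosine, 5-hydroxymethylcytosine and
    N6-methyladenine on individual single-molecule real-time (SMRT)
    sequencing molecules from polymerase kinetics (inter-pulse durations
    and pulse widths). Builds normalized 21-nt measurement windows around
    candidate sites, including adapter-padded windows at fragment ends and
    a thymine-median normalization with confounder masking for adenine
    methylation, and scores them with a compact convolutional plus
    transformer network trained on labelled windows. Ships a synthetic
    kinetics simulator with ground truth (CpG methylation, Dam-style GATC
    adenine methylation, jagged cell-free DNA ends, accessibility-driven
    periodic adenine methylation), per-molecule calling workflows
    including two-stage 5hmC resolution and iterative 6mA confounder
    masking, evaluation statistics (ROC/PR areas, DeLong's test,
    depth-stratified accuracy), and downstream analyses: jagged-end
    profiles, nucleosome periodicity around anchor sites, de novo motif
    enrichment and reference-panel molecule-origin scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    Rsamtools
Config/testthat/edition: 3
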