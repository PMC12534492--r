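Package: phosphonorm
Title: Proteome-Normalized Phosphoproteomics and Cell-Type-Resolved
    Multi-Omics Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for cell-type-resolved proteomics and phosphoproteomics
    analysis: collapse of precursor-level phosphopeptide reports to class-I
    phosphosite matrices using localization probabilities, two-group
    differential expression on log2 intensities, proteome normalization of
    phosphosite regulation (fold-change subtraction with conservative
    exponential p-value dampening), left-shifted Gaussian imputation of
    missing values, proteome-transcriptome replicate correlation and
    sample-level clustering, ANOVA-based cell-type profiling with k-means
    response clusters, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    withr,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, DifferentialExpression,
    Transcriptomics, Clustering
RoxygenNote: 7.3.3
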