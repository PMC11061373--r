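Package: burstlink
Title: Linking In Vivo Spike Features of Single Neurons to Their
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to relate in vivo juxtacellular spike patterns of
    single hippocampal CA1 pyramidal neurons (burstiness, firing rate,
    spike rise time) to their single-cell RNA-seq expression profiles.
    Provides spike detection by Hilbert-envelope thresholding of
    high-pass-filtered voltage traces, averaged-waveform rise-time
    estimation, inter-spike-interval based bursty/non-bursty
    classification (PCA, k-means, Fisher linear discriminant), UMI count
    quality control, normalization and per-gene z-scoring, per-gene
    Poisson likelihood-ratio differential expression with
    Benjamini-Hochberg correction, metagene construction by Ward
    hierarchical clustering on Spearman dissimilarities, association of
    spike features with metagene or gene-panel expression (Spearman
    correlation and AIC subset regression), a ground-truthed synthetic
    cohort generator for validation, and a one-call pipeline driver.
License: MIT + file LICENSE
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ape,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
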