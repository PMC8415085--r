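Package: codexbench
Title: Benchmarking Normalization and Clustering for Multiplexed Imaging
    Cell-Type Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible benchmarking pipeline for cell-type identification
    in CODEX-style multiplexed tissue imaging. Provides a synthetic tissue
    generator with known ground truth emulating the major noise sources of
    segmented single-cell fluorescence data (low-signal channels, high
    background, lateral segmentation spillover, tissue-fold artifacts); five
    single-cell intensity treatments (raw, Z, log double-Z, percentile-capped
    min-max, arcsinh); four unsupervised clustering algorithms (k-means,
    Leiden, X-shift with Euclidean or angular distance) with elbow-point model
    selection; a programmatic hierarchical gating engine; a four-level
    cell-type hierarchy with level merging; cluster-to-type annotation
    including an over-clustered reference standard; agreement metrics
    (per-type F-score, Cohen's kappa, fold changes, all-vs-all
    cross-comparison); and spatial cellular-neighborhood analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
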