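Package: muscleniche
Title: Integrated Single-Nucleus and Spatial Transcriptomic Analysis of the
    Skeletal-Muscle Secretory Niche
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for integrated single-nucleus RNA-seq and
    Visium-style spatial transcriptomics analysis of skeletal muscle:
    nucleus and gene quality control, Wilcoxon marker detection and negative
    binomial differential expression with fold-change thresholds, secretory
    protein annotation from subcellular-location tables, hypergeometric
    gene-set enrichment, non-negative least-squares spot deconvolution with
    delineation of regions rich or poor in fibro/adipogenic progenitors
    (FAPs), and a random equal-area region resampling procedure that
    correlates secretory genes with myofiber-type and metabolism genes
    across region pseudo-bulk profiles. Ships a synthetic-data generator
    with known ground truth (cell-type signatures, spot proportions,
    planted gene-gene correlations) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
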