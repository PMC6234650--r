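Package: tatamisom
Title: Self-Organizing-Map Co-Expression Analysis of Fungal RNA-Seq Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-course bulk RNA-seq analysis for wood-decay fungi grown on
    contrasting substrates: counts-per-million and median-of-ratios
    normalization, a simplified negative-binomial Wald test with
    Benjamini-Hochberg selection of growth-point contrasts, online Kohonen
    self-organizing-map (SOM) co-expression clustering on a rectangular node
    grid with Tatami-map rendering, condition-specific node calling,
    high-expression gene filtering, annotation overlay, and replicate quality
    control. Includes a negative-binomial synthetic-data generator with
    planted co-expression modules so the whole pipeline is testable without
    external sequencing data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
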