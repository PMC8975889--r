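Package: emvec
Title: Arteriovenous Identity Analysis for Embryonic Vascular Endothelial
    Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting arterial-venous identity in embryonic
    vascular endothelial cell (VEC) single-cell RNA-seq data: UMI count
    normalization and quality-control filtering, per-cell arteriovenous
    signature scoring on a 0-10 scale with threshold classification and
    cluster confidence ellipses, cell-cycle phase scoring, Wilcoxon rank-sum
    differential expression with fold-change and expressing-fraction filters,
    random-forest vote-probability cluster refinement, principal-curve
    pseudo-ordering in a modified PCA space, ligand-receptor interaction
    calling between mural cells and VECs, and cross-species conserved-gene
    screening via Fisher's combined probability. Includes a negative-binomial
    synthetic data generator with ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    randomForest,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
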