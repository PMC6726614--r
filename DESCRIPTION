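Package: smhg
Title: Spatial Enrichment of Binary-Labelled Genomic Bins in 3D Genome
    Embeddings
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects spatial co-localization of binary-labelled genomic bins
    in low-dimensional embeddings of Hi-C contact maps.  Arbitrary pivot
    points in space are scored with the exact minimum-hypergeometric (mHG)
    statistic and its exactly corrected p-value; optimal pivots are sought
    both by exhaustive enumeration of the perpendicular-bisector arrangement
    and by octree branch-and-bound, and findings are guarded with bead-pivot,
    genomic-order and label-shuffle controls plus Benjamini-Hochberg
    q-values.  Also provides sNMDS, a smoothed nonmetric multidimensional
    scaling procedure that embeds contact maps in three dimensions while
    correcting genomic-neighbour discontinuities, annotation-to-bin mapping
    with CGH and differential contact-map binarization, Procrustes alignment
    of time-course embeddings, and synthetic polymer/contact-map generators
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    graphics,
    IRanges,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
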