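Package: rnasites
Title: Functional-Site Prediction for Noncoding RNAs from
    Secondary-Structure Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate functional sites of noncoding RNAs from the
    geometry of their secondary structure. Per-nucleotide location metrics
    (distance to the molecular centroid, NDC, and sum of distances to all
    other nucleotides, NDS) are computed from 2D layout coordinates, smoothed
    with a Gaussian filter, and the extreme points of the resulting distance
    curve are merged into predicted site intervals. Includes readers for
    dot-bracket, CT, RNAfold-dialect PostScript and PDB coordinates, a
    deterministic radiate layout engine, interval-overlap evaluation against
    known site lists (sensitivity and positive predictive value), and a
    2D-3D distance-curve Spearman correlation analysis with Storey or
    Benjamini-Hochberg false discovery rate estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
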