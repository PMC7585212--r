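Package: rankcorr
Title: Rank-Based Marker Gene Selection for Clustered Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects marker genes for clustered single-cell RNA-seq count data
    by rank-transforming UMI counts and solving an l1/l2-constrained sparse
    separating-hyperplane problem for each cluster against the rest.  The
    solver has an exact closed form via soft thresholding of the vector of
    per-gene Spearman correlations with the cluster indicator, so marker
    selection reduces to finding the threshold at which the normalized
    soft-thresholded correlation vector reaches the l1 sphere of radius
    sqrt(s).  Includes an evaluation harness (5-fold cross-validation,
    nearest-centroid classification, clustering-agreement metrics, AoM
    ranking), a Splat-style two-group negative-binomial count simulator with
    ground-truth differential-expression flags, dispersion-bin gene filtering,
    and readers/writers for 10x-style MatrixMarket and delimited count files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
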