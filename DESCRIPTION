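Package: clonetraj
Title: Longitudinal Clonal Trajectory Analysis for Single-Cell and Bulk
    Tumour Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing subclonal evolution of a tumour
    followed over many years: bin-based copy-number calling for
    low-coverage single-cell and bulk whole-genome sequencing (circular
    binary segmentation, MAPD quality control, ward.D2 subclone
    clustering, false-positive segment testing), mosaic chromosomal
    aberration detection from SNP-array LRR/BAF tracks with mosaic
    cell-fraction estimation and a targeted focal-deletion test,
    clustering of variant-allele-frequency trajectories across time
    points with a self-organizing tree algorithm, an iterative
    PCA/hierarchical-clustering procedure for single-cell expression
    with Kruskal-Wallis gene selection and hypergeometric marker
    calling, and minimum-spanning-tree pseudotime with time-anchored
    reordering.  A fully parameterized synthetic-patient generator with
    known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
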