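Package: decoyclust
Title: Exact Threshold Clustering of Protein Structure Decoys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters large ensembles of protein structure decoys by C-alpha
    RMSD and ranks decoys by neighbor count within a threshold distance, the
    standard model-selection criterion in ab initio structure prediction.
    Acceleration comes from three strategies that leave the result bit-identical
    to brute-force pairwise clustering: leader-style auxiliary grouping with
    triangle-inequality group accept/reject, cheap per-pair RMSD lower and upper
    bounds (centroid-distance signatures, reference-decoy bounds, rRMSD), and
    probabilistic outlier pre-filtering. Includes automatic threshold discovery
    (percentile and mode-based), a synthetic decoy-ensemble generator with
    planted ground truth, a PDB C-alpha reader/writer, and a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
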