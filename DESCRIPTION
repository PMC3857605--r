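Package: neteff
Title: Weighted Physical-Distance Efficiency Analysis of Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes nodal global and nodal local efficiency of structural
    brain networks from region-level tract-count and mean-fiber-length
    matrices, using shortest physical-path (travel-distance) lengths and a
    weighted distance in which strong connections shorten effective paths.
    Efficiencies are normalized against the ideal fully connected network.
    Per-region linear models relate efficiency to intra-cranial volume and
    diagnostic group with Benjamini-Hochberg false-discovery-rate correction,
    and regional t-statistic maps are compared by cosine similarity. Includes
    a generator of spatially embedded synthetic connectome cohorts with known
    intra-cranial-volume and group effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
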