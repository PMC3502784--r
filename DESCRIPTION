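Package: mirmod
Title: MRE-Mediated miRNA-miRNA Modulation Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers microRNA-microRNA modulation networks mediated by shared
    mRNA targets (microRNA response elements). Scores candidate
    (miRNA, miRNA, mRNA) triplets by the change in mutual information between
    two miRNAs when conditioning on a target mRNA's expression, assigns
    permutation p-values, combines evidence across shared targets with
    Fisher's method, and builds an undirected miRNA network with hub
    analysis. Ships bias-control comparator networks (shared-target
    hypergeometric and expression-correlation networks), diagnostic and
    prognostic evaluation of miRNA signatures (cross-validated classifier
    accuracy against a random-signature null, PCA and clustering views,
    fold-change differential expression, Kaplan-Meier/Cox survival of
    k-means risk groups), and a synthetic-data generator with planted
    modulation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    e1071,
    survival,
    jsonlite,
    withr,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
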