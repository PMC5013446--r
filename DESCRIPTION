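Package: ddinet
Title: Dual Clustering of Drug-Drug Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analyzing drug-drug interaction (DDI) networks with a
    dual-clustering methodology: modularity-based community detection is
    cross-referenced with topological communities that emerge from
    attraction-repulsion (a-r) energy-model layouts (Fruchterman-Reingold,
    LinLog and a ForceAtlas2-style preset). Clusters are labeled by the
    pharmacological property shared by the largest majority of their member
    drugs, each drug is classified as confirmed, explained or not explained
    against two tiers of property annotations, and unexplained or border-zone
    drugs seed repurposing hypotheses. Includes global network statistics,
    five node centralities with top-k ranking tables, a statistical network
    fidelity score, a planted-partition synthetic data generator with
    two-tier annotations, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
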