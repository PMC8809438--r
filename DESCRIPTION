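Package: floraphylo
Title: Flora Age and Community Phylogenetic Structure from Dated Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dating regional floras and probing community assembly
    from a dated phylogeny, a genus-level clade-age table, and site-by-species
    occurrence checklists. Computes the species-weighted mean divergence time
    (MDT) of an assemblage, its standardized effect size (SES-MDT) against a
    richness-preserving permutation null, and the mean nearest taxon distance
    (MNTD) with the nearest taxon index (NTI) against a taxa-shuffle null,
    classifying floras as significantly ancient or young and communities as
    phylogenetically clustered or dispersed. Includes tabulations of
    geographical origins, age-threshold filters, richness and endemism
    summaries, a synthetic-data generator (Yule and birth-death trees,
    clade-age tables, neutral/filtering/repulsion community assembly), and a
    seeded end-to-end pipeline with machine-readable outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
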