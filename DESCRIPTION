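Package: cocultr
Title: Classification and Quantification of Pairwise Bacterial
    Interactions Across Carbon-Source Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing endpoint cell densities of bacterial
    mono- and co-cultures grown across environments that differ in
    carbon-source diversity. Implements unidirectional effect testing
    with Benjamini-Hochberg false-discovery-rate control and the
    six-class interaction scheme (mutualism, commensalism, exploitation,
    neutralism, amensalism, competition); the log2 effect size E and the
    interaction-type angle theta with per-environment and per-pair
    averages; tests of whether growth on carbon-source mixtures matches
    the average of growth on the components; Ward-criterion
    grower/non-grower stratification with hypergeometric class
    enrichment; community-level statistics (Monte-Carlo chi-square,
    pairwise PERMANOVA over biochemical categories, rank-based species
    enrichment, Spearman trend tests); flux-balance-analysis counting of
    carbon-containing metabolic by-products on stoichiometric models;
    and a synthetic-data module with planted-effect tables and a
    resource-explicit batch consumer-resource simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
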