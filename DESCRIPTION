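Package: benthicnet
Title: Microbial Network States and Macrofauna Ecological Status in Seafloor Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies seafloor sediment samples into opposing microbial
    co-occurrence network states -- one centred on a sulfur-oxidizing hub
    genus, the other on an ammonia-oxidizing archaeal hub -- from 16S
    rRNA-derived genus count tables, and quantifies the association of those
    states with benthic macrofauna ecological status (nEQR), sediment
    chemistry and geography. Implements genus-level Spearman correlation
    networks with Benjamini-Hochberg control, Hartigan dip-test binarization
    of per-sample network abundance with kernel-density antimode thresholds,
    odds ratios with Altman 95% confidence intervals, AMBI tolerance-group
    correlation profiles, Simpson/Shannon alpha diversity, Bray-Curtis PCoA
    ordination, and cross-validated generalized additive models of nEQR with
    partial-dependence and ICE summaries. Ships a synthetic two-state
    community generator so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
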