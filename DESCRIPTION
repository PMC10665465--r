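Package: angiodiv
Title: Spatial and Temporal Diversification Dynamics of Plant Genus Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the geography of lineage diversification at
    the genus level: greedy marker selection for composite supermatrix
    terminals, monophyly screening against a reference phylogeny, extraction
    of tip rates and rates through time from dated trees annotated with
    exponential-change rate regimes, assemblage summaries over geographic
    units with quality-controlled incidence data, latitudinal-belt
    aggregation, spatially corrected correlation tests with effective sample
    sizes, reduced major axis regression, richness-preserving null models,
    and a simulator that generates trees, rate-shift configurations and
    latitude-structured occurrence data with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    phytools,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
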