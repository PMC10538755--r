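Package: tortsim
Title: Agent-Based Simulation of Desert Tortoise Gene Flow Across Barriers and Culverts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially explicit, forward-in-time, agent-based simulation of
    gene flow for low-vagility species on gridded resistance landscapes, built
    around the Mojave desert tortoise system: linear barriers (roads, railways)
    with or without connectivity culverts, habitat-suitability derived
    resistance and carrying capacity, and variable population density.
    Includes a synthetic microsatellite founder generator calibrated to target
    heterozygosity and allelic richness, and the downstream population-genetic
    analysis stack: observed/expected heterozygosity, allelic richness,
    pairwise Weir-Cockerham FST, linkage-disequilibrium effective population
    size with parametric confidence intervals, Hardy-Weinberg exact tests,
    spatial principal components analysis with Moran's I permutation tests,
    and Mantel tests for isolation by distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
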