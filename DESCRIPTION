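Package: scalediv
Title: Scale-Dependent Partitioning of Biodiversity Responses to Land Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-scale partitioning of grassland biodiversity responses to land
    management (pasture vs. meadow). Computes individual-based rarefied richness,
    Hurlbert's probability of interspecific encounter (PIE) and its effective
    species number, and multiplicative alpha-beta-gamma diversity partitions from
    subplot-by-species abundance tables; quantifies management effects as
    log-response ratios with one-way ANOVA at the subplot scale and permutation
    tests at the pooled site scale; balances unequal sampling designs by
    resampling whole plots and combining replicates with harmonic-mean p-values;
    and classifies the scale dependence of each response. Includes a hierarchical
    community simulator with independently controllable density, species-abundance
    distribution shape, and intraspecific spatial aggregation for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
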