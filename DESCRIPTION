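Package: phynat
Title: Phylogenetic Relatedness and Invasiveness of Alien Floras
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing Darwin's naturalization hypothesis in regional
    floras. Computes phylogenetic nearest-neighbour distance (PNND) and mean
    phylogenetic distance (MPD) of alien species to native assemblages at
    country and plot scales, the Fritz-Purvis D statistic for binary-trait
    phylogenetic signal with permutation and Brownian-threshold nulls,
    Dutilleul's modified test for correlation between spatially
    autocorrelated richness surfaces, loess residual hot-spot maps, AICc
    multimodel-averaged binomial GLMs of invasiveness on traits and
    relatedness, and nested random-effect models of plot-scale relatedness.
    Includes a synthetic-data generator (ultrametric trees, status labels,
    phylogenetically structured traits, survey plots, autocorrelated hectad
    richness grids) so the full analysis runs end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
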