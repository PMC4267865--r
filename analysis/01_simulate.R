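#!/usr/bin/env Rscript
# Stage 1: generate the synthetic flora bundle at study scale and write
# it under results/flora/: a dated ultrametric tree (~1612 species at
# the published status prevalences), trait table, survey plots, and the
# hectad richness grid.  Later stages read these files, so the whole
# analysis is reproducible from one root seed.

library(phynat)

seed <- 1
cfg <- sim_config(seed = seed)
flora <- simulate_flora(cfg)

st <- table(flora$species$status)
message(sprintf("species: %d native / %d non-invasive / %d invasive",
                st["native"], st["non-invasive alien"],
                st["invasive alien"]))
key <- paste(flora$plots$square, flora$plots$plot)
status <- setNames(flora$species$status, flora$species$species)
apv <- tapply(status[flora$plots$species] != "native", key, sum)
message(sprintf("plots: %d, mean %.2f aliens per plot (max %d)",
                length(apv), mean(apv), max(apv)))
message(sprintf("grid: %d hectad cells, %d empty of both alien groups",
                nrow(flora$grid),
                sum(flora$grid$richness_invasive == 0 &
                      flora$grid$richness_noninvasive == 0)))

paths <- write_flora(flora, "results/flora")
message("wrote: ", paste(basename(paths), collapse = ", "))
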