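#!/usr/bin/env Rscript
# Stage 2: phylogenetic relatedness of aliens to the native flora at two
# scales.  Country scale: PNND and MPD of every alien against all
# natives, compared between invasive and non-invasive aliens with a
# two-group linear model.  Plot scale: PNND/MPD against the natives
# co-occurring in each survey plot, modelled with nested random
# intercepts (species, and square within species) under REML.

library(phynat)

tree <- read_newick("results/flora/tree.nwk")
species <- read.csv("results/flora/species.csv")
plots <- read.csv("results/flora/plots.csv")

country <- country_relatedness(tree, species)
write.csv(country, "results/country_relatedness.csv", row.names = FALSE)
groups <- country_group_lm(country)
write.csv(groups, "results/country_group_tests.csv", row.names = FALSE)
for (i in seq_len(nrow(groups))) {
  message(sprintf(
    "country %s: invasive %.1f vs non-invasive %.1f My (t = %.3f, df = %d, %d, p = %.3f)",
    toupper(groups$response[i]), groups$mean_invasive[i],
    groups$mean_noninvasive[i], groups$t[i], groups$df1[i],
    groups$df2[i], groups$p[i]))
}

plot_rec <- plot_relatedness(tree, species, plots)
write.csv(plot_rec, "results/plot_relatedness.csv", row.names = FALSE)
rep <- attr(plot_rec, "filter_report")
message(sprintf("plot scale: %d alien occurrences in %d retained plots (%d dropped)",
                nrow(plot_rec), rep$plots_retained, rep$plots_dropped))

lmm_rows <- list()
for (resp in c("pnnd", "mpd")) {
  fit <- fit_nested_lmm(plot_rec, resp)
  m <- fit$means
  message(sprintf("plot %s (REML): invasive %.2f +/- %.2f, non-invasive %.2f +/- %.2f",
                  toupper(resp),
                  m$estimate[m$group == "invasive"],
                  m$se[m$group == "invasive"],
                  m$estimate[m$group == "non-invasive"],
                  m$se[m$group == "non-invasive"]))
  lmm_rows[[resp]] <- cbind(response = resp, m)
}
write.csv(do.call(rbind, lmm_rows), "results/plot_lmm_means.csv",
          row.names = FALSE)

# classification sanity check: invasives should show larger range change
ci <- species$change_index
w <- wilcoxon_rank_sum(ci[species$status == "invasive alien"],
                       ci[species$status == "non-invasive alien"])
message(sprintf("change index, invasive vs non-invasive: W = %.1f, p = %.2g",
                w$W, w$p))
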