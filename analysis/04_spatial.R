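#!/usr/bin/env Rscript
# Stage 4: spatial congruence of invasive and non-invasive alien
# richness at the hectad scale.  Cells empty of both groups are dropped;
# the Spearman correlation between the two richness surfaces is tested
# with Dutilleul's modified test (effective degrees of freedom corrected
# for the spatial autocorrelation of both surfaces); and residuals from
# a loess regression (span 0.75, degree 2) of invasive on non-invasive
# richness mark hot spots of excess invasion.

library(phynat)

grid <- read.csv("results/flora/grid.csv")
clean <- drop_empty_cells(grid)
message(sprintf("dropped %d of %d cells empty of both alien groups",
                attr(clean, "n_dropped"), nrow(grid)))

test <- dutilleul_test(clean$richness_invasive,
                       clean$richness_noninvasive,
                       clean[, c("x", "y")])
print(test)
write.csv(data.frame(r = test$r, F = test$F, df1 = 1,
                     df2 = test$effective_df, p = test$p,
                     n_cells = test$n),
          "results/spatial_congruence.csv", row.names = FALSE)

res <- residual_hotspots(clean)
write.csv(res, "results/richness_residuals.csv", row.names = FALSE)
message(sprintf("loess pseudo-R2 = %.3f; %d cells with positive residuals (hot spots)",
                attr(res, "pseudo_r2"), sum(res$residual > 0)))
top <- res[order(-res$residual), ][1:5, c("x", "y", "residual")]
message("top hot-spot cells:")
print(top, row.names = FALSE)
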