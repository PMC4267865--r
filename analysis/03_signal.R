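#!/usr/bin/env Rscript
# Stage 3: phylogenetic signal of invasiveness.  The Fritz-Purvis D
# statistic is computed among all naturalized aliens, among neophytes
# and among archaeophytes (tree pruned to each group), each with 10,000
# randomizations of both nulls: D ~ 1 means invasiveness is shuffled at
# random over the tips, D ~ 0 means it is as clumped as a Brownian
# threshold trait.

library(phynat)

tree <- read_newick("results/flora/tree.nwk")
species <- read.csv("results/flora/species.csv")

tab <- d_by_group(tree, species, n = 10000, seed = child_seed(1, "signal"))
write.csv(tab, "results/d_by_group.csv", row.names = FALSE)

for (i in seq_len(nrow(tab))) {
  message(sprintf(
    "%-14s n1 = %3d, n0 = %3d:  D = %.3f,  P(random) = %.3g,  P(Brownian) = %.3g",
    tab$group[i], tab$n_invasive[i], tab$n_noninvasive[i], tab$D[i],
    tab$P_random[i], tab$P_brownian[i]))
}
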