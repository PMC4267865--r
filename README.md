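# phynat

Phylogenetic relatedness and invasiveness of alien floras: an analysis
pipeline for testing **Darwin's naturalization hypothesis** — the
prediction that alien species establish more easily where the native
flora contains few close relatives (reduced competition and shared
enemies), against the rival prediction that close native relatives mark
pre-adapted environments.

The package is aimed at invasion ecologists and eco-phylogeneticists
working with a dated regional phylogeny, a classified species list
(native / non-invasive alien / invasive alien; archaeophyte / neophyte),
stratified survey plots, and atlas-scale richness grids.  A full
synthetic-data generator reproduces the statistical structure of such a
study system, so the entire pipeline runs, and is tested, without any
restricted survey data.

## What it computes

* **Relatedness at two scales.**  For each alien `a` against a native
  set `N`: the phylogenetic nearest-neighbour distance
  `PNND = min_{n∈N} d(a, n)` and the mean phylogenetic distance
  `MPD = mean_{n∈N} d(a, n)`, with `d` the patristic distance (My).
  Country scale: `N` = all natives, compared between invasiveness
  groups by linear model.  Plot scale: `N` = natives co-occurring in
  each survey plot (plots without both a native and an alien are
  excluded and counted), compared with a nested mixed model
  `PNND ~ invasiveness + (1 | species/square)` fitted by REML.
* **Phylogenetic signal of invasiveness.**  The Fritz–Purvis
  `D = (d_obs − E[d_Brownian]) / (E[d_random] − E[d_Brownian])`, where
  `d` is the sum of sister-clade differences in nodal values estimated
  by the independent-contrasts down-pass, with permutation and
  Brownian-threshold nulls at exact observed prevalence
  (`D ≈ 1` random, `D ≈ 0` Brownian-clumped), per alien group on the
  group-pruned tree.
* **Spatial congruence.**  Spearman correlation of invasive vs
  non-invasive hectad richness tested with **Dutilleul's modified
  test**: Moran's-I correlograms over distance classes yield an
  effective sample size `M̂ = 1 + tr(BΣ̂x)tr(BΣ̂y)/tr(BΣ̂xBΣ̂y)` and an
  F test on `(1, M̂−2)` df; plus loess (span 0.75, degree 2) residual
  hot spots of invasive richness.
* **Trait models.**  Binomial GLMs of invasiveness on PNND, alien
  group, absolute traits (Ellenberg L/F/N/R/S, log height, clonality,
  life-form) and nearest-native trait differences; all variable subsets
  up to size 5, AICc Akaike weights, full (zero-substituted) model
  averaging with Burnham–Anderson adjusted SEs, 95% CIs and relative
  importance; Wilcoxon rank-sum check that invasives increased more in
  range.

## Worked example

```r
library(phynat)

cfg <- sim_config(n_tips = 400, n_squares = 30, plots_per_square = 10,
                  grid_side = 20, seed = 42)
flora <- simulate_flora(cfg)
table(flora$species$status)
#>     invasive alien             native non-invasive alien
#>                 22                310                 68

d_by_group(flora$tree, flora$species, n = 2000, seed = 42)
#>           group n_invasive n_noninvasive     D P_random P_brownian
#> 1    all_aliens         22            68 0.563    0.020     0.0400
#> 2     neophytes         10            37 0.913    0.402     0.0825
#> 3 archaeophytes         12            31 0.806    0.264     0.0440

country <- country_relatedness(flora$tree, flora$species)
country_group_lm(country)
#>   response     t df1 df2     p mean_invasive mean_noninvasive
#> 1     pnnd 0.924   1  88 0.358           120             98.5
#> 2      mpd 0.617   1  88 0.539           551            547.6

grid <- drop_empty_cells(flora$grid)
dutilleul_test(grid$richness_invasive, grid$richness_noninvasive,
               grid[, c("x", "y")])
#> Modified (Dutilleul) correlation test [spearman]
#>   r = 0.923, F = 63.8, df = 1, 11.1, p = 6.268e-06  (n = 391)
```

Reading the output: `D = 0.563` with `P_random = 0.020` says
invasiveness among these 90 synthetic aliens is more phylogenetically
clustered than a random tip shuffle (this particular draw happens to
fall between the random and Brownian anchors); the group comparison
finds no PNND/MPD difference between invasive and non-invasive aliens
(`p = 0.36` and `0.54`) — the Darwin's-hypothesis null outcome; and the
two richness surfaces correlate at `r = 0.923`, but after the spatial
correction that correlation is judged against ~11 effective degrees of
freedom, not 389.

The `analysis/` directory holds the full-scale study drivers
(`01_simulate.R` … `05_trait_models.R`); run them in order from the
repository root to regenerate every results table under `results/`.

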