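---
title: "Testing Darwin's naturalization hypothesis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing Darwin's naturalization hypothesis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phynat)
```

## The scientific question

Darwin's naturalization hypothesis predicts that alien species succeed
where they have *few* close native relatives: close relatives should
compete for the same resources and share natural enemies.  The opposite
prediction is equally old — close relatives mark environments to which a
lineage is preadapted.  phynat implements a complete analysis pipeline
for arbitrating between these predictions in a regional flora, at two
spatial scales, together with a trait-based model of what actually
predicts invasiveness.

The pipeline needs four inputs: a dated ultrametric phylogeny of the
flora (branch lengths in My), a species table (status: native /
non-invasive alien / invasive alien; alien group: archaeophyte /
neophyte; Ellenberg indicator values L, F, N, R, S; height; life-form;
clonality; a range-change index), a plot-occurrence table from a
stratified survey (squares containing plots containing species), and a
hectad-scale richness grid for the two alien groups.  A synthetic-data
generator produces all four with the statistical structure the analysis
assumes, so every stage of the pipeline is exercised and tested without
restricted survey data.

## Relatedness metrics

For each alien `a` and native set `N` the package computes

* **PNND** — the phylogenetic nearest-neighbour distance,
  `min over n in N of d(a, n)`, where `d` is the patristic distance (total
  intervening branch length, so on a dated tree twice the age of the
  most recent common ancestor);
* **MPD** — the mean phylogenetic distance, `mean over n in N of d(a, n)`.

Note that MPD here is *focal-alien-to-all-natives*, not the community
all-pairs MPD common elsewhere in eco-phylogenetics; `min <= mean`
guarantees PNND ≤ MPD for every record.  At the country scale `N` is
the full native flora; at the plot scale `N` is the natives co-occurring
in the survey plot, so plot-scale PNND can only be larger than
country-scale PNND for the same alien.  Plots lacking either a native
or an alien after tree matching are excluded and counted, never
silently dropped; species in plots but absent from the tree are removed
from that plot's sets and tallied, mirroring how incomplete phylogeny
coverage is reported for real floras.

Country-scale group differences use a two-group linear model (pooled-t).
Plot-scale records are non-independent — the same alien recurs across
plots and squares — so the group contrast is estimated by a linear
mixed model with nested random intercepts, `y ~ invasiveness +
(1 | species/square)`, fitted by REML via lme4.  Group means and their
standard errors come from the cell-means parameterization
(`~ 0 + group`).  Convergence messages are surfaced, not swallowed; the
test suite verifies that the fit collapses to ordinary least squares
when the random-effect variances are zero and that variance components
(species, square-within-species, residual) are recovered from simulated
surveys of ~3000 records with median relative error well under 30%.

## Phylogenetic signal of invasiveness: the D statistic

For a binary trait on a tree, the package computes the sum of
sister-clade differences `d`: tips are coded 0/1, ancestral nodal
values are estimated by the branch-length-weighted averaging down-pass
of Felsenstein's independent-contrasts algorithm (weights `1/branch
length`, with the standard branch-length extension as pruning
proceeds), and the absolute differences between the two daughter values
entering each node are summed.  The observed `d` is located between
two simulated anchors at the same prevalence:

    D = (d_obs - mean d_Brownian) / (mean d_random - mean d_Brownian)

where the random anchor permutes the labels across tips and the
Brownian anchor thresholds a unit-rate Brownian liability at the
observed prevalence (rank thresholding, so prevalence is exact in every
replicate).  `P_random` is the fraction of permutation draws with
`d <= d_obs` (small when the trait is more clustered than random);
`P_Brownian` is the fraction of Brownian draws with `d >= d_obs`.
By construction `E[D] ~ 1` under random labelling and `E[D] ~ 0` under
the Brownian threshold model; the acceptance suite verifies both
anchors on a 200-tip tree with 500 trait replicates (mean D within
±0.1), and verifies the permutation null against exhaustive enumeration
on a 5-tip tree.  Because the published variants of the ancestral-value
estimator differ in detail, the estimator here is pinned by this
calibration rather than by matching any particular implementation
line-for-line.

Numerical choices: polytomies are resolved to zero-length bifurcations
deterministically before the down-pass; zero-length branches receive an
epsilon of `1e-8` times the mean positive branch length so the
`1/branch` weights stay finite; the group analysis (all aliens,
neophytes, archaeophytes) prunes the tree to each group's tips before
computing D, since the signal is defined *among* the group.  The
down-pass is vectorised over replicates (one traversal propagates a
tips × replicates matrix), which is what makes 10,000 randomizations
per group routine.

## Spatial congruence and hot spots

Richness of the two alien groups across hectads is compared after
dropping cells empty of both groups (the both-zero rule; dropping is
idempotent and the count is reported).  Because neighbouring hectads
are strongly autocorrelated, the correlation is tested with Dutilleul's
modified test: Moran's I of each variable is estimated over 13
equal-width distance classes (empty classes dropped with a warning),
the two estimated spatial correlation matrices give an effective sample
size

    M = 1 + tr(B Sx) tr(B Sy) / tr(B Sx B Sy)

(`B` the centring matrix), and the correlation is tested with
`F = r^2 (M - 2) / (1 - r^2)` on `(1, M - 2)` df.  All traces are
computed with O(n²) centring identities, so grids of thousands of cells
are cheap.  Since the reported correlation is Spearman-type, the
correction is applied to rank-transformed data by default; raw Pearson
is available by flag (`method = "pearson"`), and the class count is a
parameter, because neither choice is canonical.  Calibration (in the
acceptance suite): under independent white noise the mean effective df
is within 10% of `n - 2`; under autocorrelated independent fields the
empirical type-I error at nominal 0.05 stays in [0.03, 0.07], where the
uncorrected test rejects ~40% of the time.

Hot spots of invasion are residuals from a loess regression (local
quadratic, tricube weights, span 0.75, no robustness iterations —
`stats::loess` with `surface = "direct"`) of invasive on non-invasive
richness; positive residuals mark cells with more invasive richness
than their non-invasive richness predicts.  On exactly quadratic data
the fit is exact for any span, and at span 1 it reproduces global
quadratic least squares on such data — both are asserted in tests.

## Trait models of invasiveness

Each alien is paired with its nearest native (ties broken
lexicographically and recorded).  Continuous trait differences are
computed as *native minus alien* — the literal reading of the
subtraction convention, stamped into the design-matrix metadata since
only coefficient signs, not significance, depend on it.  Categorical
traits (life-form, clonality) contribute 0/1 mismatch indicators.
Height is log-transformed before differencing.  Absolute traits,
country PNND and alien group complete the candidate set; life-form
enters as a factor with the most frequent class as reference and counts
as *one* variable toward the model-size cap, since splitting a factor's
dummies across candidate models would break its meaning.

All candidate subsets of up to five variables (intercept always
included) are fitted as binomial GLMs.  Five is a deliberate cap
against overfitting at a few hundred aliens; with 17 variables it
yields `sum(choose(17, 0:5)) = 9402` models.  Models are compared on
AICc (small-sample correction matters at `n ~ 363` with up to ~20
parameters; plain AIC by flag), converted to Akaike weights, and
averaged over the *full* candidate set: a coefficient is treated as 0
with 0 variance in models that exclude it, which shrinks
weakly-supported effects toward zero (conditional averaging is
available for sensitivity).  The adjusted standard error is the
Burnham–Anderson unconditional form
`sqrt(sum_i w_i (var(b_i) + (b_i - bbar)^2))`, CIs are `± 1.96 SE`, a
variable's relative importance is the sum of the weights of models
containing it, and a coefficient is "significant" when its CI excludes
zero.  Fits showing complete separation are excluded from the average
with a logged warning rather than aborting the set.  Recovery: with 2
true and 6 null predictors at `n = 2000`, the true predictors' CIs
exclude 0 and their importance exceeds every null predictor's in ≥90%
of simulation replicates.

The change-index check — that invasive aliens increased in range more
than non-invasive aliens — is a Wilcoxon rank-sum test with mid-rank
ties, exact for small untied samples and normal-approximated with tie
correction otherwise.

## What the synthetic generator emulates (and what it does not)

The generator's defaults are the study system's conditions: 1612
species at status prevalences 1249/274/89 (largest-remainder rounding,
so the exact counts are reproduced), archaeophyte fraction 135/363, a
Yule tree rescaled to a 350 My root (a vascular-plant-scale age; the
analysis consumes only branch lengths), ~3600 plots in 120 squares with
mean 1.53 aliens per plot capped at 12, and a 53 × 53 hectad grid
(~2800 cells) whose two richness surfaces share a Gaussian random field
(exponential covariance, range 8 cells, shared weight 0.99, latent sd
1.3) through a Poisson log link — strong congruence (Spearman ~0.9)
with ~2% of cells rendered unsuitable and hence empty of both groups.
Traits evolve by Brownian motion and are discretized to the Ellenberg
ordinal scales by rank-quantile binning (which preserves the
phylogenetic signal through discretization); life-form and clonality
are equal-rates Markov processes on the tree; the change index is
drawn with an upward shift for invasives.  Invasiveness placement has
two modes — exchangeable (`random`, the default, calibrating D at 1)
and `brownian_threshold` (calibrating D at 0) — and can instead be
re-drawn from a logistic model on the traits to provide ground truth
for the model-averaging recovery tests.

What it does *not* emulate: abundance (occurrence-only plots — recorded
cover in real surveys of this kind is too thin to classify local
invasiveness, so no abundance data model is attempted), habitat
stratification and urban under-sampling, spatial position of squares
(plots get square-level composition effects but squares have no
coordinates), taxonomic structure in phylogeny coverage, and any
coupling between a species' traits and where it occurs.  Passing tests
therefore demonstrate the *machinery* — estimators calibrated, filters
applied, models recovered — not that real floras behave like the
generator.

## Reproducibility and problem sizes

Every generator and every randomized statistic is a pure function of
its inputs and a seed; pipeline stages derive child seeds from one root
seed by a fixed hash (`child_seed()`), so stages can be re-run
independently and an identical config + seed yields byte-identical
output files.  The analysis drivers under `analysis/` run the
full-scale system (1612 tips, 10,000 randomizations).  The test suite
runs the same code at reduced sizes chosen to keep each property
sharply testable — e.g. 500 trait replicates × 1000 randomizations on a
200-tip tree for the D anchors, 100 simulated surveys of ~3000 records
for variance-component recovery, 1000 nulls for the spatial type-I
check — sizes at which the asserted tolerances are comfortably inside
Monte-Carlo error.

## Known limitations

* The D-statistic ancestral estimator is calibration-pinned, not
  source-pinned; implementations that differ in their down-pass details
  will agree in D only up to Monte-Carlo error.
* Dutilleul's correction treats the Moran's I correlogram as known; at
  small n (tens of cells) the effective df is noisy, and the default 13
  distance classes are a convention, not an optimum.
* Full model averaging mixes estimates across non-nested models; the
  averaged coefficients are best read as effect summaries with honest
  (unconditional) uncertainty, not as estimates of any single model's
  parameters.
* The plot-scale MPD is computed against plot natives (the natural
  reading at the local scale); computing it against the country pool
  instead would only require passing the full native set.
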