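## Synthetic flora generator: dated tree, status labels, traits, survey
## plots and hectad richness grids with the statistical structure the
## downstream analyses assume.  Every generator is a pure function of its
## inputs and a seed; a pipeline run derives per-stage child seeds from
## one root seed (see child_seed()).

#' Configuration for the synthetic flora
#'
#' Defaults emulate the British-flora study system: ~1612 species with
#' 1249 natives, 274 non-invasive and 89 invasive aliens; aliens split
#' into archaeophytes and neophytes; 2x2 m survey plots nested in 1 km
#' squares with on average ~1.5 aliens per plot (capped at 12); and a
#' hectad (10 km) richness grid of about 2800 cells with strong shared
#' spatial structure between the two alien richness surfaces.
#'
#' @param n_tips number of species (tree tips).
#' @param tree_depth root age in My.
#' @param prevalence_native,prevalence_noninvasive,prevalence_invasive
#'   status proportions; must sum to 1.
#' @param p_archaeophyte proportion of aliens that are archaeophytes.
#' @param trait_signal_mode how invasiveness is placed on the tree:
#'   `"random"` (exchangeable permutation; expected D of 1) or
#'   `"brownian_threshold"` (thresholded Brownian liability; expected D
#'   of 0).
#' @param logistic_coefficients named numeric vector of effects (on
#'   centred trait columns, plus `"(Intercept)"`) used by
#'   [simulate_invasiveness_from_traits()].
#' @param n_squares,plots_per_square survey design: number of 1 km
#'   squares and plots per square.
#' @param plot_native_rate mean natives per plot (at least 1 always).
#' @param plot_alien_rate mean aliens per plot (at least 1 always).
#' @param plot_alien_max cap on aliens per plot.
#' @param grid_side hectad grid is `grid_side` x `grid_side` cells.
#' @param spatial_range range parameter (cells) of the exponential
#'   spatial covariance of the richness surfaces.
#' @param shared_weight weight in `[0, 1]` of the shared spatial field in
#'   each richness surface (high values give strongly congruent maps).
#' @param richness_sd standard deviation of the latent log-richness
#'   fields; larger values let the spatial field dominate Poisson noise.
#' @param mean_richness_invasive,mean_richness_noninvasive approximate
#'   mean per-cell richness of each surface.
#' @param uninvaded_frac fraction of cells rendered unsuitable (both
#'   richness values forced to zero), emulating uninvaded cells.
#' @param seed root seed; per-stage child seeds are derived from it.
#' @return a list of class `phynat_config`.
#' @export
sim_config <- function(n_tips = 1612,
                       tree_depth = 350,
                       prevalence_native = 1249 / 1612,
                       prevalence_noninvasive = 274 / 1612,
                       prevalence_invasive = 89 / 1612,
                       p_archaeophyte = 135 / 363,
                       trait_signal_mode = c("random",
                                             "brownian_threshold"),
                       logistic_coefficients = c(`(Intercept)` = -1.13,
                                                 F = 0.303, N = 0.263),
                       n_squares = 120,
                       plots_per_square = 30,
                       plot_native_rate = 8,
                       plot_alien_rate = 1.53,
                       plot_alien_max = 12,
                       grid_side = 53,
                       spatial_range = 8,
                       shared_weight = 0.99,
                       richness_sd = 1.3,
                       mean_richness_invasive = 15,
                       mean_richness_noninvasive = 40,
                       uninvaded_frac = 64 / 2814,
                       seed = 1) {
  prev <- c(prevalence_native, prevalence_noninvasive, prevalence_invasive)
  if (any(prev < 0) || any(prev > 1) || abs(sum(prev) - 1) > 1e-8) {
    stop("status prevalences must lie in [0, 1] and sum to 1")
  }
  counts <- c(n_tips, n_squares, plots_per_square, grid_side)
  if (any(counts < 1)) stop("all counts must be >= 1")
  cfg <- list(n_tips = n_tips, tree_depth = tree_depth,
              prevalence_native = prevalence_native,
              prevalence_noninvasive = prevalence_noninvasive,
              prevalence_invasive = prevalence_invasive,
              p_archaeophyte = p_archaeophyte,
              trait_signal_mode = match.arg(trait_signal_mode),
              logistic_coefficients = logistic_coefficients,
              n_squares = n_squares, plots_per_square = plots_per_square,
              plot_native_rate = plot_native_rate,
              plot_alien_rate = plot_alien_rate,
              plot_alien_max = plot_alien_max,
              grid_side = grid_side, spatial_range = spatial_range,
              shared_weight = shared_weight, richness_sd = richness_sd,
              mean_richness_invasive = mean_richness_invasive,
              mean_richness_noninvasive = mean_richness_noninvasive,
              uninvaded_frac = uninvaded_frac, seed = seed)
  class(cfg) <- "phynat_config"
  cfg
}

# integer class counts from proportions by largest remainder, so exact
# target counts are reproducible
largest_remainder <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a dated ultrametric tree
#'
#' Constant-rate pure-birth (Yule) tree conditioned on the number of tips
#' ([ape::rphylo()] with zero extinction), rescaled so the root-to-tip
#' depth equals `depth` exactly.  Tip labels are `s0001`, `s0002`, ...
#'
#' @param n_tips number of tips (>= 2).
#' @param depth root age (My).
#' @param seed integer seed.
#' @return a `phylo` object, rooted, binary, ultrametric.
#' @export
simulate_tree <- function(n_tips, depth, seed = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (depth <= 0) stop("depth must be positive")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  cur <- max(node_depths(tree)[seq_len(n_tips)])
  tree$edge.length <- tree$edge.length * (depth / cur)
  tree$tip.label <- sprintf("s%04d", seq_len(n_tips))
  tree
}

#' Assign native / alien / invasive status to tree tips
#'
#' Status counts follow the configured prevalences exactly
#' (largest-remainder rounding).  Which tips are aliens is always an
#' exchangeable random choice; which aliens are invasive depends on
#' `trait_signal_mode`: `"random"` permutes the invasive labels among
#' aliens (so the D statistic of invasiveness is calibrated at 1), while
#' `"brownian_threshold"` simulates a Brownian liability on the
#' aliens-only subtree and marks the top-k liabilities invasive (D
#' calibrated at 0).  Aliens are independently labelled archaeophyte or
#' neophyte with probability `p_archaeophyte`.
#'
#' @param tree a `phylo` object.
#' @param cfg a [sim_config()] object.
#' @param seed integer seed.
#' @return species table: `species`, `status`, `alien_group`.
#' @export
assign_status <- function(tree, cfg, seed = cfg$seed) {
  n <- ape::Ntip(tree)
  counts <- largest_remainder(n, c(cfg$prevalence_native,
                                   cfg$prevalence_noninvasive,
                                   cfg$prevalence_invasive))
  n_nat <- counts[1]; n_non <- counts[2]; n_inv <- counts[3]
  if (n_non + n_inv < 2) {
    stop("need at least 2 aliens to form the invasive/non-invasive ",
         "contrast")
  }
  with_seed(seed, {
    tips <- tree$tip.label
    aliens <- sample(tips, n_non + n_inv)
    invasive <- if (cfg$trait_signal_mode == "random" || n_inv == 0) {
      sample(aliens, n_inv)
    } else {
      sub <- ape::keep.tip(tree, aliens)
      liab <- drop(simulate_bm_matrix(sub, 1))
      names(liab) <- sub$tip.label
      names(sort(liab, decreasing = TRUE))[seq_len(n_inv)]
    }
    grp <- ifelse(runif(length(aliens)) < cfg$p_archaeophyte,
                  "archaeophyte", "neophyte")
    status <- rep("native", n)
    names(status) <- tips
    status[aliens] <- "non-invasive alien"
    status[invasive] <- "invasive alien"
    out <- data.frame(species = tips, status = unname(status[tips]),
                      alien_group = NA_character_,
                      stringsAsFactors = FALSE)
    out$alien_group[match(aliens, out$species)] <- grp
    out
  })
}

#' Simulate phylogenetically structured traits
#'
#' Continuous traits evolve by unit-rate Brownian motion on the tree.
#' Ellenberg-style indicator fields are then discretized by rank-quantile
#' binning of the Brownian values into ordinal scales (L, F, N, R on 1-9;
#' S on 0-9), which preserves the phylogenetic signal in the ordinal
#' trait.  Height is lognormal around a Brownian latent value (reported
#' in cm).  Primary life-form is an equal-rates Markov process on the
#' tree over eight Raunkiaer-style classes; clonality is a two-state
#' Markov process.  A change index (relative range-change score) is drawn
#' for aliens only, with invasives shifted upwards.
#'
#' @param tree a `phylo` object (ultrametric).
#' @param species species table from [assign_status()]; trait columns are
#'   appended.  If `NULL`, a natives-only table is created.
#' @param cfg a [sim_config()] object.
#' @param seed integer seed.
#' @param bm_sigma Brownian rate for the continuous traits; `0` gives all
#'   tips the root value.
#' @return the species table with columns `L`, `F`, `N`, `R`, `S`,
#'   `height`, `life_form`, `clonal`, `change_index` appended.
#' @export
simulate_traits <- function(tree, species = NULL, cfg = sim_config(),
                            seed = cfg$seed, bm_sigma = 1) {
  n <- ape::Ntip(tree)
  if (is.null(species)) {
    species <- data.frame(species = tree$tip.label, status = "native",
                          alien_group = NA_character_,
                          stringsAsFactors = FALSE)
  }
  stopifnot(identical(sort(species$species), sort(tree$tip.label)))
  life_forms <- c("hemicryptophyte", "therophyte", "phanerophyte",
                  "nanophanerophyte", "chamaephyte", "bulbous geophyte",
                  "nonbulbous geophyte", "hydrophyte")
  with_seed(seed, {
    lat <- simulate_bm_matrix(tree, 6) * bm_sigma  # L F N R S height
    rownames(lat) <- tree$tip.label
    lat <- lat[species$species, , drop = FALSE]
    to_ordinal <- function(z, levels) {
      if (sd(z) == 0) return(rep(levels[ceiling(length(levels) / 2)], n))
      levels[cut(rank(z, ties.method = "first"),
                 breaks = length(levels), labels = FALSE)]
    }
    species$L <- to_ordinal(lat[, 1], 1:9)
    species$F <- to_ordinal(lat[, 2], 1:9)
    species$N <- to_ordinal(lat[, 3], 1:9)
    species$R <- to_ordinal(lat[, 4], 1:9)
    species$S <- to_ordinal(lat[, 5], 0:9)
    z <- lat[, 6]
    if (sd(z) > 0) z <- (z - mean(z)) / sd(z)
    species$height <- exp(3 + z)        # cm; median ~20 cm
    depth <- max(node_depths(tree)[seq_len(n)])
    lf <- ape::rTraitDisc(tree, model = "ER", k = length(life_forms),
                          rate = 2 / depth, states = life_forms,
                          root.value = 1)
    species$life_form <- as.character(lf[species$species])
    cl <- ape::rTraitDisc(tree, model = "ER", k = 2, rate = 2 / depth,
                          states = c("0", "1"), root.value = 1)
    species$clonal <- as.integer(as.character(cl[species$species]))
    alien <- species$status != "native"
    ci <- rep(NA_real_, n)
    ci[alien] <- rnorm(sum(alien),
                       mean = ifelse(species$status[alien] ==
                                       "invasive alien", 0.5, -0.2),
                       sd = 0.5)
    species$change_index <- ci
    species
  })
}

#' Redraw invasiveness from a logistic model on the traits
#'
#' Provides ground truth for recovery tests of the invasiveness model:
#' each alien's invasive flag is drawn Bernoulli with probability
#' `plogis(b0 + sum(beta * x))`, where `x` are the named (centred within
#' aliens) trait columns.  Natives are never invasive.
#'
#' @param species species table with trait columns.
#' @param coefficients named numeric vector; `"(Intercept)"` plus names
#'   of numeric columns of `species`.
#' @param seed integer seed.
#' @return the species table with `status` updated among aliens.
#' @export
simulate_invasiveness_from_traits <- function(species, coefficients,
                                              seed = 1) {
  vars <- setdiff(names(coefficients), "(Intercept)")
  missing <- setdiff(vars, names(species))
  if (length(missing)) {
    stop("coefficients reference unknown columns: ",
         paste(missing, collapse = ", "))
  }
  alien <- species$status != "native"
  eta <- rep(coefficients[["(Intercept)"]] %||% 0, sum(alien))
  for (v in vars) {
    x <- as.numeric(species[[v]][alien])
    eta <- eta + coefficients[[v]] * (x - mean(x))
  }
  with_seed(seed, {
    inv <- rbinom(sum(alien), 1, plogis(eta)) == 1
    species$status[alien] <- ifelse(inv, "invasive alien",
                                    "non-invasive alien")
    species
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate survey plot assemblages
#'
#' Squares contain plots; every plot holds at least one native and at
#' least one alien (the survey inclusion rule), with mean aliens per plot
#' `plot_alien_rate` capped at `plot_alien_max`.  Species enter plots
#' with lognormal species-level occupancy weights, and each square draws
#' its own native and alien pools (a square-level random effect on
#' inclusion odds), so both species and square-within-species variance
#' components exist for the mixed-model stage.
#'
#' @param species species table with `status`.
#' @param cfg a [sim_config()] object.
#' @param seed integer seed.
#' @return occurrence table: columns `square`, `plot`, `species`.
#' @export
simulate_plots <- function(species, cfg = sim_config(), seed = cfg$seed) {
  natives <- species$species[species$status == "native"]
  aliens <- species$species[species$status != "native"]
  if (length(natives) < 1 || length(aliens) < 1) {
    stop("need at least one native and one alien species")
  }
  with_seed(seed, {
    w_nat <- stats::rlnorm(length(natives), 0, 1)
    w_ali <- stats::rlnorm(length(aliens), 0, 1)
    rows <- vector("list", cfg$n_squares * cfg$plots_per_square)
    idx <- 0L
    for (q in seq_len(cfg$n_squares)) {
      # square-level pools: shared composition within a square
      pool_nat <- sample(natives,
                         size = max(5L, min(length(natives),
                                            round(length(natives) * 0.1))),
                         prob = w_nat)
      pool_ali <- sample(aliens,
                         size = min(length(aliens),
                                    max(3L, round(length(aliens) * 0.08))),
                         prob = w_ali)
      for (p in seq_len(cfg$plots_per_square)) {
        n_nat <- 1L + rpois(1, max(cfg$plot_native_rate - 1, 0))
        n_ali <- min(1L + rpois(1, max(cfg$plot_alien_rate - 1, 0)),
                     cfg$plot_alien_max)
        sp <- c(sample(pool_nat, min(n_nat, length(pool_nat))),
                sample(pool_ali, min(n_ali, length(pool_ali))))
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          square = sprintf("sq%03d", q),
          plot = sprintf("sq%03d_p%02d", q, p),
          species = sp, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a hectad richness grid
#'
#' Two richness surfaces (invasive and non-invasive alien richness) on a
#' square grid of cell centroids: a shared Gaussian random field with
#' exponential covariance (range `spatial_range`) mixed with independent
#' fields at weight `shared_weight`, passed through a log link to Poisson
#' counts.  The cells with the lowest shared-field values (fraction
#' `uninvaded_frac`) are rendered unsuitable, giving doubly-empty cells
#' that downstream analysis must drop.
#'
#' @param cfg a [sim_config()] object.
#' @param seed integer seed.
#' @return data frame: `x`, `y`, `richness_invasive`,
#'   `richness_noninvasive`.
#' @export
simulate_hectad_grid <- function(cfg = sim_config(), seed = cfg$seed) {
  if (cfg$grid_side < 3) stop("grid_side must be >= 3")
  g <- cfg$grid_side
  xy <- expand.grid(x = seq_len(g), y = seq_len(g))
  n <- nrow(xy)
  with_seed(seed, {
    Z <- gaussian_field(xy, cfg$spatial_range, 3)
    w <- cfg$shared_weight
    lat_inv <- w * Z[, 1] + sqrt(1 - w^2) * Z[, 2]
    lat_non <- w * Z[, 1] + sqrt(1 - w^2) * Z[, 3]
    sdl <- cfg$richness_sd %||% 1.3
    mu_inv <- log(cfg$mean_richness_invasive) - sdl^2 / 2
    mu_non <- log(cfg$mean_richness_noninvasive) - sdl^2 / 2
    ri <- rpois(n, exp(mu_inv + sdl * lat_inv))
    rn <- rpois(n, exp(mu_non + sdl * lat_non))
    if (cfg$uninvaded_frac > 0) {
      k <- round(cfg$uninvaded_frac * n)
      if (k > 0) {
        bad <- order(Z[, 1])[seq_len(k)]
        ri[bad] <- 0L
        rn[bad] <- 0L
      }
    }
    data.frame(x = xy$x, y = xy$y, richness_invasive = ri,
               richness_noninvasive = rn)
  })
}

# m independent draws of a zero-mean unit-variance Gaussian field with
# exponential covariance exp(-d / range) at the given coordinates
gaussian_field <- function(coords, range, m = 1) {
  n <- nrow(coords)
  if (range <= 1e-9) return(matrix(rnorm(n * m), n, m))
  S <- exp(-as.matrix(dist(coords)) / range)
  L <- chol(S + diag(1e-8, n))
  crossprod(L, matrix(rnorm(n * m), n, m))
}

#' Generate a complete synthetic flora bundle
#'
#' Runs every generator with child seeds derived from the configured root
#' seed: tree, status labels, traits, plot assemblages, hectad grid.
#'
#' @param cfg a [sim_config()] object.
#' @return list with elements `tree`, `species`, `plots`, `grid`, `config`.
#' @export
simulate_flora <- function(cfg = sim_config()) {
  tree <- simulate_tree(cfg$n_tips, cfg$tree_depth,
                        seed = child_seed(cfg$seed, "tree"))
  species <- assign_status(tree, cfg, seed = child_seed(cfg$seed, "status"))
  species <- simulate_traits(tree, species, cfg,
                             seed = child_seed(cfg$seed, "traits"))
  plots <- simulate_plots(species, cfg,
                          seed = child_seed(cfg$seed, "plots"))
  grid <- simulate_hectad_grid(cfg, seed = child_seed(cfg$seed, "grid"))
  list(tree = tree, species = species, plots = plots, grid = grid,
       config = cfg)
}

#' Write a flora bundle to disk
#'
#' Newick for the tree, CSV for the species table, plot occurrences and
#' hectad grid.
#'
#' @param flora a [simulate_flora()] bundle (or a compatible list).
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_flora <- function(flora, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             species = file.path(dir, "species.csv"),
             plots = file.path(dir, "plots.csv"),
             grid = file.path(dir, "grid.csv"))
  write_newick(flora$tree, paths["tree"])
  utils::write.csv(flora$species, paths["species"], row.names = FALSE)
  utils::write.csv(flora$plots, paths["plots"], row.names = FALSE)
  utils::write.csv(flora$grid, paths["grid"], row.names = FALSE)
  invisible(paths)
}
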