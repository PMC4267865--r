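small_cfg <- function(seed = 1, ...) {
  args <- list(n_tips = 200, n_squares = 15, plots_per_square = 8,
               grid_side = 12, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

test_that("simulated trees are binary, ultrametric and deterministic", {
  expect_error(simulate_tree(1, 10), "n_tips")
  t2 <- simulate_tree(2, 10, seed = 1)
  expect_equal(unname(t2$edge.length), c(10, 10))
  tr <- simulate_tree(100, 121, seed = 1)
  expect_true(ape::is.binary(tr))
  chk <- check_ultrametric(tr, tol = 1e-9)
  expect_true(chk$ultrametric)
  expect_equal(max(ape::node.depth.edgelength(tr)[1:100]), 121,
               tolerance = 1e-9)
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_tree(100, 121, seed = 1)))
  expect_false(identical(ape::write.tree(tr),
                         ape::write.tree(simulate_tree(100, 121,
                                                       seed = 2))))
})

test_that("status prevalences are honoured exactly", {
  cfg <- sim_config(n_tips = 1612, seed = 2)
  tr <- simulate_tree(30, 10, seed = 2)   # small tree for speed
  # largest-remainder rounding at the study's prevalences on the full
  # tip count gives the exact published class sizes
  counts <- phynat:::largest_remainder(
    1612, c(1249 / 1612, 274 / 1612, 89 / 1612))
  expect_identical(counts, c(1249L, 274L, 89L))

  sp <- assign_status(tr, small_cfg(seed = 3), seed = 3)
  expect_equal(sort(unique(sp$status)),
               sort(c("native", "non-invasive alien", "invasive alien")))
  tab <- table(sp$status)
  expect_identical(
    unname(as.integer(tab[c("native", "non-invasive alien",
                            "invasive alien")])),
    phynat:::largest_remainder(30, c(1249, 274, 89) / 1612))
  # aliens get a group label, natives do not
  expect_true(all(is.na(sp$alien_group[sp$status == "native"])))
  expect_true(all(sp$alien_group[sp$status != "native"] %in%
                    c("archaeophyte", "neophyte")))
  # determinism
  expect_identical(sp, assign_status(tr, small_cfg(seed = 3), seed = 3))
})

test_that("brownian-threshold status clusters invasiveness on the tree", {
  cfg_b <- small_cfg(seed = 4, trait_signal_mode = "brownian_threshold")
  cfg_r <- small_cfg(seed = 4, trait_signal_mode = "random")
  tr <- simulate_tree(200, 100, seed = 4)
  # mean D over replicates: ~1 under random labels, ~0 under the
  # Brownian threshold mode (a reduced-size version of the acceptance
  # calibration)
  mean_d <- function(cfg, n_rep = 20) {
    mean(vapply(seq_len(n_rep), function(i) {
      sp <- assign_status(tr, cfg, seed = 100 + i)
      aliens <- sp[sp$status != "native", ]
      sub <- ape::keep.tip(tr, aliens$species)
      trait <- setNames(as.integer(aliens$status == "invasive alien"),
                        aliens$species)
      d_statistic(sub, trait, n = 300, seed = i)$D
    }, numeric(1)))
  }
  expect_lt(abs(mean_d(cfg_r) - 1), 0.25)
  expect_lt(abs(mean_d(cfg_b)), 0.25)
})

test_that("traits carry phylogenetic signal and honour degenerate rates", {
  cfg <- small_cfg(seed = 5)
  tr <- simulate_tree(200, 100, seed = 5)
  sp <- assign_status(tr, cfg, seed = 6)
  traits <- simulate_traits(tr, sp, cfg, seed = 7)
  expect_true(all(traits$L %in% 1:9))
  expect_true(all(traits$S %in% 0:9))
  expect_true(all(traits$height > 0))
  expect_true(all(traits$clonal %in% 0:1))
  expect_true(all(is.na(traits$change_index[traits$status == "native"])))
  expect_false(anyNA(traits$change_index[traits$status != "native"]))
  # determinism
  expect_identical(traits, simulate_traits(tr, sp, cfg, seed = 7))
  # zero Brownian rate: every tip inherits the root value
  flat <- simulate_traits(tr, sp, cfg, seed = 8, bm_sigma = 0)
  expect_equal(length(unique(flat$L)), 1)

  # sister tips are more similar than random pairs (Brownian variance
  # grows with distance); averaged over replicate trait draws
  dm <- distance_matrix(tr)
  diag(dm) <- Inf
  sisters <- which(dm < quantile(dm[is.finite(dm)], 0.01),
                   arr.ind = TRUE)
  sisters <- sisters[sisters[, 1] < sisters[, 2], , drop = FALSE]
  diffs <- replicate(30, {
    tt <- simulate_traits(tr, sp, cfg, seed = sample.int(1e6, 1))
    f <- as.numeric(tt$F)[match(tr$tip.label, tt$species)]
    far <- cbind(sample(200, nrow(sisters), replace = TRUE),
                 sample(200, nrow(sisters), replace = TRUE))
    c(mean(abs(f[sisters[, 1]] - f[sisters[, 2]])),
      mean(abs(f[far[, 1]] - f[far[, 2]])))
  })
  expect_lt(mean(diffs[1, ]), mean(diffs[2, ]))
})

test_that("trait-driven invasiveness follows the logistic model", {
  cfg <- small_cfg(seed = 9)
  tr <- simulate_tree(1200, 100, seed = 9)
  sp <- assign_status(tr, sim_config(n_tips = 1200,
                                     prevalence_native = 0.1,
                                     prevalence_noninvasive = 0.6,
                                     prevalence_invasive = 0.3,
                                     seed = 9), seed = 10)
  sp <- simulate_traits(tr, sp, cfg, seed = 11)
  # null model: invasive fraction ~ 0.5
  sp0 <- simulate_invasiveness_from_traits(
    sp, c(`(Intercept)` = 0), seed = 12)
  frac <- mean(sp0$status[sp0$status != "native"] == "invasive alien")
  expect_lt(abs(frac - 0.5), 0.05)
  # single-variable effect recovered within 2 SE
  sp1 <- simulate_invasiveness_from_traits(
    sp, c(`(Intercept)` = 0, N = 1), seed = 13)
  aliens <- sp1[sp1$status != "native", ]
  fit <- glm(I(status == "invasive alien") ~ N, binomial(),
             data = aliens)
  se <- sqrt(diag(vcov(fit)))["N"]
  expect_lt(abs(coef(fit)["N"] - 1), 2 * se)
  expect_error(
    simulate_invasiveness_from_traits(sp, c(nope = 1)), "unknown col")
})

test_that("plots always contain a native and an alien at the target rate", {
  cfg <- small_cfg(seed = 14, n_squares = 40, plots_per_square = 15)
  tr <- simulate_tree(200, 100, seed = 14)
  sp <- assign_status(tr, cfg, seed = 15)
  plots <- simulate_plots(sp, cfg, seed = 16)
  st <- setNames(sp$status, sp$species)
  key <- paste(plots$square, plots$plot)
  has_native <- tapply(st[plots$species] == "native", key, any)
  has_alien <- tapply(st[plots$species] != "native", key, any)
  expect_true(all(has_native))
  expect_true(all(has_alien))
  aliens_per_plot <- tapply(st[plots$species] != "native", key, sum)
  expect_lt(abs(mean(aliens_per_plot) - 1.53), 0.2)
  expect_lte(max(aliens_per_plot), 12)
  expect_identical(plots, simulate_plots(sp, cfg, seed = 16))
})

test_that("hectad grids are congruent, non-negative and seeded", {
  cfg <- small_cfg(seed = 17, grid_side = 20)
  grid <- simulate_hectad_grid(cfg, seed = 18)
  expect_equal(nrow(grid), 400)
  expect_true(all(grid$richness_invasive >= 0))
  expect_true(all(grid$richness_noninvasive >= 0))
  expect_false(anyDuplicated(grid[c("x", "y")]) > 0)
  expect_identical(grid, simulate_hectad_grid(cfg, seed = 18))
  # strong shared field: congruence typically high (averaged over
  # draws, since one small grid holds few independent spatial patches)
  rhos <- vapply(1:5, function(i) {
    g <- simulate_hectad_grid(cfg, seed = 100 + i)
    g <- drop_empty_cells(g)
    spearman_rho(g$richness_invasive, g$richness_noninvasive)
  }, numeric(1))
  expect_gt(mean(rhos), 0.8)
  # no spatial structure and no shared field: correlation collapses
  cfg0 <- small_cfg(seed = 19, grid_side = 20, spatial_range = 1e-12,
                    shared_weight = 0)
  g0 <- simulate_hectad_grid(cfg0, seed = 19)
  expect_lt(abs(spearman_rho(g0$richness_invasive,
                             g0$richness_noninvasive)), 0.15)
})

test_that("the flora bundle is reproducible and writeable", {
  cfg <- small_cfg(seed = 20)
  fl <- simulate_flora(cfg)
  fl2 <- simulate_flora(cfg)
  expect_identical(ape::write.tree(fl$tree), ape::write.tree(fl2$tree))
  expect_identical(fl$species, fl2$species)
  expect_identical(fl$plots, fl2$plots)
  expect_identical(fl$grid, fl2$grid)
  dir <- tempfile()
  paths <- write_flora(fl, dir)
  expect_true(all(file.exists(paths)))
  back <- read_newick(paths[["tree"]])
  expect_equal(sort(back$tip.label), sort(fl$tree$tip.label))
})
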