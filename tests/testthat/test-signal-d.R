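test_that("contrast sum matches hand values on tiny trees", {
  # single contrast |1 - 0| regardless of branch lengths
  expect_equal(contrast_sum(read_newick("(A:1,B:3);"), c(A = 1, B = 0)), 1)
  expect_equal(contrast_sum(read_newick("(A:9,B:0.1);"), c(A = 0, B = 1)), 1)
  # perfect clade split on a symmetric 4-tip tree: only the root
  # contrast is nonzero
  expect_equal(contrast_sum(tree_abcd(), c(A = 1, B = 1, C = 0, D = 0)), 1)
  expect_error(contrast_sum(tree_abcd(), c(A = 1, B = 1, C = 1, D = 1)),
               "monomorphic")
})

test_that("contrast sum equals the recursive down-pass oracle", {
  set.seed(4)
  for (i in 1:20) {
    tr <- simulate_tree(8, 10, seed = i)
    x <- setNames(sample(c(0, 1), 8, replace = TRUE), tr$tip.label)
    if (length(unique(x)) < 2) x[1] <- 1 - x[1]
    expect_equal(contrast_sum(tr, x), bf_contrast_sum(tr, x),
                 tolerance = 1e-12)
    # invariance under 0 <-> 1 relabelling
    expect_equal(contrast_sum(tr, x), contrast_sum(tr, 1 - x),
                 tolerance = 1e-12)
  }
})

test_that("contrast sum works through polytomies and zero branches", {
  tr <- read_newick("((A:1,B:1,C:1):1,(D:0,E:2):2);")
  x <- c(A = 1, B = 0, C = 1, D = 0, E = 1)
  expect_gt(contrast_sum(tr, x), 0)
  expect_equal(contrast_sum(tr, x), bf_contrast_sum(tr, x),
               tolerance = 1e-9)
})

test_that("permutation null preserves prevalence and its exact mean", {
  tr <- read_newick("(A:1,B:1);")
  d <- permutation_null(tr, c(A = 1, B = 0), n = 50, seed = 1)
  expect_true(all(d == 1))

  tr5 <- simulate_tree(5, 10, seed = 2)
  x <- setNames(c(1, 1, 0, 0, 0), tr5$tip.label)
  # exact mean over all C(5,2) = 10 labelings
  combos <- combn(5, 2)
  exact <- mean(apply(combos, 2, function(idx) {
    z <- numeric(5)
    z[idx] <- 1
    contrast_sum(tr5, setNames(z, tr5$tip.label))
  }))
  emp <- mean(permutation_null(tr5, x, n = 10000, seed = 3))
  expect_lt(abs(emp - exact) / exact, 0.02)
})

test_that("Brownian null thresholds at exact prevalence and shrinks with depth", {
  tr <- simulate_tree(40, 20, seed = 6)
  star <- ape::stree(40, type = "star")
  star$edge.length <- rep(20, 40)
  star$tip.label <- tr$tip.label

  # prevalence is exact in every replicate: on a fully symmetric
  # balanced tree every k=1 labelling has the same contrast sum, so the
  # null draws are constant iff exactly one tip is in state 1 each time
  bal <- ape::stree(32, type = "balanced")
  bal$edge.length <- rep(1, nrow(bal$edge))
  d1 <- brownian_null(bal, k = 1, n = 200, seed = 7)
  expect_equal(max(d1) - min(d1), 0, tolerance = 1e-9)

  # star phylogeny: no shared branches, Brownian liabilities are iid, so
  # the Brownian null coincides with the permutation null
  x <- setNames(rep(c(1, 0), each = 20), star$tip.label)
  db <- brownian_null(star, k = 20, n = 3000, seed = 8)
  dp <- permutation_null(star, x, n = 3000, seed = 9)
  expect_lt(abs(mean(db) - mean(dp)) / mean(dp), 0.05)

  # shared ancestry clusters liabilities: deeper trees give smaller mean d
  db_tree <- brownian_null(tr, k = 20, n = 2000, seed = 10)
  expect_lt(mean(db_tree), mean(db))
})

test_that("D statistic is calibrated at its anchors on a synthetic tree", {
  tr <- simulate_tree(120, 100, seed = 12)
  # a modest replicate budget here; the full 500-replicate calibration
  # runs in the acceptance suite
  Ds_rand <- vapply(1:30, function(i) {
    x <- numeric(120)
    set.seed(100 + i)
    x[sample(120, 30)] <- 1
    d_statistic(tr, setNames(x, tr$tip.label), n = 400, seed = i)$D
  }, numeric(1))
  expect_lt(abs(mean(Ds_rand) - 1), 0.15)

  Ds_br <- vapply(1:30, function(i) {
    z <- brownian_null(tr, k = 30, n = 1, seed = 500 + i)
    # build one Brownian-threshold labelling directly
    set.seed(700 + i)
    lia <- drop(phynat:::simulate_bm_matrix(tr, 1))
    x <- numeric(120)
    x[order(lia, decreasing = TRUE)[1:30]] <- 1
    d_statistic(tr, setNames(x, tr$tip.label), n = 400, seed = i)$D
  }, numeric(1))
  expect_lt(abs(mean(Ds_br)), 0.15)
})

test_that("d_statistic reports oriented p-values and handles degeneracy", {
  tr <- simulate_tree(80, 50, seed = 13)
  # strongly clustered trait: one clade entirely state 1
  sub <- ape::extract.clade(tr, ape::getMRCA(tr, tr$tip.label[1:2]))
  clade_tips <- sub$tip.label
  x <- setNames(as.integer(tr$tip.label %in% clade_tips), tr$tip.label)
  if (sum(x) < 2 || sum(x) > 78) x[1:2] <- c(1, 1)
  ds <- d_statistic(tr, x, n = 500, seed = 14)
  expect_lt(ds$D, 1)
  expect_lt(ds$P_random, 0.2)
  expect_true(ds$P_random >= 0 && ds$P_random <= 1)
  expect_true(ds$P_brownian >= 0 && ds$P_brownian <= 1)
  expect_false(ds$undefined)
})

test_that("d_by_group prunes to the group's tips before computing D", {
  cfg <- sim_config(n_tips = 150, seed = 15)
  tr <- simulate_tree(150, 100, seed = 15)
  sp <- assign_status(tr, cfg, seed = 16)
  tab <- d_by_group(tr, sp, n = 300, seed = 17)
  expect_equal(tab$group, c("all_aliens", "neophytes", "archaeophytes"))
  aliens <- sp[sp$status != "native", ]
  expect_equal(tab$n_invasive[1], sum(aliens$status == "invasive alien"))
  expect_equal(tab$n_invasive[2] + tab$n_invasive[3], tab$n_invasive[1])

  # pruning: D for a group is unaffected by tips outside the group
  neo <- aliens[aliens$alien_group == "neophyte", ]
  sub <- ape::keep.tip(tr, neo$species)
  trait <- setNames(as.integer(neo$status == "invasive alien"),
                    neo$species)
  ds <- d_statistic(sub, trait, n = 300,
                    seed = child_seed(17, "neophytes"))
  expect_equal(tab$D[tab$group == "neophytes"], ds$D, tolerance = 1e-12)
})
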