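## Fritz-Purvis D: phylogenetic signal of a binary trait.
##
## The statistic rescales the observed sum of sister-clade differences in
## estimated nodal values (d_obs) between two anchors obtained by
## simulation on the same tree at the same prevalence:
##   D = (d_obs - mean d_Brownian) / (mean d_random - mean d_Brownian)
## so that D ~ 1 when the trait is shuffled at random across tips and
## D ~ 0 when it arises by thresholding a Brownian liability.

# Precompute the traversal tables used by the vectorised down-pass.
# Polytomies are resolved to zero-length bifurcations (deterministic,
# random = FALSE) and zero-length branches are replaced by a small
# epsilon relative to the mean positive branch length, so the
# 1/branch-length weights of the contrasts down-pass are defined.
d_prep <- function(tree, epsilon_frac = 1e-8) {
  validate_tree(tree)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  ntip <- ape::Ntip(tree)
  el <- tree$edge.length
  pos <- el[el > 0]
  eps <- if (length(pos)) epsilon_frac * mean(pos) else epsilon_frac
  el[el <= 0] <- eps
  po <- ape::reorder.phylo(tree, "postorder")
  el_po <- po$edge.length
  el_po[el_po <= 0] <- eps
  parents <- po$edge[, 1]
  order_nodes <- unique(parents)      # children always precede parents
  ch <- matrix(0L, length(order_nodes), 2L)
  bl <- matrix(0, length(order_nodes), 2L)
  for (i in seq_along(order_nodes)) {
    j <- which(parents == order_nodes[i])
    ch[i, ] <- po$edge[j, 2]
    bl[i, ] <- el_po[j]
  }
  list(tree = tree, ntip = ntip, nnode = tree$Nnode,
       order_nodes = order_nodes, children = ch, child_bl = bl,
       tip_label = tree$tip.label)
}

# Sum of absolute sister differences in nodal values for each column of X
# (tips x replicates), nodal values estimated by the 1/branch-length
# weighted averaging of Felsenstein's contrasts algorithm, with the usual
# branch-length extension as the pruning proceeds.
contrast_sum_matrix <- function(prep, X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == prep$ntip)
  R <- ncol(X)
  ntot <- prep$ntip + prep$nnode
  V <- matrix(0, ntot, R)
  V[seq_len(prep$ntip), ] <- X
  vl <- numeric(ntot)           # adjusted length of the edge above a node
  d <- numeric(R)
  ch <- prep$children
  bl <- prep$child_bl
  for (i in seq_along(prep$order_nodes)) {
    c1 <- ch[i, 1L]; c2 <- ch[i, 2L]
    v1 <- bl[i, 1L] + vl[c1]
    v2 <- bl[i, 2L] + vl[c2]
    x1 <- V[c1, ]; x2 <- V[c2, ]
    d <- d + abs(x1 - x2)
    p <- prep$order_nodes[i]
    V[p, ] <- (x1 / v1 + x2 / v2) / (1 / v1 + 1 / v2)
    vl[p] <- v1 * v2 / (v1 + v2)
  }
  d
}

# Brownian tip values, one column per replicate, unit rate.
simulate_bm_matrix <- function(tree, R) {
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  V <- matrix(0, ntot, R)
  cw <- ape::reorder.phylo(tree, "cladewise")   # parents precede children
  for (j in seq_len(nrow(cw$edge))) {
    par <- cw$edge[j, 1]; chd <- cw$edge[j, 2]
    len <- cw$edge.length[j]
    V[chd, ] <- V[par, ] + if (len > 0) rnorm(R, 0, sqrt(len)) else 0
  }
  V[seq_len(ntip), , drop = FALSE]
}

as_trait01 <- function(prep, trait01) {
  if (is.logical(trait01)) trait01 <- as.integer(trait01)
  if (!is.null(names(trait01))) {
    idx <- match(prep$tip_label, names(trait01))
    if (anyNA(idx)) {
      stop("trait values missing for tips: ",
           paste(head(prep$tip_label[is.na(idx)], 5), collapse = ", "))
    }
    trait01 <- trait01[idx]
  } else if (length(trait01) != prep$ntip) {
    stop("unnamed trait vector must have one value per tip")
  }
  if (anyNA(trait01) || !all(trait01 %in% c(0, 1))) {
    stop("trait must be binary 0/1 with no missing values")
  }
  if (length(unique(trait01)) < 2L) {
    stop("monomorphic trait: D is undefined when only one state is present")
  }
  as.numeric(trait01)
}

#' Sum of sister-clade differences for a binary trait
#'
#' The observed quantity underlying the Fritz-Purvis D statistic: tips are
#' coded 0/1, nodal values are estimated by the branch-length-weighted
#' averaging down-pass of the independent-contrasts algorithm, and the
#' absolute differences between the two daughter values entering each
#' internal node are summed.  Invariant under swapping the 0/1 coding.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param trait01 binary (0/1 or logical) vector, named by tip label or in
#'   tip order.  Both states must be present.
#' @return the contrast sum (a nonnegative number).
#' @export
contrast_sum <- function(tree, trait01) {
  prep <- d_prep(tree)
  contrast_sum_matrix(prep, matrix(as_trait01(prep, trait01), ncol = 1))
}

#' Permutation null distribution of the contrast sum
#'
#' Contrast sums for `n` uniform random permutations of the observed 0/1
#' labels across the tips; prevalence is preserved exactly in every
#' replicate.
#'
#' @inheritParams contrast_sum
#' @param n number of permutations.
#' @param seed integer seed.
#' @return numeric vector of `n` contrast sums.
#' @export
permutation_null <- function(tree, trait01, n = 1000, seed = 1) {
  stopifnot(n >= 1)
  prep <- d_prep(tree)
  x <- as_trait01(prep, trait01)
  with_seed(seed, {
    X <- vapply(seq_len(n), function(i) sample(x), numeric(length(x)))
    contrast_sum_matrix(prep, X)
  })
}

#' Brownian-threshold null distribution of the contrast sum
#'
#' Per replicate, a unit-rate Brownian liability is simulated on the tree
#' and the `k` tips with the largest liabilities are set to state 1 (rank
#' thresholding, so the observed prevalence is preserved exactly); the
#' contrast sum of the resulting binary trait is returned.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param k number of state-1 tips per replicate (`1 <= k <= Ntip - 1`).
#' @param n number of replicates.
#' @param seed integer seed.
#' @return numeric vector of `n` contrast sums.
#' @export
brownian_null <- function(tree, k, n = 1000, seed = 1) {
  prep <- d_prep(tree)
  ntip <- prep$ntip
  stopifnot(n >= 1, k >= 1, k <= ntip - 1)
  with_seed(seed, {
    L <- simulate_bm_matrix(prep$tree, n)
    X <- apply(L, 2, function(z) {
      out <- numeric(ntip)
      out[order(z, decreasing = TRUE)[seq_len(k)]] <- 1
      out
    })
    contrast_sum_matrix(prep, X)
  })
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' Scales the observed contrast sum between its expectations under two
#' null models on the same tree at the same prevalence: random shuffling
#' of the labels across tips (`D = 1`) and a Brownian threshold model
#' (`D = 0`).  `D < 1` indicates the trait is more phylogenetically
#' clustered than random; `D > 1`, more overdispersed.
#'
#' `P_random` is the proportion of permutation-null contrast sums less
#' than or equal to the observed one (small when the trait is clustered);
#' `P_brownian` is the proportion of Brownian-null contrast sums greater
#' than or equal to the observed one (small when clustering is even
#' stronger than Brownian).
#'
#' @inheritParams contrast_sum
#' @param n number of randomizations for each null.
#' @param seed integer seed.
#' @return an object of class `phynat_dstat`: list with `n_state1`,
#'   `n_state0`, `d_obs`, `mean_d_random`, `mean_d_brownian`, `D`,
#'   `P_random`, `P_brownian`, `n_randomizations`, `seed`, `undefined`.
#' @export
d_statistic <- function(tree, trait01, n = 10000, seed = 1) {
  prep <- d_prep(tree)
  x <- as_trait01(prep, trait01)
  k <- sum(x == 1)
  d_obs <- contrast_sum_matrix(prep, matrix(x, ncol = 1))
  d_rand <- permutation_null(tree, x, n = n, seed = child_seed(seed, "perm"))
  d_brow <- brownian_null(tree, k, n = n, seed = child_seed(seed, "brownian"))
  mr <- mean(d_rand)
  mb <- mean(d_brow)
  denom <- mr - mb
  undefined <- abs(denom) < 1e-12 * max(abs(mr), abs(mb), 1)
  out <- list(
    n_state1 = k, n_state0 = length(x) - k,
    d_obs = d_obs,
    mean_d_random = mr, mean_d_brownian = mb,
    D = if (undefined) NA_real_ else (d_obs - mb) / denom,
    P_random = mean(d_rand <= d_obs),
    P_brownian = mean(d_brow >= d_obs),
    n_randomizations = n, seed = seed, undefined = undefined)
  class(out) <- "phynat_dstat"
  out
}

#' @export
print.phynat_dstat <- function(x, ...) {
  cat(sprintf(
    "Fritz-Purvis D: %.3f  (n1 = %d, n0 = %d, %d randomizations)\n",
    x$D, x$n_state1, x$n_state0, x$n_randomizations))
  cat(sprintf("  d_obs = %.3f, E[d|random] = %.3f, E[d|Brownian] = %.3f\n",
              x$d_obs, x$mean_d_random, x$mean_d_brownian))
  cat(sprintf("  P(random) = %.4g, P(Brownian) = %.4g\n",
              x$P_random, x$P_brownian))
  invisible(x)
}

#' D statistic of invasiveness within alien groups
#'
#' Computes D for the invasive / non-invasive contrast among all
#' naturalized aliens, among neophytes, and among archaeophytes; each
#' group's tree is pruned to the group's tips before the statistic is
#' computed.  Groups in which only one state is present in the tree are
#' skipped with a warning.
#'
#' @param tree a `phylo` object covering (at least) the alien species.
#' @param species a species table as produced by [assign_status()]:
#'   columns `species`, `status`, `alien_group`.
#' @param n randomizations per group.
#' @param seed integer seed.
#' @return data frame with one row per group: `group`, `n_invasive`,
#'   `n_noninvasive`, `D`, `P_random`, `P_brownian`.
#' @export
d_by_group <- function(tree, species, n = 10000, seed = 1) {
  stopifnot(all(c("species", "status") %in% names(species)))
  aliens <- species[species$status != "native", , drop = FALSE]
  groups <- list(
    all_aliens = aliens,
    neophytes = aliens[!is.na(aliens$alien_group) &
                         aliens$alien_group == "neophyte", , drop = FALSE],
    archaeophytes = aliens[!is.na(aliens$alien_group) &
                             aliens$alien_group == "archaeophyte", ,
                           drop = FALSE])
  rows <- lapply(names(groups), function(g) {
    tab <- groups[[g]]
    tab <- tab[normalize_labels(tab$species) %in%
                 normalize_labels(tree$tip.label), , drop = FALSE]
    inv <- tab$status == "invasive alien"
    res <- data.frame(group = g, n_invasive = sum(inv),
                      n_noninvasive = sum(!inv), D = NA_real_,
                      P_random = NA_real_, P_brownian = NA_real_)
    if (sum(inv) < 1 || sum(!inv) < 1) {
      warning("group '", g, "' has a single invasiveness state; skipped")
      return(res)
    }
    sub <- ape::keep.tip(tree, tab$species)
    trait <- setNames(as.integer(inv), tab$species)
    ds <- d_statistic(sub, trait, n = n, seed = child_seed(seed, g))
    res$D <- ds$D
    res$P_random <- ds$P_random
    res$P_brownian <- ds$P_brownian
    res
  })
  do.call(rbind, rows)
}

#' Reproduce the phylogenetic-signal table from external data
#'
#' Convenience wrapper for re-running the invasiveness signal analysis on
#' an externally supplied dated tree and status classification (e.g. an
#' archived flora phylogeny and its species status list), producing the
#' per-group D table.
#'
#' @param tree_path newick file of the dated phylogeny.
#' @param status_path CSV with columns `species`, `status`
#'   (`native` / `non-invasive alien` / `invasive alien`) and
#'   `alien_group` (`archaeophyte` / `neophyte`).
#' @param n randomizations per group.
#' @param seed integer seed.
#' @return the [d_by_group()] data frame.
#' @export
reproduce_signal_table <- function(tree_path, status_path, n = 10000,
                                   seed = 1) {
  tree <- read_newick(tree_path)
  species <- utils::read.csv(status_path, stringsAsFactors = FALSE)
  d_by_group(tree, species, n = n, seed = seed)
}
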