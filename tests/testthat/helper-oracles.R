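# Independent brute-force oracles used across the suite.

# patristic distance by explicit path walking: climb parent pointers from
# each tip to the root and sum branch lengths over the symmetric
# difference of the two root paths
bf_patristic <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  ntot <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(ntot)
  plen <- numeric(ntot)
  for (j in seq_len(nrow(tree$edge))) {
    parent[tree$edge[j, 2]] <- tree$edge[j, 1]
    plen[tree$edge[j, 2]] <- tree$edge.length[j]
  }
  path_up <- function(i) {
    nodes <- integer()
    while (parent[i] != 0L) {
      nodes <- c(nodes, i)
      i <- parent[i]
    }
    nodes
  }
  pa <- path_up(ia)
  pb <- path_up(ib)
  sum(plen[setdiff(pa, pb)]) + sum(plen[setdiff(pb, pa)])
}

bf_distance_matrix <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  m <- matrix(0, n, n, dimnames = list(tips, tips))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- bf_patristic(tree, tips[i], tips[j])
    }
  }
  m
}

# recursive (non-vectorised) implementation of the weighted contrasts
# down-pass and sister-difference sum
bf_contrast_sum <- function(tree, x01) {
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  el <- tree$edge.length
  pos <- el[el > 0]
  el[el <= 0] <- if (length(pos)) 1e-8 * mean(pos) else 1e-8
  n <- ape::Ntip(tree)
  val <- numeric(n + tree$Nnode)
  vlen <- numeric(n + tree$Nnode)
  val[seq_len(n)] <- x01[tree$tip.label]
  total <- 0
  recurse <- function(node) {
    rows <- which(tree$edge[, 1] == node)
    ch <- tree$edge[rows, 2]
    for (k in ch) if (k > n) recurse(k)
    b <- el[rows] + vlen[ch]
    total <<- total + abs(val[ch[1]] - val[ch[2]])
    val[node] <<- sum(val[ch] / b) / sum(1 / b)
    vlen[node] <<- prod(b) / sum(b)
  }
  recurse(n + 1L)
  total
}

# small ultrametric fixtures
tree_abc <- function() read_newick("((A:1,B:1):1,C:2);")
tree_abcd <- function() read_newick("((A:1,B:1):1,(C:1,D:1):1);")

# survey records with known variance components, for LMM recovery
simulate_lmm_survey <- function(n_species = 50, n_squares = 12,
                                obs_per_square = 5, var_species = 100,
                                var_square = 25, var_res = 50,
                                effect = 0, seed = 1) {
  set.seed(seed)
  species <- sprintf("al%03d", seq_len(n_species))
  invasive <- rep(c(TRUE, FALSE), length.out = n_species)
  b_sp <- rnorm(n_species, 0, sqrt(var_species))
  rows <- list()
  for (i in seq_len(n_species)) {
    squares <- sample(sprintf("sq%03d", 1:40), n_squares)
    b_sq <- rnorm(n_squares, 0, sqrt(var_square))
    for (j in seq_len(n_squares)) {
      y <- 200 + effect * invasive[i] + b_sp[i] + b_sq[j] +
        rnorm(obs_per_square, 0, sqrt(var_res))
      rows[[length(rows) + 1]] <- data.frame(
        species = species[i], square = squares[j],
        plot = paste0(squares[j], "_", seq_len(obs_per_square)),
        pnnd = y, mpd = y, invasive = invasive[i],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
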