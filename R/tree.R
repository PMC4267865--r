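#' Read a dated phylogeny from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' downstream analyses rely on: every tip uniquely labelled and every edge
#' carrying a branch length (in millions of years for a dated tree).
#' Polytomies are retained; all distance computations in the package are
#' polytomy-safe.
#'
#' @param path path to a newick file (or a newick string ending in ";").
#' @return an object of class `phylo`.
#' @export
read_newick <- function(path) {
  is_string <- grepl(";", path, fixed = TRUE)
  if (!is_string && !file.exists(path)) {
    stop("newick file not found: ", path)
  }
  txt <- if (is_string) path else paste(readLines(path, warn = FALSE),
                                        collapse = "")
  # cheap structural check so malformed input fails with a position
  bal <- cumsum((strsplit(txt, "")[[1]] == "(") -
                  (strsplit(txt, "")[[1]] == ")"))
  if (any(bal < 0)) {
    stop("malformed newick: unbalanced ')' at character ",
         which(bal < 0)[1])
  }
  if (length(bal) && bal[length(bal)] != 0) {
    stop("malformed newick: ", bal[length(bal)],
         " unclosed '(' by character ", length(bal))
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error: no tree read")
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; dated branch lengths are required")
  }
  if (anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths on ",
         sum(is.na(tree$edge.length)), " edge(s)")
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) {
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  }
  invisible(tree)
}

#' Write a phylogeny to newick
#'
#' @param tree a `phylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Check whether a tree is ultrametric
#'
#' A dated tree must have all tips equidistant from the root.  Deviation is
#' measured as the range of root-to-tip path lengths relative to the
#' maximum depth.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param tol relative tolerance on root-to-tip depth spread.
#' @return list with `ultrametric` (logical) and `max_deviation`
#'   (absolute depth spread, same units as the branch lengths).
#' @export
check_ultrametric <- function(tree, tol = 1e-8) {
  validate_tree(tree)
  depths <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  dev <- max(depths) - min(depths)
  list(ultrametric = dev <= tol * max(depths, .Machine$double.eps),
       max_deviation = dev)
}

# root-to-node path lengths for all nodes (tips first, ape numbering)
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Patristic distance between two tips
#'
#' Total intervening branch length between two tips, computed as
#' `depth(a) + depth(b) - 2 * depth(mrca(a, b))`.  Valid on any rooted
#' tree with branch lengths, including trees with polytomies and
#' zero-length edges.
#'
#' @param tree a `phylo` object.
#' @param a,b tip labels.
#' @return distance in the units of the branch lengths (My for dated
#'   trees).
#' @export
patristic_distance <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia)) stop("unknown tip: ", a)
  if (is.na(ib)) stop("unknown tip: ", b)
  if (ia == ib) return(0)
  depths <- node_depths(tree)
  anc <- ape::getMRCA(tree, c(ia, ib))
  depths[ia] + depths[ib] - 2 * depths[anc]
}

#' Patristic distance matrix
#'
#' All pairwise tip-to-tip path lengths in a single traversal
#' ([ape::cophenetic.phylo()]), optionally restricted to a subset of tips.
#'
#' @param tree a `phylo` object.
#' @param subset optional character vector of tip labels.
#' @return symmetric numeric matrix with zero diagonal, labelled by tip.
#' @export
distance_matrix <- function(tree, subset = NULL) {
  validate_tree(tree)
  dm <- ape::cophenetic.phylo(tree)
  if (!is.null(subset)) {
    if (length(subset) == 0L) stop("empty tip subset")
    missing <- setdiff(subset, tree$tip.label)
    if (length(missing)) {
      stop("tips not in tree: ", paste(head(missing, 5), collapse = ", "))
    }
    dm <- dm[subset, subset, drop = FALSE]
  }
  dm
}

#' Normalize species labels for tree/table matching
#'
#' One documented normalization only: trim surrounding whitespace, collapse
#' internal runs of whitespace, and map spaces to underscores (the newick
#' convention).  Matching elsewhere is exact string equality after this.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
normalize_labels <- function(x) {
  x <- gsub("^\\s+|\\s+$", "", x)
  x <- gsub("\\s+", " ", x)
  gsub(" ", "_", x, fixed = TRUE)
}

#' Match a species table to tree tips, reporting coverage
#'
#' Species absent from the tree are reported, never silently dropped: the
#' return value carries per-status coverage so incomplete phylogenies are
#' visible in every run report.
#'
#' @param tree a `phylo` object.
#' @param species a species table with a `species` column and optionally a
#'   `status` column.
#' @return list with `matched` (species present as tips), `unmatched`
#'   (species absent from the tree), `extra_tips` (tips without table
#'   rows), and `coverage` (fraction matched, overall and by status).
#' @export
match_species <- function(tree, species) {
  stopifnot(is.data.frame(species), "species" %in% names(species))
  tips <- normalize_labels(tree$tip.label)
  labs <- normalize_labels(species$species)
  hit <- labs %in% tips
  cov <- c(overall = mean(hit))
  if ("status" %in% names(species)) {
    by_status <- tapply(hit, species$status, mean)
    cov <- c(cov, by_status)
  }
  list(matched = species$species[hit],
       unmatched = species$species[!hit],
       extra_tips = tree$tip.label[!(tips %in% labs)],
       coverage = cov)
}
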