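## PNND and MPD: relatedness of each alien to a native assemblage.

#' Phylogenetic nearest-neighbour distance of an alien to a native set
#'
#' Minimum patristic distance from the focal alien to any member of the
#' native set.  Ties for the nearest native are broken by lexicographic
#' tip label, and all tied natives are recorded.
#'
#' @param tree a `phylo` object.
#' @param alien focal tip label.
#' @param natives character vector of native tip labels (non-empty, not
#'   containing `alien`).
#' @param dm optional precomputed patristic distance matrix (rows/columns
#'   labelled by tip) to avoid repeated traversals.
#' @return list with `pnnd`, `nearest_native` (deterministic
#'   representative), `tied` (all argmin labels).
#' @export
pnnd <- function(tree, alien, natives, dm = NULL) {
  if (length(natives) == 0L) stop("empty native set")
  if (alien %in% natives) stop("alien occurs in the native set")
  if (is.null(dm)) dm <- distance_matrix(tree, c(alien, natives))
  row <- dm[alien, natives]
  m <- min(row)
  tied <- sort(names(row)[row <= m + 1e-12])
  list(pnnd = m, nearest_native = tied[1], tied = tied)
}

#' Mean phylogenetic distance of an alien to a native set
#'
#' Arithmetic mean of the patristic distances from the focal alien to
#' every member of the native set (one focal species against a set, not
#' the community all-pairs MPD).
#'
#' @inheritParams pnnd
#' @return mean distance (My on a dated tree).
#' @export
mpd <- function(tree, alien, natives, dm = NULL) {
  if (length(natives) == 0L) stop("empty native set")
  if (alien %in% natives) stop("alien occurs in the native set")
  if (is.null(dm)) dm <- distance_matrix(tree, c(alien, natives))
  mean(dm[alien, natives])
}

#' Country-scale relatedness of every alien to the full native flora
#'
#' One record per alien present in the tree, with PNND and MPD computed
#' against all native tips.
#'
#' @param tree a `phylo` object.
#' @param species species table with columns `species`, `status`, and
#'   optionally `alien_group`.
#' @return data frame with columns `species`, `scale` ("country"),
#'   `pnnd`, `mpd`, `nearest_native`, `invasive`, `alien_group`.
#' @export
country_relatedness <- function(tree, species) {
  stopifnot(all(c("species", "status") %in% names(species)))
  tips <- tree$tip.label
  natives <- intersect(species$species[species$status == "native"], tips)
  aliens <- intersect(species$species[species$status != "native"], tips)
  if (length(natives) == 0L) stop("no native species present in the tree")
  if (length(aliens) == 0L) stop("no alien species present in the tree")
  dm <- distance_matrix(tree, c(aliens, natives))
  sub <- dm[aliens, natives, drop = FALSE]
  nn_idx <- apply(sub, 1, function(r) {
    m <- min(r)
    sort(colnames(sub)[r <= m + 1e-12])[1]
  })
  info <- species[match(aliens, species$species), , drop = FALSE]
  out <- data.frame(
    species = aliens,
    scale = "country",
    pnnd = apply(sub, 1, min),
    mpd = rowMeans(sub),
    nearest_native = nn_idx,
    invasive = info$status == "invasive alien",
    alien_group = if ("alien_group" %in% names(info)) info$alien_group
                  else NA_character_,
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot-scale relatedness of aliens to co-occurring natives
#'
#' For each occurrence of an alien in a survey plot, PNND and MPD are
#' computed against the native species recorded in that same plot.  Plots
#' failing the inclusion rule (at least one native and one alien after
#' matching species to the tree) are excluded; species present in plots
#' but absent from the tree are dropped from the plot's species sets and
#' tallied.  The filter report is attached as attribute `filter_report`.
#'
#' @param tree a `phylo` object.
#' @param species species table (columns `species`, `status`,
#'   optionally `alien_group`).
#' @param plots plot occurrence table: columns `square`, `plot`,
#'   `species` (one row per occurrence).
#' @return data frame with columns `species`, `scale` ("plot"), `square`,
#'   `plot`, `pnnd`, `mpd`, `nearest_native`, `invasive`, `alien_group`;
#'   attribute `filter_report` lists plots dropped and unmatched species.
#' @export
plot_relatedness <- function(tree, species, plots) {
  stopifnot(all(c("square", "plot", "species") %in% names(plots)))
  status <- setNames(species$status, species$species)
  in_tree <- plots$species %in% tree$tip.label
  known <- plots$species %in% names(status)
  usable <- in_tree & known
  n_unmatched <- sum(!usable)
  occ <- plots[usable, , drop = FALSE]
  occ$status <- status[occ$species]
  key <- paste(occ$square, occ$plot, sep = "\r")
  keep_plot <- tapply(occ$status, key, function(s) {
    any(s == "native") && any(s != "native")
  })
  dropped <- sum(!keep_plot)
  occ <- occ[keep_plot[key], , drop = FALSE]
  if (nrow(occ) == 0L) {
    out <- data.frame(species = character(), scale = character(),
                      square = character(), plot = character(),
                      pnnd = numeric(), mpd = numeric(),
                      nearest_native = character(), invasive = logical(),
                      alien_group = character(), stringsAsFactors = FALSE)
    attr(out, "filter_report") <- list(plots_dropped = dropped,
                                       plots_retained = 0L,
                                       unmatched_occurrences = n_unmatched)
    return(out)
  }
  used <- unique(occ$species)
  dm <- distance_matrix(tree, used)
  info <- species[match(used, species$species), , drop = FALSE]
  grp <- if ("alien_group" %in% names(info)) {
    setNames(info$alien_group, used)
  } else setNames(rep(NA_character_, length(used)), used)
  key <- paste(occ$square, occ$plot, sep = "\r")
  res <- lapply(split(occ, key), function(p) {
    nat <- p$species[p$status == "native"]
    ali <- p$species[p$status != "native"]
    sub <- dm[ali, nat, drop = FALSE]
    nn <- apply(sub, 1, function(r) {
      m <- min(r)
      sort(colnames(sub)[r <= m + 1e-12])[1]
    })
    data.frame(species = ali, scale = "plot",
               square = p$square[match(ali, p$species)],
               plot = p$plot[match(ali, p$species)],
               pnnd = apply(sub, 1, min), mpd = rowMeans(sub),
               nearest_native = nn,
               invasive = p$status[match(ali, p$species)] ==
                 "invasive alien",
               alien_group = unname(grp[ali]),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "filter_report") <- list(
    plots_dropped = dropped,
    plots_retained = length(unique(key)),
    unmatched_occurrences = n_unmatched)
  out
}
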