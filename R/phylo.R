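#' Read a time-calibrated (or gene) tree from newick
#'
#' Wraps [ape::read.tree()] with the checks the downstream analyses rely on:
#' unique tip labels, branch lengths present, and non-negative lengths.
#' Branch lengths are in millions of years for the species chronogram and in
#' substitutions/site for per-gene trees; nothing downstream mixes the two.
#'
#' @param path Path to a newick file, or a newick string (if `text = TRUE`).
#' @param text Treat `path` as newick text rather than a file path.
#' @param allow_missing If `TRUE`, missing branch lengths are replaced by 0
#'   with a warning; if `FALSE` (default) they are an error.
#' @return An object of class `phylo` (rooted, branch lengths set).
#' @export
read_time_tree <- function(path, text = FALSE, allow_missing = FALSE) {
  tree <- if (text) ape::read.tree(text = path) else ape::read.tree(path)
  if (is.null(tree)) stop("malformed newick: could not parse tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) {
    if (!allow_missing) stop("tree has no branch lengths")
    warning("tree has no branch lengths; treating all as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (!allow_missing) stop("tree has missing branch lengths")
    warning("missing branch lengths treated as 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  term <- tree$edge[, 2] <= ape::Ntip(tree)
  if (any(tree$edge.length[term] == 0))
    warning("zero-length terminal branches present (age ties possible)")
  tree
}

#' Write a tree to newick
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @param digits Significant digits for branch lengths.
#' @export
write_time_tree <- function(tree, path, digits = 10) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Stable branch identities as descendant tip sets
#'
#' A branch is identified by the set of tip labels descending from its child
#' node, encoded as the sorted labels joined with `"|"`. This identity
#' survives per-gene pruning (after intersecting with the kept tips), which
#' is how branches are matched between the species chronogram and thousands
#' of differently pruned gene trees.
#'
#' @param tree A `phylo` object.
#' @return A data frame with one row per branch (edge): `branch_id`,
#'   `is_terminal`, `species` (tip label for terminal branches, `NA`
#'   otherwise), `length`, and `node` (the ape child-node index).
#' @export
branch_table <- function(tree) {
  ntip <- ape::Ntip(tree)
  child <- tree$edge[, 2]
  desc <- phangorn::Descendants(tree, child, type = "tips")
  ids <- vapply(desc, function(i) paste(sort(tree$tip.label[i]), collapse = "|"), "")
  data.frame(
    branch_id = ids,
    is_terminal = child <= ntip,
    species = ifelse(child <= ntip, tree$tip.label[pmin(child, ntip)], NA_character_),
    length = tree$edge.length,
    node = child,
    stringsAsFactors = FALSE
  )
}

#' Branch identity for a set of tip labels
#'
#' @param tips Character vector of tip labels.
#' @return The canonical branch-id string.
#' @export
branch_id <- function(tips) paste(sort(unique(tips)), collapse = "|")

#' Tips making up a branch id
#' @param id A branch-id string.
#' @return Character vector of tip labels.
#' @export
branch_id_tips <- function(id) strsplit(id, "|", fixed = TRUE)[[1]]

# depth (path length from root) of every node, in tree units
node_depths <- function(tree) ape::node.depth.edgelength(tree)

#' Node age of a species pair
#'
#' The age of the most recent common ancestor of two tips, computed as the
#' mean of the two tip-to-MRCA path lengths. On an ultrametric chronogram
#' both paths are equal and the value is the MRCA depth below the present;
#' on a slightly non-ultrametric tree the mean is the natural compromise.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param a,b Distinct tip labels.
#' @return A single non-negative number (same units as the branch lengths).
#' @export
node_age <- function(tree, a, b) {
  if (identical(a, b)) stop("node_age requires two distinct tips")
  idx <- match(c(a, b), tree$tip.label)
  if (anyNA(idx)) stop("unknown tip(s): ", paste(c(a, b)[is.na(idx)], collapse = ", "))
  m <- ape::getMRCA(tree, idx)
  d <- node_depths(tree)
  ((d[idx[1]] - d[m]) + (d[idx[2]] - d[m])) / 2
}

#' Node ages for many species pairs at once
#'
#' @param tree A `phylo` object.
#' @param pairs Data frame with columns `species_a`, `species_b`.
#' @return `pairs` with a `node_age` column appended.
#' @export
node_age_table <- function(tree, pairs) {
  stopifnot(all(c("species_a", "species_b") %in% names(pairs)))
  pairs$node_age <- mapply(function(a, b) node_age(tree, a, b),
                           pairs$species_a, pairs$species_b)
  pairs
}

#' Prune a tree to a set of taxa
#'
#' Drops all other tips and collapses the resulting degree-2 nodes, summing
#' their branch lengths, so pairwise path lengths among kept tips are
#' preserved. Surviving branch identities equal the original descendant tip
#' sets intersected with `keep`.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(keep)
  if (!all(keep %in% tree$tip.label))
    stop("keep contains tips not in the tree: ",
         paste(setdiff(keep, tree$tip.label), collapse = ", "))
  if (length(keep) < 2) stop("need at least 2 tips to keep")
  ape::keep.tip(tree, keep)
}

#' Check ultrametricity (reported, not enforced)
#'
#' Chronograms produced by penalized-likelihood dating can deviate slightly
#' from exact ultrametricity, so this check reports rather than rejects.
#'
#' @param tree A `phylo` object.
#' @param tol Absolute tolerance on tip-depth spread (default 1e-6, in the
#'   tree's own length units).
#' @return Logical; the maximum tip-depth deviation is attached as
#'   attribute `"deviation"`.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  dev <- max(d) - min(d)
  structure(dev <= tol, deviation = dev)
}

#' Alignment-retention filter
#'
#' Retains genes whose alignments contain at least `min_taxa` sequences and,
#' when `clade_requirements` is given, at least one species from every
#' required biogeographic clade (any ecomorph counts). This mirrors the
#' usual retention rule for genome-wide screens built from reference-guided
#' ortholog annotations, where incomplete assemblies drop taxa from
#' individual alignments.
#'
#' @param gene_taxa Named list: gene id -> character vector of taxa present
#'   in that gene's alignment.
#' @param min_taxa Minimum number of sequences (default 20).
#' @param clade_requirements Optional named list: clade label -> character
#'   vector of member species; each clade must be represented by >= 1 taxon.
#' @return Character vector of retained gene ids (possibly empty).
#' @export
filter_alignable_genes <- function(gene_taxa, min_taxa = 20,
                                   clade_requirements = NULL) {
  stopifnot(min_taxa >= 2)
  keep <- vapply(gene_taxa, function(taxa) {
    taxa <- unique(taxa)
    if (length(taxa) < min_taxa) return(FALSE)
    if (!is.null(clade_requirements)) {
      for (members in clade_requirements) {
        if (!any(members %in% taxa)) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  names(gene_taxa)[keep]
}

#' Read a two-column species-to-group map
#'
#' @param path TSV with columns `species` and a group column (e.g.
#'   `ecomorph` or `region`); a header line is required.
#' @return Data frame as read.
#' @export
read_species_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("species map needs at least two columns")
  df
}
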