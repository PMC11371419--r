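# Gene reuse: pairwise shared-selection counts, max-normalization, and the
# node-age regression, with GO-restricted variants.

#' Species pairs for the reuse analysis
#'
#' The headline pair universe is all same-ecomorph pairs among the focal
#' (non-outgroup) species; outgroup pairs can be added for contrast.
#' Cross-ecomorph pairs are excluded by default, since reuse is defined
#' within repeatedly evolved phenotypes.
#'
#' @param branch_info Branch metadata (see [make_branch_metadata()]).
#' @param include_outgroup Also return all pairs among outgroup species,
#'   tagged `"outgroup"`.
#' @param outgroup_label Ecomorph label marking non-focal species.
#' @return Data frame: `species_a`, `species_b`, `ecomorph`.
#' @export
same_ecomorph_pairs <- function(branch_info, include_outgroup = FALSE,
                                outgroup_label = "outgroup") {
  term <- branch_info[branch_info$is_terminal & !is.na(branch_info$ecomorph), ]
  groups <- unique(term$ecomorph)
  if (!include_outgroup) groups <- setdiff(groups, outgroup_label)
  out <- do.call(rbind, lapply(groups, function(e) {
    sp <- sort(term$species[term$ecomorph == e])
    if (length(sp) < 2) return(NULL)
    cp <- t(utils::combn(sp, 2))
    data.frame(species_a = cp[, 1], species_b = cp[, 2], ecomorph = e,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) stop("no ecomorph has >= 2 species")
  rownames(out) <- NULL
  out
}

#' Shared selected-gene counts per species pair
#'
#' For each pair, the number of genes called selected on both species'
#' terminal branches. Genes untested (absent) in either species are
#' excluded from that pair's countable universe — absence of a test is not
#' evidence either way.
#'
#' @param sm A `selection_matrix`.
#' @param pairs Data frame with `species_a`, `species_b` (extra columns
#'   carried through).
#' @param genes Optional gene subset to count within (used by the
#'   GO-restricted analysis).
#' @return `pairs` with columns `shared_count` and `n_testable` appended.
#' @export
pair_shared_counts <- function(sm, pairs, genes = NULL) {
  meta <- sm$branches
  term <- meta[meta$is_terminal, ]
  col_of <- stats::setNames(match(term$branch_id, colnames(sm$selected)),
                            term$species)
  sel <- sm$selected
  if (!is.null(genes)) {
    keep <- rownames(sel) %in% genes
    sel <- sel[keep, , drop = FALSE]
  }
  get_col <- function(sp) {
    j <- unname(col_of[sp])
    if (is.na(j)) stop("species without terminal branch: ", sp)
    sel[, j]
  }
  pairs$shared_count <- NA_integer_
  pairs$n_testable <- NA_integer_
  for (i in seq_len(nrow(pairs))) {
    va <- get_col(pairs$species_a[i])
    vb <- get_col(pairs$species_b[i])
    testable <- !is.na(va) & !is.na(vb)
    pairs$n_testable[i] <- sum(testable)
    pairs$shared_count[i] <- sum(va == 1 & vb == 1, na.rm = TRUE)
  }
  pairs
}

#' Normalize shared counts by the observed maximum
#'
#' Each pair's proportion of gene reuse is its shared count divided by the
#' largest shared count observed in the table, so the max-attaining pair
#' scores exactly 1.0. Normalizing by the total number of screened genes is
#' deliberately avoided: that denominator is so large that all proportions
#' collapse toward zero and differences become uninterpretable without a
#' further log transform.
#'
#' @param counts Data frame with a `shared_count` column (from
#'   [pair_shared_counts()]).
#' @return The input with a `proportion` column appended; the maximum used
#'   is attached as attribute `"max_count"`.
#' @export
normalize_by_max <- function(counts) {
  stopifnot("shared_count" %in% names(counts))
  mx <- max(counts$shared_count)
  if (mx <= 0) stop("all shared counts are zero; nothing to normalize")
  counts$proportion <- counts$shared_count / mx
  attr(counts, "max_count") <- mx
  counts
}

#' Regress gene-reuse proportion on node age
#'
#' OLS of the normalized shared-gene proportion on pair divergence time
#' (node age, in millions of years). A negative slope is the classical
#' expectation — reuse of the same genes should be more common between
#' recently diverged lineages; the fit reports slope, R², F and P so either
#' sign is simply measured.
#'
#' @param records Data frame with `node_age` and `proportion` (or
#'   `shared_count` when `use_counts = TRUE`).
#' @param use_counts Regress raw counts instead of proportions (sensitivity
#'   variant; identical R² by construction).
#' @return A `regression_fit` (see [ols_fit()]).
#' @export
reuse_regression <- function(records, use_counts = FALSE) {
  y <- if (use_counts) records$shared_count else records$proportion
  if (length(y) < 3) stop("need at least 3 pairs")
  ols_fit(records$node_age, y)
}

#' Restrict the reuse analysis to genes annotated to a GO term
#'
#' Recomputes pair shared counts over only the genes annotated to
#' `go_term` (including descendant terms when a term graph is supplied) and
#' renormalizes by the restricted maximum.
#'
#' @param sm A `selection_matrix`.
#' @param pairs Pair table with `node_age` already attached.
#' @param go_term Term identifier.
#' @param annotations Named list: term -> character vector of genes.
#' @param graph Optional term graph from [read_obo()]; descendants of
#'   `go_term` are pooled in.
#' @return Pair records with restricted `shared_count` and `proportion`.
#' @export
restrict_to_go <- function(sm, pairs, go_term, annotations, graph = NULL) {
  if (!go_term %in% names(annotations) &&
      (is.null(graph) || !go_term %in% graph$terms$id))
    stop("term not present in annotations: ", go_term)
  terms <- go_term
  if (!is.null(graph)) terms <- union(terms, term_descendants(graph, go_term))
  genes <- unique(unlist(annotations[intersect(terms, names(annotations))]))
  genes <- intersect(genes, rownames(sm$selected))
  if (length(genes) == 0) stop("term annotates no screened genes: ", go_term)
  counts <- pair_shared_counts(sm, pairs, genes = genes)
  normalize_by_max(counts)
}

#' Plot gene reuse against node age
#'
#' Scatter of normalized reuse proportion vs pair node age with per-group
#' glyphs and the fitted OLS line.
#'
#' @param records Pair records with `node_age`, `proportion`, and
#'   optionally `ecomorph`.
#' @param main Plot title.
#' @export
plot_reuse <- function(records, main = "Gene reuse vs node age") {
  grp <- if ("ecomorph" %in% names(records))
    factor(records$ecomorph) else factor(rep("all", nrow(records)))
  graphics::plot(records$node_age, records$proportion,
                 pch = as.integer(grp) - 1 + 15, col = as.integer(grp),
                 xlab = "node age (My)", ylab = "proportion of shared genes",
                 main = main)
  fit <- reuse_regression(records)
  graphics::abline(fit$intercept, fit$slope, lty = 2)
  graphics::legend("topleft", legend = levels(grp), pch = seq_along(levels(grp)) + 14,
                   col = seq_along(levels(grp)), bty = "n")
  invisible(fit)
}
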