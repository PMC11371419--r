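# Ingestion of per-gene per-branch selection-test results, within-gene FDR,
# the gene x branch selection matrix, and the branch-representation bias check.

#' Build branch metadata for a selection analysis
#'
#' Joins the tree's branch identities with a species-to-ecomorph (and
#' optionally region) map. Every terminal branch must map to exactly one
#' ecomorph; a species appearing under two ecomorphs is rejected here, which
#' is what keeps group gene sets disjoint at the metadata level.
#'
#' @param tree A `phylo` object (the analysis chronogram).
#' @param ecomorph_map Data frame with columns `species`, `ecomorph`, and
#'   optionally `region`.
#' @return Data frame: `branch_id`, `is_terminal`, `species`, `ecomorph`,
#'   `region` (one row per branch of the tree).
#' @export
make_branch_metadata <- function(tree, ecomorph_map) {
  stopifnot(all(c("species", "ecomorph") %in% names(ecomorph_map)))
  if (anyDuplicated(ecomorph_map$species))
    stop("a species appears more than once in the ecomorph map")
  bt <- branch_table(tree)
  miss <- setdiff(tree$tip.label, ecomorph_map$species)
  if (length(miss))
    stop("tips without ecomorph assignment: ", paste(miss, collapse = ", "))
  i <- match(bt$species, ecomorph_map$species)
  bt$ecomorph <- ecomorph_map$ecomorph[i]
  bt$region <- if ("region" %in% names(ecomorph_map))
    ecomorph_map$region[i] else NA_character_
  bt[, c("branch_id", "is_terminal", "species", "ecomorph", "region")]
}

#' Read per-branch selection-test results
#'
#' Two dialects are supported. `"tsv"`: tab-separated files with a header
#' and columns `gene`, `branch`, `p` (one or more files, concatenated).
#' `"native"`: one JSON result file per gene in the layout written by the
#' adaptive branch-site random-effects test, with per-branch
#' `"Uncorrected P-value"` / `"Corrected P-value"` entries under
#' `"branch attributes"`; the gene id is the file name without extension.
#' The default reads the uncorrected p so that the within-gene FDR rule is
#' applied explicitly by [build_selection_matrix()]; set
#' `p_field = "corrected"` to trust the file's own correction.
#'
#' When `tree` is supplied, branch names are resolved against it (tip labels
#' for terminal branches, `"a|b|c"` descendant-tip ids otherwise);
#' unresolvable names are returned in the `"unresolved"` attribute, with a
#' warning, rather than silently dropped.
#'
#' @param paths Character vector of input files.
#' @param dialect `"tsv"` or `"native"`.
#' @param p_field For the native dialect, `"uncorrected"` (default) or
#'   `"corrected"`.
#' @param tree Optional `phylo` used to validate branch names.
#' @return Data frame with columns `gene`, `branch_id`, `p_raw`.
#' @export
read_screen_results <- function(paths, dialect = c("tsv", "native"),
                                p_field = c("uncorrected", "corrected"),
                                tree = NULL) {
  dialect <- match.arg(dialect)
  p_field <- match.arg(p_field)
  if (dialect == "tsv") {
    recs <- do.call(rbind, lapply(paths, function(p) {
      df <- utils::read.delim(p, stringsAsFactors = FALSE, comment.char = "#")
      if (!all(c("gene", "branch", "p") %in% names(df)))
        stop("tsv screen file needs columns gene, branch, p: ", p)
      data.frame(gene = as.character(df$gene),
                 branch_id = as.character(df$branch),
                 p_raw = as.numeric(df$p), stringsAsFactors = FALSE)
    }))
  } else {
    key <- if (p_field == "uncorrected") "Uncorrected P-value" else "Corrected P-value"
    recs <- do.call(rbind, lapply(paths, function(p) {
      obj <- jsonlite::read_json(p)
      ba <- obj[["branch attributes"]][["0"]]
      if (is.null(ba)) stop("no branch attributes in native result file: ", p)
      gene <- sub("\\.[^.]*$", "", basename(p))
      data.frame(gene = gene, branch_id = names(ba),
                 p_raw = vapply(ba, function(b) as.numeric(b[[key]]), 0),
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(recs) || nrow(recs) == 0) stop("no selection records parsed")
  if (any(recs$p_raw < 0 | recs$p_raw > 1 | is.na(recs$p_raw)))
    stop("p-values outside [0,1] in screen results")
  rownames(recs) <- NULL
  unresolved <- character(0)
  if (!is.null(tree)) {
    known <- branch_table(tree)$branch_id
    bad <- !(recs$branch_id %in% known)
    if (any(bad)) {
      unresolved <- unique(recs$branch_id[bad])
      warning(length(unresolved), " branch name(s) did not resolve against the tree")
      recs <- recs[!bad, , drop = FALSE]
    }
  }
  attr(recs, "unresolved") <- unresolved
  recs
}

#' Write per-branch selection results (synthetic or exported)
#'
#' Inverse of [read_screen_results()]; used by the simulator to exercise
#' both dialects.
#'
#' @param calls Data frame with `gene`, `branch_id`, `p_raw`.
#' @param dir Output directory (created if needed).
#' @param dialect `"tsv"` (one file) or `"native"` (one JSON per gene).
#' @return Character vector of files written.
#' @export
write_screen_results <- function(calls, dir, dialect = c("tsv", "native")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (dialect == "tsv") {
    path <- file.path(dir, "screen_results.tsv")
    utils::write.table(
      data.frame(gene = calls$gene, branch = calls$branch_id, p = calls$p_raw),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(path)
  }
  vapply(split(calls, calls$gene), function(g) {
    path <- file.path(dir, paste0(g$gene[1], ".json"))
    ba <- stats::setNames(lapply(seq_len(nrow(g)), function(i) list(
      `Uncorrected P-value` = g$p_raw[i],
      `Corrected P-value` = min(1, g$p_raw[i] * nrow(g)))), g$branch_id)
    jsonlite::write_json(list(`branch attributes` = list(`0` = ba)),
                         path, auto_unbox = TRUE, digits = NA)
    path
  }, "")
}

#' Benjamini-Hochberg adjustment within one gene
#'
#' Step-up false-discovery-rate adjustment of the per-branch p-values of a
#' single gene, order-preserving with the input. The within-gene scope
#' matters: each gene's branches form their own family, so a gene tested on
#' few branches is not penalized for the size of the genome-wide screen.
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @return Numeric vector of q-values, same order as `p`.
#' @export
fdr_within_gene <- function(p) {
  if (length(p) == 0) stop("empty p-value list")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Build the gene x branch selection matrix
#'
#' Applies [fdr_within_gene()] to each gene's branch p-values and calls a
#' cell selected when `q <= alpha`. Branches untested for a gene are `NA`
#' ("absent"), which all downstream counting keeps distinct from 0
#' ("tested, not selected"): a branch missing from an alignment is not
#' evidence of no selection.
#'
#' @param calls Data frame with `gene`, `branch_id`, `p_raw` (one row per
#'   tested branch per gene).
#' @param alpha Significance threshold on q (default 0.05).
#' @param branch_info Branch metadata from [make_branch_metadata()]; must
#'   cover every terminal branch present in `calls`.
#' @return An object of class `selection_matrix`: list with integer matrix
#'   `selected` (genes x branches; 0/1/`NA`), numeric matrices `p` and `q`,
#'   the `branches` metadata (ordered as the matrix columns), `genes`, and
#'   `alpha`.
#' @export
build_selection_matrix <- function(calls, alpha = 0.05, branch_info) {
  stopifnot(alpha >= 0, alpha < 1)  # alpha = 0 gives an all-empty screen
  if (any(calls$p_raw < 0 | calls$p_raw > 1)) stop("p-values outside [0,1]")
  terminal_ids <- unique(calls$branch_id[!grepl("|", calls$branch_id, fixed = TRUE)])
  known_term <- branch_info$branch_id[branch_info$is_terminal &
                                        !is.na(branch_info$ecomorph)]
  miss <- setdiff(terminal_ids, known_term)
  if (length(miss))
    stop("metadata missing for terminal branch(es): ", paste(miss, collapse = ", "))
  genes <- unique(calls$gene)
  extra <- setdiff(unique(calls$branch_id), branch_info$branch_id)
  if (length(extra)) {
    branch_info <- rbind(branch_info,
      data.frame(branch_id = extra, is_terminal = !grepl("|", extra, fixed = TRUE),
                 species = NA_character_, ecomorph = NA_character_,
                 region = NA_character_))
  }
  branches <- branch_info$branch_id
  sel <- matrix(NA_integer_, length(genes), length(branches),
                dimnames = list(genes, branches))
  pm <- qm <- matrix(NA_real_, length(genes), length(branches),
                     dimnames = list(genes, branches))
  gi <- match(calls$gene, genes)
  bi <- match(calls$branch_id, branches)
  idx <- cbind(gi, bi)
  if (anyDuplicated(idx)) stop("duplicate (gene, branch) records")
  pm[idx] <- calls$p_raw
  q <- unlist(lapply(split(seq_len(nrow(calls)), calls$gene),
                     function(i) fdr_within_gene(calls$p_raw[i])),
              use.names = FALSE)
  ord <- order(calls$gene)  # split() groups by gene in sorted order
  qv <- numeric(nrow(calls)); qv[ord] <- q
  qm[idx] <- qv
  sel[idx] <- as.integer(qv <= alpha)
  structure(list(selected = sel, p = pm, q = qm,
                 branches = branch_info, genes = genes, alpha = alpha),
            class = "selection_matrix")
}

#' @export
print.selection_matrix <- function(x, ...) {
  cat(sprintf("selection_matrix: %d genes x %d branches, alpha = %g\n",
              length(x$genes), nrow(x$branches), x$alpha))
  cat(sprintf("  selected cells: %d; tested cells: %d\n",
              sum(x$selected == 1, na.rm = TRUE), sum(!is.na(x$selected))))
  invisible(x)
}

#' Export / import a selection matrix as TSV (0/1/NA cells)
#'
#' @param sm A `selection_matrix`.
#' @param path Output path.
#' @export
write_selection_matrix <- function(sm, path) {
  df <- data.frame(gene = rownames(sm$selected), sm$selected,
                   check.names = FALSE)
  write_tsv_schema(df, path)
}

#' @rdname write_selection_matrix
#' @param branch_info Branch metadata to reattach on read.
#' @param alpha Threshold recorded on the imported object.
#' @export
read_selection_matrix <- function(path, branch_info, alpha = 0.05) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene
  structure(list(selected = m, p = NULL, q = NULL,
                 branches = branch_info, genes = df$gene, alpha = alpha),
            class = "selection_matrix")
}

#' Branch-representation bias check
#'
#' Regresses, across branches, the number of genes in which a branch is
#' called selected on the number of gene alignments in which the branch is
#' represented (tested). A flat fit indicates the selection calls are not
#' driven by heterogeneous genome completeness.
#'
#' @param sm A `selection_matrix`.
#' @return A `regression_fit` (see [ols_fit()]) with the per-branch counts
#'   attached as attribute `"counts"`.
#' @export
branch_bias_check <- function(sm) {
  tested <- colSums(!is.na(sm$selected))
  selected <- colSums(sm$selected == 1, na.rm = TRUE)
  keep <- tested > 0
  if (sum(keep) < 3) stop("need at least 3 represented branches")
  fit <- ols_fit(tested[keep], selected[keep])
  attr(fit, "counts") <- data.frame(branch_id = colnames(sm$selected)[keep],
                                    tested = tested[keep],
                                    selected = selected[keep])
  fit
}
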