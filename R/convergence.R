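# Ecomorph-level aggregation: per-group gene sets, three-set Venn
# partitions, omega_c branch-pair filtering, and three-way evidence overlap.

#' Genes selected in an ecomorph
#'
#' Union, over the (terminal) branches of the species in one ecomorph, of
#' the genes called selected on that branch — the "under selection in at
#' least one species of the group" rule. The outgroup label is supported so
#' the same aggregation can be run for non-focal species as a contrast.
#'
#' @param sm A `selection_matrix`.
#' @param ecomorph Ecomorph label present in the branch metadata.
#' @param terminal_only Restrict to terminal branches (default `TRUE`;
#'   ecomorphs are phenotypes of extant species).
#' @return Character vector of gene ids (a gene set).
#' @export
genes_selected_in_group <- function(sm, ecomorph, terminal_only = TRUE) {
  meta <- sm$branches
  pick <- !is.na(meta$ecomorph) & meta$ecomorph == ecomorph
  if (terminal_only) pick <- pick & meta$is_terminal
  if (!any(pick)) stop("unknown ecomorph or no branches: ", ecomorph)
  cols <- match(meta$branch_id[pick], colnames(sm$selected))
  sub <- sm$selected[, cols, drop = FALSE]
  sort(rownames(sub)[rowSums(sub == 1, na.rm = TRUE) > 0])
}

#' Three-set Venn partition
#'
#' The 7 mutually exclusive region counts of three gene sets, plus each
#' set's exclusive fraction (genes in that set only / set size) — the
#' statistic behind "70--80% of each group's selected genes are private to
#' the group".
#'
#' @param a,b,c Character vectors (gene sets).
#' @param labels Length-3 labels for reporting.
#' @return List of class `venn_partition` with `regions` (named counts
#'   `a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`),
#'   `exclusive_fraction`, `sizes`, and `union_size`.
#' @export
venn_partition <- function(a, b, c, labels = c("a", "b", "c")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  regions <- c(
    a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab = sum(ina & inb & !inc),
    ac = sum(ina & !inb & inc),
    bc = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc))
  sizes <- c(length(a), length(b), length(c))
  excl <- ifelse(sizes > 0,
                 regions[c("a_only", "b_only", "c_only")] / sizes, NA_real_)
  structure(list(regions = regions,
                 exclusive_fraction = stats::setNames(excl, labels),
                 sizes = stats::setNames(sizes, labels),
                 union_size = length(u), labels = labels),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition (", paste(x$labels, collapse = " / "), ")\n", sep = "")
  print(x$regions)
  cat("exclusive fractions:",
      paste(sprintf("%s = %.3f", x$labels, x$exclusive_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read a table of omega_c convergence records
#'
#' @param path TSV with columns `gene`, `branch1`, `branch2`, `mode`,
#'   `omega_c`.
#' @return Data frame of records (validated).
#' @export
read_omega_c <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene", "branch1", "branch2", "mode", "omega_c")
  if (!all(need %in% names(df))) stop("omega_c table needs columns: ",
                                      paste(need, collapse = ", "))
  if (any(df$omega_c < 0)) stop("omega_c must be non-negative")
  if (any(df$branch1 == df$branch2)) stop("branch pair members must differ")
  df
}

#' Filter omega_c records to convergent genes
#'
#' Retains genes having at least one branch-pair record with
#' `omega_c >= threshold` (inclusive), in the requested convergence mode,
#' and with at least one branch of the pair in the foreground set (both,
#' if `require_both`). Modes follow the error-corrected convergence-rate
#' tool: `"any2spe"` means any ancestral state transitioning to the same
#' specific derived state on both branches.
#'
#' @param records Data frame from [read_omega_c()] (or equivalent).
#' @param threshold Minimum omega_c (default 3).
#' @param mode Convergence mode to keep (default `"any2spe"`).
#' @param foreground Character vector of foreground branch ids; `NULL`
#'   disables the foreground restriction.
#' @param require_both Require both branches of the pair in the foreground.
#' @return Character vector of gene ids.
#' @export
filter_omega_c <- function(records, threshold = 3, mode = "any2spe",
                           foreground = NULL, require_both = FALSE) {
  stopifnot(threshold > 0)
  keep <- records$omega_c >= threshold & records$mode == mode
  if (!is.null(foreground)) {
    in1 <- records$branch1 %in% foreground
    in2 <- records$branch2 %in% foreground
    keep <- keep & if (require_both) in1 & in2 else in1 | in2
  }
  sort(unique(records$gene[keep]))
}

#' Three-way evidence overlap for one ecomorph
#'
#' Cross-references the genes under positive selection with the genes
#' flagged by the rate-association and protein-convergence analyses:
#' the full 7-region partition plus the headline fractions — the proportion
#' of selected genes also found in each convergence set, and the overlap
#' between the two convergence sets themselves.
#'
#' @param selected,rer_significant,omega_significant Gene sets (character).
#' @return A `venn_partition` with an `overlap_fractions` element appended:
#'   `selected_in_rer`, `selected_in_omega`, `rer_omega_jaccard`.
#' @export
overlap_evidence <- function(selected, rer_significant, omega_significant) {
  vp <- venn_partition(selected, rer_significant, omega_significant,
                       labels = c("selected", "rer", "omega_c"))
  n_sel <- length(unique(selected))
  inter_ro <- length(intersect(rer_significant, omega_significant))
  union_ro <- length(union(rer_significant, omega_significant))
  vp$overlap_fractions <- c(
    selected_in_rer = if (n_sel) length(intersect(selected, rer_significant)) / n_sel else NA_real_,
    selected_in_omega = if (n_sel) length(intersect(selected, omega_significant)) / n_sel else NA_real_,
    rer_omega_jaccard = if (union_ro) inter_ro / union_ro else 0)
  vp
}

#' Write a gene set as one id per line
#' @param genes Character vector.
#' @param path Output path.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(sort(unique(genes)), path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) readLines(path)
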