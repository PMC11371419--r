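# Hypergeometric gene-set enrichment with BH q-values, GO-depth filtering,
# a matched-size randomization null, and per-species robustness runs.
# This replaces web enrichment services with the standard exact test;
# comparisons are at the level of which terms pass q < 0.05.

#' Read gene-set annotations in GMT format
#'
#' @param path GMT file (term, description, genes...).
#' @return Named list: term -> character vector of genes.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write annotations as GMT
#'
#' @param annotations Named list term -> genes.
#' @param path Output path.
#' @param descriptions Optional named descriptions (default `"na"`).
#' @export
write_gmt <- function(annotations, path, descriptions = NULL) {
  lines <- vapply(names(annotations), function(tm) {
    d <- if (!is.null(descriptions) && tm %in% names(descriptions))
      descriptions[[tm]] else "na"
    paste(c(tm, d, annotations[[tm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Minimal OBO reader (is_a hierarchy only)
#'
#' Parses `[Term]` stanzas for `id`, `name`, and `is_a` edges; obsolete
#' terms are dropped. Only the is_a hierarchy is used downstream (depth
#' filtering and descendant pooling).
#'
#' @param path OBO file.
#' @return List of class `term_graph`: `terms` (data frame `id`, `name`)
#'   and `edges` (data frame `child`, `parent`).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0) stop("no [Term] stanzas found")
  bounds <- c(starts, length(lines) + 1L)
  terms <- list(); edges <- list()
  for (i in seq_along(starts)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    get <- function(key) sub(paste0("^", key, ": "), "",
                             grep(paste0("^", key, ": "), block, value = TRUE))
    id <- get("id")[1]
    if (is.na(id) || any(grepl("^is_obsolete: true", block))) next
    terms[[length(terms) + 1L]] <- data.frame(
      id = id, name = if (length(get("name"))) get("name")[1] else id,
      stringsAsFactors = FALSE)
    isa <- get("is_a")
    if (length(isa)) {
      parent <- sub(" !.*$", "", isa)
      edges[[length(edges) + 1L]] <- data.frame(child = id, parent = parent,
                                                stringsAsFactors = FALSE)
    }
  }
  structure(list(terms = do.call(rbind, terms),
                 edges = if (length(edges)) do.call(rbind, edges)
                         else data.frame(child = character(), parent = character())),
            class = "term_graph")
}

#' Build a term graph from edge lists (for constructed ontologies)
#'
#' @param edges Data frame with `child`, `parent`.
#' @param names Optional named character vector of term names.
#' @return A `term_graph`.
#' @export
term_graph <- function(edges, names = NULL) {
  ids <- unique(c(edges$child, edges$parent))
  structure(list(
    terms = data.frame(id = ids,
                       name = if (is.null(names)) ids else
                         ifelse(ids %in% names(names), names[ids], ids),
                       stringsAsFactors = FALSE),
    edges = edges), class = "term_graph")
}

graph_as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("parent", "child")], directed = TRUE,
    vertices = graph$terms$id)
}

#' Descendants of a term in the is_a hierarchy
#' @param graph A `term_graph`.
#' @param term Term id.
#' @return Character vector of descendant term ids (excluding `term`).
#' @export
term_descendants <- function(graph, term) {
  g <- graph_as_igraph(graph)
  if (!term %in% graph$terms$id) return(character(0))
  out <- igraph::subcomponent(g, term, mode = "out")
  setdiff(names(out), term)
}

#' Propagate gene annotations up the is_a hierarchy
#'
#' A gene annotated to a term counts for all of the term's ancestors.
#' Without a graph (flat GMT mode) annotations are used as given.
#'
#' @param annotations Named list term -> genes.
#' @param graph A `term_graph`.
#' @return Named list with ancestor-pooled gene sets.
#' @export
propagate_annotations <- function(annotations, graph) {
  g <- graph_as_igraph(graph)
  out <- stats::setNames(vector("list", nrow(graph$terms)), graph$terms$id)
  for (tm in graph$terms$id) {
    below <- c(tm, term_descendants(graph, tm))
    out[[tm]] <- sort(unique(unlist(annotations[intersect(below, names(annotations))])))
  }
  extra <- setdiff(names(annotations), graph$terms$id)
  c(out[lengths(out) > 0], annotations[extra])
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric test per term: the probability of observing at
#' least `k` study genes annotated to the term, given `K` annotated genes
#' in a background of `N` and a study set of size `n`, with
#' Benjamini-Hochberg correction across the tested terms. The background
#' defaults to the screened/annotatable universe rather than the whole
#' genome, conditioning on testability.
#'
#' @param study Character vector of study genes (must be within
#'   `background`).
#' @param background Character vector: the gene universe.
#' @param annotations Named list term -> genes.
#' @param q_threshold Significance threshold on q (default 0.05).
#' @return Data frame of class `enrichment_result`: `term`, `k`, `K`, `n`,
#'   `N`, `p`, `q`, `log_q`, `significant`, sorted by p. Terms with
#'   `K = 0` are skipped.
#' @export
hypergeom_enrich <- function(study, background, annotations,
                             q_threshold = 0.05) {
  study <- unique(study); background <- unique(background)
  if (length(study) == 0) stop("empty study set")
  if (!all(study %in% background))
    stop("study set must be a subset of the background")
  N <- length(background); n <- length(study)
  rows <- lapply(names(annotations), function(tm) {
    ann <- intersect(annotations[[tm]], background)
    K <- length(ann)
    if (K == 0) return(NULL)
    k <- length(intersect(ann, study))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop("no term annotates any background gene")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$log_q <- log10(out$q)
  out$significant <- out$q < q_threshold
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Filter terms by depth below a root term
#'
#' Keeps terms whose minimum is_a path length from `root` is at most
#' `max_depth` — the usual way of pruning very specific GO terms while
#' reporting at interpretable levels (e.g. five levels below Biological
#' Process). Terms absent from the graph are retained but flagged, with a
#' warning.
#'
#' @param terms Character vector of term ids.
#' @param graph A `term_graph`.
#' @param max_depth Maximum depth (default 5; root itself has depth 0).
#' @param root Root term id.
#' @return Character vector of retained terms; attribute `"flagged"` lists
#'   terms not found in the graph, attribute `"depths"` the depths used.
#' @export
go_depth_filter <- function(terms, graph, max_depth = 5, root) {
  if (!root %in% graph$terms$id) stop("root term absent from graph")
  g <- graph_as_igraph(graph)
  if (!igraph::is_dag(g)) stop("term graph must be acyclic")
  known <- terms[terms %in% graph$terms$id]
  flagged <- setdiff(terms, known)
  if (length(flagged))
    warning(length(flagged), " term(s) absent from the graph retained and flagged")
  d <- suppressWarnings(
    igraph::distances(g, v = root, to = known, mode = "out"))[1, ]
  keep <- known[is.finite(d) & d <= max_depth]
  out <- terms[terms %in% c(keep, flagged)]
  attr(out, "flagged") <- flagged
  attr(out, "depths") <- d
  out
}

#' Matched-size randomization null for enrichment
#'
#' For each term, compares the observed enrichment p-value against the
#' p-values obtained for random gene sets of the same size drawn uniformly
#' from the background. The empirical p uses the add-one correction
#' `(1 + #(null <= observed)) / (1 + draws)` and is fully reproducible
#' from `seed`. This is the test that the functional pattern of a group's
#' genes is not what any same-sized gene sample from the screen would show.
#'
#' @param observed Character vector: the observed gene set.
#' @param background Character vector: the universe to draw from.
#' @param annotations Named list term -> genes.
#' @param terms Terms of interest (default: all terms with annotated
#'   background genes).
#' @param draws Number of random draws (>= 100; default 1000).
#' @param seed Integer seed (mandatory).
#' @return Data frame: `term`, `observed_p`, `empirical_p`; the null
#'   p-value matrix (terms x draws) is attached as attribute `"null_p"`.
#' @export
randomization_test <- function(observed, background, annotations,
                               terms = NULL, draws = 1000, seed) {
  stopifnot(draws >= 100)
  if (missing(seed)) stop("seed is mandatory for the randomization test")
  observed <- unique(observed); background <- unique(background)
  if (length(observed) > length(background))
    stop("observed set larger than the background")
  obs <- hypergeom_enrich(observed, background, annotations)
  if (is.null(terms)) terms <- obs$term
  obs <- obs[match(terms, obs$term), ]
  set.seed(seed)
  # null p-values computed from precomputed term-membership masks -- the
  # same hypergeometric tail as hypergeom_enrich(), without re-resolving
  # gene ids on every draw
  N <- length(background)
  n <- length(observed)
  mask <- vapply(terms, function(tm)
    background %in% annotations[[tm]], logical(N))
  K <- colSums(mask)
  nullp <- matrix(NA_real_, length(terms), draws,
                  dimnames = list(terms, NULL))
  for (d in seq_len(draws)) {
    idx <- sample.int(N, n)
    k <- colSums(mask[idx, , drop = FALSE])
    nullp[, d] <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  emp <- (1 + rowSums(nullp <= obs$p + 1e-15)) / (1 + draws)
  out <- data.frame(term = terms, observed_p = obs$p, empirical_p = emp,
                    stringsAsFactors = FALSE)
  attr(out, "null_p") <- nullp
  out
}

#' Per-species enrichment robustness
#'
#' Runs the enrichment separately on each species' own selected-gene set
#' within an ecomorph, to check that group-level functional patterns are
#' not driven by a single species. Species with empty selected sets are
#' skipped and reported.
#'
#' @param sm A `selection_matrix`.
#' @param ecomorph Ecomorph label (must have >= 2 species).
#' @param annotations Named list term -> genes.
#' @param background Gene universe (default: all genes in the matrix).
#' @param min_species Consistency threshold: terms significant in at least
#'   this many species are summarized (default 2).
#' @return List: `per_species` (named list of enrichment results),
#'   `skipped` (species with no selected genes), and `consistent_terms`.
#' @export
per_species_enrichment <- function(sm, ecomorph, annotations,
                                   background = NULL, min_species = 2) {
  meta <- sm$branches
  sp <- meta$species[meta$is_terminal & !is.na(meta$ecomorph) &
                       meta$ecomorph == ecomorph]
  if (length(sp) < 2) stop("ecomorph needs >= 2 species: ", ecomorph)
  if (is.null(background)) background <- rownames(sm$selected)
  res <- list(); skipped <- character(0)
  for (s in sp) {
    j <- match(meta$branch_id[meta$is_terminal & !is.na(meta$species) &
                                meta$species == s], colnames(sm$selected))
    genes <- rownames(sm$selected)[which(sm$selected[, j] == 1)]
    if (length(genes) == 0) {
      skipped <- c(skipped, s)
      next
    }
    res[[s]] <- hypergeom_enrich(genes, background, annotations)
  }
  sig <- lapply(res, function(e) e$term[e$significant])
  tab <- table(unlist(sig))
  list(per_species = res, skipped = skipped,
       consistent_terms = names(tab)[tab >= min_species])
}

#' Write an enrichment table as TSV
#' @param result An `enrichment_result`.
#' @param path Output path.
#' @export
write_enrichment <- function(result, path) {
  write_tsv_schema(as.data.frame(result), path)
}
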