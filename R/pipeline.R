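# End-to-end driver: screen -> group gene sets -> RER association ->
# omega_c filter -> evidence overlap -> gene reuse -> enrichment, with a
# machine-readable summary. Used by the numbered analysis scripts and by
# the acceptance checks.

default_thresholds <- function() {
  list(alpha_fdr = 0.05, alpha_kendall = 0.01, omega_c_min = 3,
       q_enrich = 0.05, min_taxa = 20)
}

#' Load a pipeline run configuration
#'
#' @param config A list, or the path of a YAML file. Recognized fields:
#'   `seed`; `simulate` (list of [sim_config()] overrides) or `inputs`
#'   (paths: `tree`, `ecomorph_map`, `screen_tsv`, `rate_matrix`,
#'   `omega_c`, `gmt`); `thresholds` (`alpha_fdr`, `alpha_kendall`,
#'   `omega_c_min`, `q_enrich`, `min_taxa`); `output_dir`;
#'   `randomization_draws` (0 disables).
#' @return Normalized config list.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  th <- utils::modifyList(default_thresholds(),
                          if (is.null(config$thresholds)) list() else config$thresholds)
  stopifnot(th$alpha_fdr >= 0, th$alpha_fdr < 1,
            th$alpha_kendall > 0, th$alpha_kendall < 1,
            th$omega_c_min > 0, th$q_enrich > 0, th$q_enrich < 1)
  config$thresholds <- th
  if (is.null(config$seed)) config$seed <- 1
  if (is.null(config$randomization_draws)) config$randomization_draws <- 0
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config needs either a 'simulate' or an 'inputs' section")
  config
}

# assemble the input bundle (simulated or read from files)
pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sc <- do.call(sim_config,
                  utils::modifyList(list(seed = config$seed), config$simulate))
    st <- simulate_time_tree(sc)
    smx <- simulate_selection_matrix(st, sc)
    list(tree = st$tree, ecomorph_map = st$ecomorph_map,
         calls = attr(smx, "calls"), truth = attr(smx, "truth"),
         rates = simulate_rate_matrix(st, sc),
         omega = simulate_omega_c(st, sc),
         annotations = simulate_annotations(
           sc, sim_genes(sc),
           planted_pool = attr(smx, "truth")$gene)$annotations)
  } else {
    inp <- config$inputs
    tree <- read_time_tree(inp$tree)
    list(tree = tree,
         ecomorph_map = read_species_map(inp$ecomorph_map),
         calls = read_screen_results(inp$screen_tsv, dialect = "tsv",
                                     tree = tree),
         truth = NULL,
         rates = if (!is.null(inp$rate_matrix)) read_rate_matrix(inp$rate_matrix),
         omega = if (!is.null(inp$omega_c)) read_omega_c(inp$omega_c),
         annotations = if (!is.null(inp$gmt)) read_gmt(inp$gmt))
  }
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
}

# degenerate-tolerant wrapper: returns list(error = msg) instead of failing,
# for analyses that legitimately have nothing to fit (e.g. empty screens)
soft_stage <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

#' Run the full convergence/reuse pipeline
#'
#' Orchestrates the whole analysis in the order of the study design:
#' selection screen aggregation with within-gene FDR, per-ecomorph gene
#' sets and their Venn partition, RER trait association, omega_c
#' filtering, three-way evidence overlap, gene-reuse regression on node
#' age, and per-group enrichment (with optional matched-size
#' randomization). All stage tables are written under `output_dir` with
#' schema headers, plus `summary.json` and a run log.
#'
#' @param config See [load_run_config()].
#' @return The summary list, invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  out_dir <- if (is.null(config$output_dir)) tempfile("run") else config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  log <- file.path(out_dir, "run.log")
  logline <- function(...) cat(..., "\n", sep = "", file = log, append = TRUE)
  cat("", file = log)
  logline("ecoconv ", as.character(utils::packageVersion("ecoconv")),
          " | R ", as.character(getRversion()))
  logline("seed: ", config$seed)
  logline("thresholds: ", paste(names(th), unlist(th), sep = "=", collapse = ", "))

  inp <- stage("inputs", pipeline_inputs(config))
  meta <- stage("metadata", make_branch_metadata(inp$tree, inp$ecomorph_map))
  val <- stage("validate", validate_inputs(inp))
  if (any(val$level == "fatal"))
    stop("stage [validate]: ", paste(val$message[val$level == "fatal"],
                                     collapse = "; "))

  sm <- stage("screen", build_selection_matrix(inp$calls, th$alpha_fdr, meta))
  write_selection_matrix(sm, file.path(out_dir, "selection_matrix.tsv"))
  bias <- soft_stage(branch_bias_check(sm))

  groups <- setdiff(unique(meta$ecomorph[!is.na(meta$ecomorph)]), "outgroup")
  sets <- stage("groups", lapply(stats::setNames(groups, groups), function(e)
    genes_selected_in_group(sm, e)))
  for (e in groups)
    write_gene_set(sets[[e]], file.path(out_dir, paste0("selected_", e, ".txt")))
  vp <- if (length(groups) == 3)
    stage("venn", venn_partition(sets[[1]], sets[[2]], sets[[3]], labels = groups))

  rer_sets <- stats::setNames(vector("list", length(groups)), groups)
  assoc_tabs <- list()
  if (!is.null(inp$rates)) {
    rers <- stage("rer", compute_rers(compute_master_lengths(inp$rates)))
    for (e in groups) {
      assoc <- stage("rer", trait_association(
        rers, foreground_branches(meta, e), alpha = th$alpha_kendall))
      assoc_tabs[[e]] <- assoc
      rer_sets[[e]] <- assoc$gene[assoc$significant]
      write_tsv_schema(assoc, file.path(out_dir, paste0("rer_assoc_", e, ".tsv")))
    }
  }

  omega_sets <- stats::setNames(vector("list", length(groups)), groups)
  if (!is.null(inp$omega)) {
    for (e in groups)
      omega_sets[[e]] <- stage("omega_c", filter_omega_c(
        inp$omega, threshold = th$omega_c_min, mode = "any2spe",
        foreground = foreground_branches(meta, e)))
  }

  overlaps <- lapply(stats::setNames(groups, groups), function(e)
    overlap_evidence(sets[[e]],
                     if (is.null(rer_sets[[e]])) character(0) else rer_sets[[e]],
                     if (is.null(omega_sets[[e]])) character(0) else omega_sets[[e]]))

  pairs <- stage("reuse", same_ecomorph_pairs(meta))
  pairs <- stage("reuse", node_age_table(inp$tree, pairs))
  counts <- stage("reuse", pair_shared_counts(sm, pairs))
  reuse <- soft_stage({
    recs <- normalize_by_max(counts)
    write_tsv_schema(recs, file.path(out_dir, "reuse_pairs.tsv"))
    list(fit = reuse_regression(recs), max_count = attr(recs, "max_count"),
         records = recs)
  })

  enrich <- list()
  rand <- list()
  if (!is.null(inp$annotations)) {
    background <- rownames(sm$selected)
    for (e in groups) {
      enrich[[e]] <- soft_stage({
        res <- hypergeom_enrich(sets[[e]], background, inp$annotations,
                                q_threshold = th$q_enrich)
        write_enrichment(res, file.path(out_dir, paste0("enrichment_", e, ".tsv")))
        res
      })
      if (config$randomization_draws > 0 && is.null(enrich[[e]]$error))
        rand[[e]] <- stage("randomization", randomization_test(
          sets[[e]], background, inp$annotations,
          terms = enrich[[e]]$term[seq_len(min(5, nrow(enrich[[e]])))],
          draws = config$randomization_draws, seed = config$seed))
    }
  }

  summarize_fit <- function(f) if (!is.null(f$error)) list(error = f$error) else
    list(slope = f$slope, intercept = f$intercept, r_squared = f$r_squared,
         f_stat = f$f_stat, p = f$p, n = f$n)
  summary <- list(
    seed = config$seed, thresholds = th,
    n_genes = length(sm$genes), n_branches = nrow(meta),
    group_set_sizes = lapply(sets, length),
    venn_regions = if (!is.null(vp)) as.list(vp$regions),
    exclusive_fractions = if (!is.null(vp)) as.list(vp$exclusive_fraction),
    rer_significant = lapply(rer_sets, function(x) if (is.null(x)) 0L else length(x)),
    omega_significant = lapply(omega_sets, function(x) if (is.null(x)) 0L else length(x)),
    overlap_fractions = lapply(overlaps, function(o) as.list(o$overlap_fractions)),
    bias_check = summarize_fit(bias),
    reuse = if (!is.null(reuse$error)) list(error = reuse$error) else
      c(summarize_fit(reuse$fit), list(max_count = reuse$max_count,
                                       n_pairs = nrow(reuse$records))),
    enrichment = lapply(enrich, function(e) if (!is.null(e$error))
      list(error = e$error) else
      list(n_significant = sum(e$significant), top_term = e$term[1],
           top_q = e$q[1])),
    randomization = lapply(rand, function(r)
      list(terms = r$term, empirical_p = r$empirical_p)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  logline("completed; outputs in ", out_dir)
  invisible(summary)
}

#' Validate cross-consistency of an input bundle
#'
#' Report-based checks: species present in the ecomorph map but not the
#' tree (fatal), tree tips missing from the map (fatal), branch names in
#' the screen calls or rate matrix unmatched by any tree bipartition
#' (warning), and omega_c branch names unmatched (warning).
#'
#' @param inputs List with `tree`, `ecomorph_map`, and optionally `calls`,
#'   `rates`, `omega`.
#' @return Data frame `level` (`"fatal"`/`"warning"`), `message`; zero rows
#'   when the bundle is clean.
#' @export
validate_inputs <- function(inputs) {
  rep <- list()
  add <- function(level, msg) rep[[length(rep) + 1L]] <<-
    data.frame(level = level, message = msg, stringsAsFactors = FALSE)
  tips <- inputs$tree$tip.label
  extra <- setdiff(inputs$ecomorph_map$species, tips)
  if (length(extra))
    add("fatal", paste("species in map but not in tree:",
                       paste(extra, collapse = ", ")))
  missing <- setdiff(tips, inputs$ecomorph_map$species)
  if (length(missing))
    add("fatal", paste("tree tips missing from map:",
                       paste(missing, collapse = ", ")))
  ids <- branch_table(inputs$tree)$branch_id
  check_branches <- function(b, what) {
    bad <- setdiff(unique(b), ids)
    if (length(bad))
      add("warning", paste0(what, ": ", length(bad),
                            " branch id(s) unmatched by any tree bipartition"))
  }
  if (!is.null(inputs$calls)) check_branches(inputs$calls$branch_id, "screen calls")
  if (!is.null(inputs$rates)) check_branches(inputs$rates$branches, "rate matrix")
  if (!is.null(inputs$omega))
    check_branches(c(inputs$omega$branch1, inputs$omega$branch2), "omega_c table")
  if (length(rep) == 0)
    return(data.frame(level = character(), message = character()))
  do.call(rbind, rep)
}
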