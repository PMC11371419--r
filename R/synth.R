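# Synthetic study generator: a pure-birth chronogram with repeatedly
# evolved ecomorph labels, per-gene rate matrices with foreground
# acceleration, selection indicators with age-decaying pairwise reuse, and
# annotation sets with planted enrichment. Every generator derives its
# randomness from the config seed, so identical configs give identical
# outputs and the full pipeline is bit-reproducible.

#' Simulation configuration
#'
#' Defaults emulate the scale and structure of a 30-genome ecomorph screen:
#' 22 focal species split into trawlers, gleaners and aerial hawkers
#' (8/5/9) plus 8 outgroups; a chronogram of root age 50 My; a baseline
#' per-branch selection probability of 1% (which puts per-group union gene
#' sets in the few-percent range of the screen, as observed in real
#' screens); a 5% convergent-gene fraction per ecomorph with selection
#' probability 0.6 on foreground branches; pair-level reuse decaying at
#' 0.03 per My; a 2x foreground rate multiplier under 0.2 lognormal noise.
#'
#' @param seed Integer seed controlling all generators.
#' @param n_taxa Number of tips (default 30).
#' @param n_outgroup Number of outgroup tips (default 8).
#' @param n_genes Number of genes (default 2000).
#' @param root_age Root age of the chronogram, My (default 50).
#' @param pi0 Baseline per-branch selection probability.
#' @param rho_conv Fraction of genes convergent per ecomorph.
#' @param p_fg Selection probability on foreground branches of convergent
#'   genes.
#' @param lambda_age Reuse decay rate (per My, >= 0).
#' @param mu_fg Foreground branch-length rate multiplier (>= 1).
#' @param sigma Lognormal noise scale for gene branch lengths.
#' @param missing_rate Fraction of absent gene x branch cells.
#' @param alpha FDR threshold the simulated p-values are calibrated to.
#' @param n_terms Number of annotation terms.
#' @param term_size Length-2 range of term sizes.
#' @param planted_effect Over-sampling weight of planted-pool genes in the
#'   planted term (1 = no planting).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_taxa = 30, n_outgroup = 8,
                       n_genes = 2000, root_age = 50,
                       pi0 = 0.01, rho_conv = 0.05, p_fg = 0.6,
                       lambda_age = 0.03, mu_fg = 2, sigma = 0.2,
                       missing_rate = 0.05, alpha = 0.05,
                       n_terms = 50, term_size = c(20, 200),
                       planted_effect = 20) {
  stopifnot(n_taxa >= 4, n_outgroup >= 0, n_outgroup < n_taxa - 5,
            pi0 >= 0, pi0 <= 1, rho_conv >= 0, rho_conv <= 1,
            p_fg >= 0, p_fg <= 1, lambda_age >= 0, mu_fg >= 1,
            sigma >= 0, missing_rate >= 0, missing_rate < 1,
            alpha > 0, alpha < 1, n_terms >= 2)
  structure(as.list(environment()), class = "sim_config")
}

ecomorph_labels <- c("trawler", "gleaner", "aerial_hawker")
region_labels <- c("Nr", "WP", "EP", "Af", "Nt", "IM", "Oc")

#' Simulate the study chronogram with ecomorph labels
#'
#' A pure-birth tree conditioned on `n_taxa` tips, rescaled to the
#' configured root age (ultrametric by construction). Ecomorph labels are
#' assigned cyclically along the ladderized tip order of the focal species,
#' which guarantees each ecomorph appears in several non-sister clades —
#' the repeated-evolution structure the downstream analyses assume. The
#' last block of the ladder is tagged as outgroup.
#'
#' @param config A `sim_config`.
#' @return List of class `sim_tree`: `tree` (ultrametric `phylo` with tips
#'   `sp01`, ...) and `ecomorph_map` (data frame `species`, `ecomorph`,
#'   `region`).
#' @export
simulate_time_tree <- function(config) {
  set.seed(config$seed)
  tr <- ape::rphylo(config$n_taxa, birth = 0.1, death = 0)
  d <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * config$root_age / max(d)
  tr <- ape::ladderize(tr)
  ord <- tr$edge[tr$edge[, 2] <= config$n_taxa, 2]  # ladderized tip order
  new <- character(config$n_taxa)
  new[ord] <- sprintf("sp%02d", seq_len(config$n_taxa))
  tr$tip.label <- new
  species <- sprintf("sp%02d", seq_len(config$n_taxa))
  n_focal <- config$n_taxa - config$n_outgroup
  eco <- c(rep(ecomorph_labels, length.out = n_focal),
           rep("outgroup", config$n_outgroup))
  reg <- c(rep(region_labels, length.out = n_focal),
           rep("OG", config$n_outgroup))
  list_out <- list(tree = tr,
                   ecomorph_map = data.frame(species = species,
                                             ecomorph = eco, region = reg,
                                             stringsAsFactors = FALSE))
  class(list_out) <- "sim_tree"
  list_out
}

#' Gene identifiers of a simulated study
#' @param config A `sim_config`.
#' @return Character vector of gene ids (`g00001`, ...).
#' @export
sim_genes <- function(config) sprintf("g%05d", seq_len(config$n_genes))

# deterministic ground-truth assignment of convergent genes to ecomorphs
# (shared by the rate and selection simulators: both derive it from the
# same config seed)
convergent_truth <- function(config) {
  set.seed(config$seed * 7 + 13)
  genes <- sim_genes(config)
  n_conv <- round(config$rho_conv * config$n_genes)
  pool <- sample(genes)
  out <- data.frame(gene = character(), ecomorph = character(),
                    stringsAsFactors = FALSE)
  for (i in seq_along(ecomorph_labels)) {
    if (n_conv == 0) break
    block <- pool[((i - 1) * n_conv + 1):(i * n_conv)]
    out <- rbind(out, data.frame(gene = block, ecomorph = ecomorph_labels[i],
                                 stringsAsFactors = FALSE))
  }
  out
}

# gene x branch foreground indicator: terminal branches of the convergent
# gene's ecomorph
foreground_matrix <- function(st, config, branches) {
  truth <- convergent_truth(config)
  meta <- make_branch_metadata(st$tree, st$ecomorph_map)
  genes <- sim_genes(config)
  fg <- matrix(FALSE, length(genes), length(branches),
               dimnames = list(genes, branches))
  for (e in ecomorph_labels) {
    g <- truth$gene[truth$ecomorph == e]
    b <- meta$branch_id[meta$is_terminal & !is.na(meta$ecomorph) &
                          meta$ecomorph == e]
    fg[genes %in% g, branches %in% b] <- TRUE
  }
  fg
}

#' Simulate a per-gene branch-length (rate) matrix
#'
#' Gene branch length = chronogram branch length (My) x gene-specific rate
#' (substitutions/site/My, lognormal around 2e-3) x `mu_fg` on foreground
#' branches of convergent genes x multiplicative lognormal noise of scale
#' `sigma`; cells are deleted at `missing_rate` to emulate patchy
#' alignments.
#'
#' @param st A `sim_tree`.
#' @param config A `sim_config`.
#' @return A `rate_matrix`; the convergent-gene truth table is attached as
#'   attribute `"truth"`.
#' @export
simulate_rate_matrix <- function(st, config) {
  bt <- branch_table(st$tree)
  genes <- sim_genes(config)
  fg <- foreground_matrix(st, config, bt$branch_id)
  set.seed(config$seed * 7 + 17)
  rate <- stats::rlnorm(length(genes), meanlog = log(2e-3), sdlog = 0.5)
  base <- outer(rate, bt$length)
  noise <- matrix(exp(stats::rnorm(length(base), 0, config$sigma)),
                  nrow(base))
  L <- base * ifelse(fg, config$mu_fg, 1) * noise
  L[matrix(stats::runif(length(L)) < config$missing_rate, nrow(L))] <- NA
  dimnames(L) <- list(genes, bt$branch_id)
  rm <- rate_matrix(L)
  attr(rm, "truth") <- convergent_truth(config)
  rm
}

#' Simulate the gene x branch selection matrix
#'
#' Non-foreground cells are selected independently with probability `pi0`.
#' For a convergent gene, the terminal branches of its ecomorph follow a
#' shared latent gene-pool model with age-dependent retention: the gene is
#' present at the root and is lost along each branch with rate
#' `lambda_age` per My; a species can only show selection (probability
#' `p_fg`) if its lineage retained the gene. Two species at node age t
#' therefore share the gene with probability proportional to
#' exp(-lambda_age * (root_age + t)), so reuse decays with divergence
#' time; `lambda_age = 0` switches the decay off.
#'
#' P-values are generated consistently with the within-gene FDR rule:
#' selected cells draw from Beta(0.05, 10) truncated below
#' `alpha / n_branches(gene)` (which guarantees q <= alpha after
#' Benjamini-Hochberg within the gene), unselected cells draw uniform(0,1).
#'
#' @param st A `sim_tree`.
#' @param config A `sim_config`.
#' @return A `selection_matrix` whose `selected` entries are the simulated
#'   truth; attributes `"truth"` (convergent assignment) and `"calls"`
#'   (long-format gene/branch/p records for the screen readers).
#' @export
simulate_selection_matrix <- function(st, config) {
  bt <- branch_table(st$tree)
  meta <- make_branch_metadata(st$tree, st$ecomorph_map)
  genes <- sim_genes(config)
  truth <- convergent_truth(config)
  fg <- foreground_matrix(st, config, bt$branch_id)
  set.seed(config$seed * 7 + 19)
  nb <- nrow(bt)
  present <- matrix(stats::runif(length(genes) * nb) >= config$missing_rate,
                    length(genes), nb, dimnames = list(genes, bt$branch_id))
  sel <- matrix(stats::runif(length(genes) * nb) < config$pi0,
                length(genes), nb, dimnames = list(genes, bt$branch_id))
  # lineage retention for convergent genes: loss events on each branch of
  # the root -> tip path at rate lambda_age
  surv_prob <- exp(-config$lambda_age * bt$length)
  tip_paths <- root_tip_paths(st$tree, bt)
  for (r in seq_len(nrow(truth))) {
    g <- match(truth$gene[r], genes)
    e <- truth$ecomorph[r]
    sp <- meta$species[meta$is_terminal & !is.na(meta$ecomorph) &
                         meta$ecomorph == e]
    branch_surv <- stats::runif(nb) < surv_prob
    for (s in sp) {
      j <- match(s, bt$branch_id)  # terminal branch id == species name
      retained <- all(branch_surv[tip_paths[[s]]])
      sel[g, j] <- retained && (stats::runif(1) < config$p_fg)
    }
  }
  sel[!present] <- NA
  # p-values consistent with the calls
  pm <- matrix(NA_real_, length(genes), nb,
               dimnames = list(genes, bt$branch_id))
  m_g <- rowSums(present)
  is_sel <- !is.na(sel) & sel
  is_bg <- !is.na(sel) & !sel
  pm[is_bg] <- stats::runif(sum(is_bg))
  if (any(is_sel)) {
    cap <- (config$alpha / m_g)[row(pm)[is_sel]]
    u <- stats::runif(sum(is_sel))
    pm[is_sel] <- stats::qbeta(u * stats::pbeta(cap, 0.05, 10), 0.05, 10)
  }
  sm <- structure(list(selected = matrix(as.integer(sel), nrow(sel),
                                         dimnames = dimnames(sel)),
                       p = pm, q = NULL, branches = meta, genes = genes,
                       alpha = config$alpha),
                  class = "selection_matrix")
  idx <- which(!is.na(pm), arr.ind = TRUE)
  attr(sm, "calls") <- data.frame(gene = genes[idx[, 1]],
                                  branch_id = bt$branch_id[idx[, 2]],
                                  p_raw = pm[idx], stringsAsFactors = FALSE)
  attr(sm, "truth") <- truth
  sm
}

# indices (into the branch table) of the branches on each root->tip path
root_tip_paths <- function(tree, bt = branch_table(tree)) {
  ntip <- ape::Ntip(tree)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of <- integer(max(tree$edge))
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  out <- lapply(seq_len(ntip), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      path <- c(path, edge_of[node])
      node <- parent[node]
    }
    path
  })
  stats::setNames(out, tree$tip.label)
}

#' Simulate term annotations with an optional planted enrichment
#'
#' Terms draw genes uniformly from the background at sizes uniform in
#' `term_size`; the planted term instead samples with weight
#' `planted_effect` on the genes of `planted_pool`, so `planted_effect = 1`
#' reduces to a null annotation set.
#'
#' @param config A `sim_config`.
#' @param background Character vector: the gene universe.
#' @param planted_pool Genes to over-sample in the planted term (e.g. the
#'   convergent genes of one ecomorph); `NULL` for no planted term.
#' @return List: `annotations` (named list term -> genes, GMT-ready) and
#'   `planted` (the planted term id or `NA`).
#' @export
simulate_annotations <- function(config, background, planted_pool = NULL) {
  set.seed(config$seed * 7 + 23)
  sizes <- sample(config$term_size[1]:config$term_size[2], config$n_terms,
                  replace = TRUE)
  ids <- sprintf("T%03d", seq_len(config$n_terms))
  ann <- stats::setNames(lapply(sizes, function(s)
    sort(sample(background, min(s, length(background))))), ids)
  planted <- NA_character_
  if (!is.null(planted_pool) && length(planted_pool) > 0) {
    planted <- ids[1]
    w <- ifelse(background %in% planted_pool, config$planted_effect, 1)
    ann[[planted]] <- sort(sample(background, sizes[1], prob = w))
  }
  list(annotations = ann, planted = planted)
}

#' Simulate an omega_c branch-pair convergence table
#'
#' Convergent genes of each ecomorph receive, with probability
#' `hit_rate`, an `any2spe` record on a random pair of that ecomorph's
#' terminal branches with omega_c >= 3; background records draw omega_c
#' from an exponential (mostly < 3) on random branch pairs and random
#' modes. This emulates the shape of the consumed convergence-tool output,
#' not its statistics.
#'
#' @param st A `sim_tree`.
#' @param config A `sim_config`.
#' @param hit_rate Probability a convergent gene gets a strong record.
#' @param n_background Number of background noise records.
#' @return Data frame in the omega_c table layout (see [read_omega_c()]).
#' @export
simulate_omega_c <- function(st, config, hit_rate = 0.3,
                             n_background = 500) {
  set.seed(config$seed * 7 + 29)
  meta <- make_branch_metadata(st$tree, st$ecomorph_map)
  truth <- convergent_truth(config)
  genes <- sim_genes(config)
  rows <- list()
  for (r in seq_len(nrow(truth))) {
    if (stats::runif(1) >= hit_rate) next
    e <- truth$ecomorph[r]
    b <- meta$branch_id[meta$is_terminal & !is.na(meta$ecomorph) &
                          meta$ecomorph == e]
    pr <- sample(b, 2)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = truth$gene[r], branch1 = pr[1], branch2 = pr[2],
      mode = "any2spe", omega_c = 3 + stats::rexp(1, 0.5),
      stringsAsFactors = FALSE)
  }
  all_b <- meta$branch_id
  for (i in seq_len(n_background)) {
    pr <- sample(all_b, 2)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = sample(genes, 1), branch1 = pr[1], branch2 = pr[2],
      mode = sample(c("any2spe", "any2any", "spe2spe"), 1),
      omega_c = stats::rexp(1, 1), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Number of non-adjacent same-ecomorph blocks along the tip ladder
#'
#' Diagnostic that each ecomorph is scattered over the tree (repeated
#' evolution) rather than forming a single clade.
#'
#' @param st A `sim_tree`.
#' @return Named integer vector: ecomorph -> number of maximal runs in the
#'   ladderized tip order.
#' @export
ecomorph_run_counts <- function(st) {
  ord <- st$tree$edge[st$tree$edge[, 2] <= ape::Ntip(st$tree), 2]
  eco <- st$ecomorph_map$ecomorph[match(st$tree$tip.label[ord],
                                        st$ecomorph_map$species)]
  vapply(unique(eco), function(e) {
    runs <- rle(eco == e)
    sum(runs$values)
  }, integer(1))
}
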