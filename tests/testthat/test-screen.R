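test_that("within-gene BH adjustment matches the step-up formula", {
  expect_equal(fdr_within_gene(0.01), 0.01)
  expect_equal(fdr_within_gene(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_equal(fdr_within_gene(rep(0.5, 4)), rep(0.5, 4))
  expect_error(fdr_within_gene(numeric(0)), "empty")
  expect_error(fdr_within_gene(c(0.1, 1.2)), "\\[0,1\\]")
  set.seed(10)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    q <- fdr_within_gene(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(diff(sort(q)) >= -1e-15))  # monotone after sorting
    expect_true(all(q <= 1))
  }
})

test_that("screen results round-trip through both dialects", {
  st <- simulate_time_tree(sim_config(seed = 21, n_taxa = 8, n_outgroup = 2))
  bt <- branch_table(st$tree)
  set.seed(5)
  calls <- expand.grid(gene = c("gA", "gB", "gC"), branch_id = bt$branch_id,
                       stringsAsFactors = FALSE)
  calls$p_raw <- round(runif(nrow(calls)), 6)
  for (dialect in c("tsv", "native")) {
    dir <- withr::local_tempdir()
    paths <- write_screen_results(calls, dir, dialect = dialect)
    back <- read_screen_results(paths, dialect = dialect, tree = st$tree)
    key <- function(d) d[order(d$gene, d$branch_id), ]
    expect_equal(key(back)$p_raw, key(calls)$p_raw, tolerance = 1e-12)
    expect_identical(key(back)$branch_id, key(calls)$branch_id)
    expect_length(attr(back, "unresolved"), 0)
  }
})

test_that("unresolvable branch names are reported, not dropped silently", {
  st <- simulate_time_tree(sim_config(seed = 21, n_taxa = 8, n_outgroup = 2))
  dir <- withr::local_tempdir()
  calls <- data.frame(gene = "g1", branch_id = c("sp01", "not_a_branch"),
                      p_raw = c(0.1, 0.2))
  path <- write_screen_results(calls, dir, dialect = "tsv")
  expect_warning(back <- read_screen_results(path, tree = st$tree),
                 "did not resolve")
  expect_identical(attr(back, "unresolved"), "not_a_branch")
  expect_equal(nrow(back), 1)
})

test_that("selection matrix thresholds q and keeps absent distinct", {
  meta <- data.frame(branch_id = c("s1", "s2"), is_terminal = TRUE,
                     species = c("s1", "s2"), ecomorph = "gleaner",
                     region = "Nr")
  calls <- data.frame(gene = c("g1", "g1", "g2"),
                      branch_id = c("s1", "s2", "s1"),
                      p_raw = c(0.02, 0.06, 0.5))
  sm <- build_selection_matrix(calls, alpha = 0.05, branch_info = meta)
  # g1: BH over (0.02, 0.06) -> q = (0.04, 0.06): only s1 selected
  expect_equal(sm$selected["g1", c("s1", "s2")], c(s1 = 1L, s2 = 0L))
  # g2 untested on s2: absent, not 0
  expect_true(is.na(sm$selected["g2", "s2"]))
  expect_equal(sm$selected["g2", "s1"], 0L)
  expect_error(
    build_selection_matrix(data.frame(gene = "g", branch_id = "s9",
                                      p_raw = 0.1), 0.05, meta),
    "metadata missing")
})

test_that("per-gene FDR never mixes p-values across genes", {
  meta <- data.frame(branch_id = c("s1", "s2", "s3"), is_terminal = TRUE,
                     species = c("s1", "s2", "s3"), ecomorph = "trawler",
                     region = "Nr")
  # sentinel gene alone: its q depends only on its own branches
  lone <- data.frame(gene = "lone", branch_id = c("s1", "s2", "s3"),
                     p_raw = c(0.01, 0.02, 0.9))
  crowd <- rbind(lone, data.frame(gene = paste0("noise", 1:20),
                                  branch_id = "s1", p_raw = 1e-6))
  q_alone <- build_selection_matrix(lone, 0.05, meta)$q["lone", ]
  q_crowd <- build_selection_matrix(crowd, 0.05, meta)$q["lone", ]
  expect_equal(q_alone, q_crowd)
  expect_equal(unname(q_alone[c("s1", "s2", "s3")]), c(0.03, 0.03, 0.9))
})

test_that("selected counts match a brute-force recount and ignore order", {
  st <- simulate_time_tree(sim_config(seed = 23, n_taxa = 10, n_outgroup = 2))
  meta <- make_branch_metadata(st$tree, st$ecomorph_map)
  set.seed(6)
  calls <- expand.grid(gene = sprintf("g%03d", 1:200),
                       branch_id = meta$branch_id,
                       stringsAsFactors = FALSE)
  calls <- calls[runif(nrow(calls)) > 0.2, ]
  calls$p_raw <- runif(nrow(calls))^3
  sm <- build_selection_matrix(calls, 0.05, meta)
  # brute force: recompute q per gene from the raw call list with the oracle
  brute <- integer(nrow(meta)); names(brute) <- meta$branch_id
  for (g in unique(calls$gene)) {
    sub <- calls[calls$gene == g, ]
    hit <- sub$branch_id[bh_oracle(sub$p_raw) <= 0.05]
    brute[hit] <- brute[hit] + 1L
  }
  got <- colSums(sm$selected == 1, na.rm = TRUE)
  expect_equal(got[names(brute)], brute)
  # permutation invariance of the input record order
  sm2 <- build_selection_matrix(calls[sample(nrow(calls)), ], 0.05, meta)
  expect_equal(sum(sm2$selected == 1, na.rm = TRUE),
               sum(sm$selected == 1, na.rm = TRUE))
})

test_that("branch-representation bias check has defined conventions", {
  st <- simulate_time_tree(sim_config(seed = 23, n_taxa = 10, n_outgroup = 2))
  meta <- make_branch_metadata(st$tree, st$ecomorph_map)
  set.seed(7)
  calls <- expand.grid(gene = sprintf("g%03d", 1:150),
                       branch_id = meta$branch_id,
                       stringsAsFactors = FALSE)
  calls <- calls[runif(nrow(calls)) > 0.3, ]
  calls$p_raw <- runif(nrow(calls))^2
  sm <- build_selection_matrix(calls, 0.05, meta)
  fit <- branch_bias_check(sm)
  counts <- attr(fit, "counts")
  oracle <- ols_oracle(counts$tested, counts$selected)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-12)
  expect_equal(fit$f_stat, oracle$f_stat, tolerance = 1e-10)
  expect_equal(fit$p, oracle$p, tolerance = 1e-12)
})

test_that("ols_fit handles exact and degenerate fits", {
  x <- 1:10
  exact <- ols_fit(x, 2 * x + 1)
  expect_equal(exact$r_squared, 1.0)
  expect_equal(exact$slope, 2)
  flat <- ols_fit(x, rep(3, 10))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$p, 1)
  expect_error(ols_fit(rep(1, 5), 1:5), "zero variance")
})
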