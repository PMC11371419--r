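test_that("hypergeometric enrichment p matches exact enumeration", {
  bg <- sprintf("g%02d", 1:10)
  ann <- list(term5 = bg[1:5], all = bg)
  res <- hypergeom_enrich(bg[1:4], bg, ann)
  # N=10, K=5, n=4, k=4: C(5,4)/C(10,4) = 5/210
  expect_equal(res$p[res$term == "term5"], 5 / 210, tolerance = 1e-12)
  # a term covering the whole background is never enriched
  expect_equal(res$p[res$term == "all"], 1)
  # zero hits: upper tail is still a valid probability of 1
  res0 <- hypergeom_enrich(bg[6:9], bg, list(t = bg[1:5]))
  expect_equal(res0$k, 0)
  expect_equal(res0$p, 1)
  expect_error(hypergeom_enrich(character(0), bg, ann), "empty study")
  expect_error(hypergeom_enrich("not_there", bg, ann), "subset")
})

test_that("hypergeom p equals one-sided Fisher exact over random tables", {
  set.seed(20)
  for (i in 1:100) {
    N <- sample(20:200, 1)
    bg <- sprintf("g%03d", 1:N)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    study <- sample(bg, n)
    ann <- list(tm = sample(bg, K))
    res <- hypergeom_enrich(study, bg, ann)
    expect_equal(res$p, fisher_oracle(res$k, K, n, N), tolerance = 1e-12)
  }
})

test_that("enrichment p is monotone decreasing in the hit count", {
  N <- 200; K <- 40; n <- 30
  p <- stats::phyper(seq(0, min(K, n)) - 1, K, N - K, n, lower.tail = FALSE)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("GO depth filter keeps terms within reach of the root", {
  # chain root -> a -> b -> c -> d -> e -> f (f at depth 6)
  edges <- data.frame(child = c("a", "b", "c", "d", "e", "f"),
                      parent = c("root", "a", "b", "c", "d", "e"))
  g <- term_graph(edges)
  kept <- go_depth_filter(c("root", "c", "e", "f"), g, max_depth = 5,
                          root = "root")
  expect_setequal(as.character(kept), c("root", "c", "e"))
  expect_warning(
    flagged <- go_depth_filter(c("a", "mystery"), g, max_depth = 5,
                               root = "root"),
    "flagged")
  expect_identical(attr(flagged, "flagged"), "mystery")
  expect_true("mystery" %in% flagged)
})

test_that("depths in a random DAG equal a breadth-first-search oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 30
    ids <- sprintf("n%02d", 1:n)
    # random DAG: edges only from lower to higher index (root = n01)
    edges <- do.call(rbind, lapply(2:n, function(i) {
      np <- sample(1:2, 1)
      data.frame(child = ids[i],
                 parent = ids[sample(seq_len(i - 1), min(np, i - 1))])
    }))
    g <- term_graph(edges)
    # BFS oracle on the parent lists
    depth <- stats::setNames(rep(Inf, n), ids)
    depth["n01"] <- 0
    queue <- "n01"
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      kids <- edges$child[edges$parent == cur]
      upd <- kids[depth[kids] > depth[cur] + 1]
      depth[upd] <- depth[cur] + 1
      queue <- c(queue, upd)
    }
    for (md in c(2, 4, 6)) {
      kept <- go_depth_filter(ids, g, max_depth = md, root = "n01")
      expect_setequal(as.character(kept), ids[depth <= md])
    }
  }
})

test_that("obo reading and annotation propagation follow is_a", {
  obo <- c("format-version: 1.2", "",
           "[Term]", "id: T:1", "name: rootish", "",
           "[Term]", "id: T:2", "name: mid", "is_a: T:1 ! rootish", "",
           "[Term]", "id: T:3", "name: leaf", "is_a: T:2 ! mid", "",
           "[Term]", "id: T:9", "name: gone", "is_obsolete: true")
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(obo, path)
  g <- read_obo(path)
  expect_setequal(g$terms$id, c("T:1", "T:2", "T:3"))
  expect_setequal(term_descendants(g, "T:1"), c("T:2", "T:3"))
  prop <- propagate_annotations(list(`T:3` = c("gA", "gB"), `T:2` = "gC"), g)
  expect_setequal(prop[["T:1"]], c("gA", "gB", "gC"))
  expect_setequal(prop[["T:2"]], c("gA", "gB", "gC"))
  expect_setequal(prop[["T:3"]], c("gA", "gB"))
})

test_that("gmt files round-trip", {
  ann <- list(TA = c("g1", "g2"), TB = c("g2", "g3", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann, path)
  back <- read_gmt(path)
  expect_equal(back, ann)
})

test_that("randomization test is seeded, floored, and tie-aware", {
  set.seed(22)
  bg <- sprintf("g%03d", 1:200)
  ann <- list(tm = sample(bg, 50))
  obs <- c(sample(ann$tm, 25), sample(setdiff(bg, ann$tm), 5))
  r1 <- randomization_test(obs, bg, ann, draws = 200, seed = 99)
  r2 <- randomization_test(obs, bg, ann, draws = 200, seed = 99)
  expect_identical(attr(r1, "null_p"), attr(r2, "null_p"))
  expect_identical(r1$empirical_p, r2$empirical_p)
  # strongly enriched observed set: no null draw can beat it
  expect_equal(r1$empirical_p, 1 / 201)
  expect_error(randomization_test(obs, bg, ann, draws = 10, seed = 1),
               "draws >= 100")
  expect_error(randomization_test(c(bg, "zz"), bg, ann, draws = 100, seed = 1),
               "larger than the background")
})

test_that("per-species enrichment is independent across species", {
  meta <- data.frame(branch_id = c("s1", "s2", "s3"), is_terminal = TRUE,
                     species = c("s1", "s2", "s3"),
                     ecomorph = c("gleaner", "gleaner", "gleaner"),
                     region = NA)
  genes <- sprintf("g%02d", 1:40)
  # species 1 and 2 share the same selected set; species 3 has none
  calls <- rbind(
    data.frame(gene = genes[1:10], branch_id = "s1", p_raw = 1e-9),
    data.frame(gene = genes[1:10], branch_id = "s2", p_raw = 1e-9),
    data.frame(gene = genes, branch_id = "s3", p_raw = 0.99))
  sm <- build_selection_matrix(calls, 0.05, meta)
  ann <- list(hit = genes[1:10], other = genes[30:40])
  res <- per_species_enrichment(sm, "gleaner", ann, background = genes)
  expect_identical(res$skipped, "s3")
  expect_equal(res$per_species$s1, res$per_species$s2)
  expect_true("hit" %in% res$consistent_terms)
})
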