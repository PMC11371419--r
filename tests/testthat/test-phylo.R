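test_that("newick reading enforces the tree contract", {
  tr <- toy_tree()
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_error(read_time_tree("((A:1,A:2):1,C:3);", text = TRUE),
               "duplicate tip labels")
  expect_error(read_time_tree("((A,B),C);", text = TRUE),
               "branch lengths")
  # all-zero lengths: warns both about the substitution and the zero tips
  expect_warning(
    expect_warning(read_time_tree("((A,B),C);", text = TRUE,
                                  allow_missing = TRUE), "treating all as 0"),
    "zero-length terminal")
})

test_that("a simulated tree round-trips through write + read", {
  st <- simulate_time_tree(sim_config(seed = 7))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_time_tree(st$tree, path)
  back <- read_time_tree(path)
  bt1 <- branch_table(st$tree)
  bt2 <- branch_table(back)
  o1 <- order(bt1$branch_id); o2 <- order(bt2$branch_id)
  expect_identical(bt1$branch_id[o1], bt2$branch_id[o2])
  expect_equal(bt1$length[o1], bt2$length[o2], tolerance = 1e-9)
})

test_that("node age is half the summed paths to the MRCA", {
  tr <- toy_tree()
  expect_equal(node_age(tr, "A", "B"), 1.0)
  expect_equal(node_age(tr, "A", "C"), 3.0)
  # non-ultrametric: mean of the two unequal paths
  tr2 <- toy_tree("((A:1,B:3):1,C:5);")
  expect_equal(node_age(tr2, "A", "B"), 2.0)
  expect_error(node_age(tr, "A", "A"), "distinct")
  expect_error(node_age(tr, "A", "Z"), "unknown tip")
})

test_that("node age matches the pairwise path-sum oracle and is symmetric", {
  st <- simulate_time_tree(sim_config(seed = 11, n_taxa = 20))
  tr <- st$tree
  coph <- ape::cophenetic.phylo(tr)  # independent tip-to-tip path sums
  tips <- tr$tip.label
  set.seed(1)
  for (k in 1:30) {
    ab <- sample(tips, 2)
    age <- node_age(tr, ab[1], ab[2])
    expect_equal(age, node_age(tr, ab[2], ab[1]))
    expect_equal(age, coph[ab[1], ab[2]] / 2, tolerance = 1e-9)
  }
})

test_that("ultrametric triple property holds on a chronogram", {
  st <- simulate_time_tree(sim_config(seed = 5, n_taxa = 15))
  expect_true(is_ultrametric_tree(st$tree, tol = 1e-8))
  tips <- st$tree$tip.label
  set.seed(2)
  for (k in 1:25) {
    abc <- sample(tips, 3)
    ages <- sort(c(node_age(st$tree, abc[1], abc[2]),
                   node_age(st$tree, abc[1], abc[3]),
                   node_age(st$tree, abc[2], abc[3])))
    expect_lt(abs(ages[3] - ages[2]), 1e-9)
  }
})

test_that("pruning collapses degree-2 nodes and preserves distances", {
  tr <- toy_tree()
  pr <- prune_to_taxa(tr, c("A", "C"))
  expect_setequal(pr$tip.label, c("A", "C"))
  expect_equal(sort(pr$edge.length), c(3, 3))
  expect_equal(ape::Nnode(pr), 1)
  # keep everything is the identity on path lengths
  all_kept <- prune_to_taxa(tr, tr$tip.label)
  expect_equal(ape::cophenetic.phylo(all_kept), ape::cophenetic.phylo(tr))
  expect_error(prune_to_taxa(tr, "A"), "at least 2")

  st <- simulate_time_tree(sim_config(seed = 13))
  set.seed(3)
  for (k in 1:5) {
    keep <- sample(st$tree$tip.label, 10)
    pr <- prune_to_taxa(st$tree, keep)
    d_full <- ape::cophenetic.phylo(st$tree)[keep, keep]
    d_pr <- ape::cophenetic.phylo(pr)[keep, keep]
    expect_equal(d_pr, d_full, tolerance = 1e-9)
    # branch identities restricted to kept tips survive pruning
    ids_pr <- branch_table(pr)$branch_id
    ids_restricted <- vapply(branch_table(st$tree)$branch_id, function(id) {
      inter <- intersect(branch_id_tips(id), keep)
      if (length(inter)) branch_id(inter) else NA_character_
    }, "")
    expect_true(all(ids_pr %in% ids_restricted))
  }
})

test_that("alignment-retention filter applies both rules", {
  clades <- list(Nr = c("a1", "a2"), WP = c("b1", "b2"))
  gene_taxa <- list(
    few = paste0("x", 1:19),                               # below min_taxa
    noclade = c(paste0("x", 1:24), "a1"),                  # missing WP
    good = c(paste0("x", 1:23), "a1", "b2"))
  kept <- filter_alignable_genes(gene_taxa, min_taxa = 20,
                                 clade_requirements = clades)
  expect_identical(kept, "good")

  # re-filter oracle over many random taxon sets
  set.seed(4)
  taxa_pool <- c(paste0("x", 1:30), "a1", "a2", "b1", "b2")
  gt <- lapply(1:500, function(i) sample(taxa_pool, sample(10:34, 1)))
  names(gt) <- paste0("g", 1:500)
  kept <- filter_alignable_genes(gt, min_taxa = 20, clade_requirements = clades)
  brute <- names(gt)[vapply(gt, function(tx)
    length(tx) >= 20 && any(clades$Nr %in% tx) && any(clades$WP %in% tx),
    TRUE)]
  expect_setequal(kept, brute)
})

test_that("the shipped synthetic chronogram fixture loads cleanly", {
  nwk <- system.file("extdata", "synthetic_timetree_30taxa.nwk",
                     package = "ecoconv")
  map <- system.file("extdata", "synthetic_species_map.tsv",
                     package = "ecoconv")
  tr <- read_time_tree(nwk)
  expect_equal(ape::Ntip(tr), 30)
  expect_true(is_ultrametric_tree(tr, tol = 1e-6))
  meta <- make_branch_metadata(tr, read_species_map(map))
  expect_equal(nrow(meta), 58)
  expect_setequal(unique(meta$ecomorph[!is.na(meta$ecomorph)]),
                  c("trawler", "gleaner", "aerial_hawker", "outgroup"))
  # clean bundle validates without findings
  expect_equal(nrow(validate_inputs(list(tree = tr,
                                         ecomorph_map = read_species_map(map)))), 0)
})
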