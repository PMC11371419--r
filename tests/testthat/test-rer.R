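make_rates <- function(lengths) rate_matrix(lengths)

test_that("master lengths are per-branch means with a coverage floor", {
  L <- rbind(g1 = c(b1 = 1, b2 = 4, b3 = NA),
             g2 = c(3, 6, 2),
             g3 = c(NA, 8, NA))
  colnames(L) <- c("b1", "b2", "b3")
  r <- compute_master_lengths(make_rates(L), min_genes = 2)
  expect_equal(r$master, c(b1 = 2, b2 = 6, b3 = NA))
  # recompute oracle on a larger random matrix
  set.seed(8)
  M <- matrix(rexp(100 * 12), 100, 12,
              dimnames = list(sprintf("g%d", 1:100), sprintf("b%d", 1:12)))
  M[runif(length(M)) < 0.3] <- NA
  r2 <- compute_master_lengths(make_rates(M), min_genes = 5)
  oracle <- apply(M, 2, mean, na.rm = TRUE)
  oracle[colSums(!is.na(M)) < 5] <- NA
  expect_equal(r2$master, oracle)
})

test_that("a gene proportional to the master has all-zero residuals", {
  st <- simulate_time_tree(sim_config(seed = 31, n_taxa = 12, n_outgroup = 3))
  bt <- branch_table(st$tree)
  n_b <- nrow(bt)
  L <- outer(seq(0.5, 3, length.out = 20), bt$length)
  dimnames(L) <- list(sprintf("g%02d", 1:20), bt$branch_id)
  rers <- compute_rers(compute_master_lengths(make_rates(L)),
                       transform = "sqrt", weighting = "none")
  expect_lt(max(abs(rers$rer), na.rm = TRUE), 1e-9)
  # and weighted pass keeps the exact fit
  rers_w <- compute_rers(compute_master_lengths(make_rates(L)))
  expect_lt(max(abs(rers_w$rer), na.rm = TRUE), 1e-9)
})

test_that("genes below the branch floor are skipped with a warning", {
  L <- matrix(c(1, 2, rep(NA, 4), rexp(18)), 4, 6, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("b", 1:6)))
  expect_warning(
    rers <- compute_rers(compute_master_lengths(make_rates(L), min_genes = 2),
                         min_n = 5, weighting = "none"),
    "skipped")
  expect_true("g1" %in% rers$skipped)
  expect_false("g1" %in% rers$genes)
})

test_that("unweighted residuals equal hand-computed OLS residuals", {
  master <- c(b1 = 1, b2 = 2, b3 = 4, b4 = 7, b5 = 10)
  y_raw <- c(0.9, 2.3, 3.6, 7.8, 11.1)
  L <- rbind(gX = y_raw, gY = master * 1.3, gZ = rev(y_raw))
  colnames(L) <- names(master)
  rm <- make_rates(rbind(L, matrix(rep(master, 5), 5, byrow = TRUE,
                                   dimnames = list(paste0("f", 1:5), names(master)))))
  rers <- compute_rers(compute_master_lengths(rm, min_genes = 2),
                       transform = "sqrt", weighting = "none", min_n = 3)
  x <- sqrt(colMeans(rm$lengths))
  res_oracle <- stats::resid(stats::lm(sqrt(y_raw) ~ x))
  expect_equal(unname(rers$rer["gX", ]),
               unname(res_oracle / sd(res_oracle)), tolerance = 1e-9)
})

test_that("kendall tau-b matches enumeration and flags degenerate input", {
  expect_equal(kendall_tau(1:3, 1:3)$tau, 1.0)
  expect_equal(kendall_tau(1:3, 3:1)$tau, -1.0)
  expect_error(kendall_tau(c(1, 1, 1), 1:3), "all values tied")
  set.seed(9)
  for (i in 1:100) {
    n <- sample(4:9, 1)
    x <- sample(1:4, n, replace = TRUE)   # heavy ties
    y <- sample(1:4, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y)$tau, kendall_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact kendall p agrees with cor.test on tie-free input", {
  set.seed(10)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    x <- sample(100, n); y <- sample(100, n)
    kt <- kendall_tau(x, y, method = "exact")
    ref <- stats::cor.test(x, y, method = "kendall", exact = TRUE)
    expect_equal(kt$tau, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(kt$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("trait association recovers sign and skips constant foreground", {
  st <- simulate_time_tree(sim_config(seed = 33, n_taxa = 12, n_outgroup = 3))
  bt <- branch_table(st$tree)
  fg <- foreground_branches(make_branch_metadata(st$tree, st$ecomorph_map),
                            "gleaner")
  set.seed(11)
  base <- matrix(rexp(40 * nrow(bt)), 40,
                 dimnames = list(sprintf("g%02d", 1:40), bt$branch_id))
  L <- sweep(base, 2, bt$length, "*")
  # accelerate the foreground branches of the first 10 genes only, so the
  # acceleration is relative to the master built from the other genes
  L[1:10, fg] <- L[1:10, fg] * 5
  rers <- compute_rers(compute_master_lengths(make_rates(L)), min_n = 5)
  assoc <- trait_association(rers, fg, alpha = 0.01)
  acc <- assoc$tau[assoc$gene %in% sprintf("g%02d", 1:10)]
  expect_gte(mean(acc > 0), 0.8)
  expect_gt(mean(acc), mean(assoc$tau[!assoc$gene %in% sprintf("g%02d", 1:10)]))
  # deterministic sign: residuals strictly larger on every foreground branch
  det <- structure(list(
    rer = matrix(c(3, 4, 5, -1, -2, 0, 1, -0.5, 2, 0.3), 1,
                 dimnames = list("gD", c(fg[1:3], paste0("bg", 1:7)))),
    genes = "gD", branches = c(fg[1:3], paste0("bg", 1:7)),
    skipped = character(0)), class = "rer_matrix")
  expect_gt(trait_association(det, fg)$tau, 0)
  # constant indicator: foreground ids absent from the matrix
  assoc_none <- trait_association(rers, "no_such_branch", alpha = 0.01)
  expect_equal(nrow(assoc_none), 0)
  expect_setequal(attr(assoc_none, "skipped"), rownames(L))
})

test_that("scaling one gene's lengths leaves its residual ranks unchanged", {
  st <- simulate_time_tree(sim_config(seed = 35, n_taxa = 12, n_outgroup = 3))
  bt <- branch_table(st$tree)
  set.seed(12)
  L <- sweep(matrix(rexp(40 * nrow(bt), 2), 40), 2, bt$length, "*")
  dimnames(L) <- list(sprintf("g%02d", 1:40), bt$branch_id)
  base <- compute_master_lengths(make_rates(L))
  r1 <- compute_rers(base, min_n = 5, weighting = "none")
  L2 <- L
  L2["g01", ] <- L2["g01", ] * 17  # positive scalar on one gene
  scaled <- make_rates(L2)
  scaled$master <- base$master  # same reference lengths
  r2 <- compute_rers(scaled, min_n = 5, weighting = "none")
  # sqrt transform + per-gene standardization absorb the scalar entirely
  expect_equal(r2$rer["g01", ], r1$rer["g01", ], tolerance = 1e-9)
  expect_equal(rank(r2$rer["g01", ]), rank(r1$rer["g01", ]))
})

test_that("the exact rank-sum null agrees with full enumeration when both apply", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(6:9, 1)
    m <- sample(2:(n - 2), 1)
    x <- sample(100, n)                     # tie-free
    y <- c(rep(1, m), rep(0, n - m))[sample(n)]
    p_enum <- kendall_tau(x, y, method = "exact")$p
    p_rank <- kendall_tau(x, y, method = "exact_binary")$p
    expect_equal(p_rank, p_enum, tolerance = 1e-12)
  }
  expect_error(kendall_tau(c(1, 1, 2, 2), c(1, 2, 3, 4),
                           method = "exact_binary"), NA)
})
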