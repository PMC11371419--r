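# Independent oracles used across the suite. Each is a from-scratch
# computation (direct formula, brute-force enumeration, or a reference
# routine from a different code path) kept deliberately separate from the
# package implementations it checks.

# Benjamini-Hochberg step-up: q(i) = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Kendall tau-b by O(n^2) pair enumeration with tie correction
kendall_oracle <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    S <- S + sign(x[i] - x[j]) * sign(y[i] - y[j])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  S / sqrt((n0 - n1) * (n0 - n2))
}

# closed-form simple-regression statistics from the normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 0
  f <- if (r2 < 1) r2 / (1 - r2) * (n - 2) else Inf
  list(slope = slope, intercept = intercept, r_squared = r2, f_stat = f,
       p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

# three-set Venn region counts by membership-bitmask enumeration
venn_oracle <- function(a, b, c) {
  u <- unique(c(a, b, c))
  code <- (u %in% a) + 2 * (u %in% b) + 4 * (u %in% c)
  cnt <- function(k) sum(code == k)
  c(a_only = cnt(1), b_only = cnt(2), c_only = cnt(4),
    ab = cnt(3), ac = cnt(5), bc = cnt(6), abc = cnt(7))
}

# one-sided Fisher exact p for the 2x2 enrichment table
fisher_oracle <- function(k, K, n, N) {
  tab <- matrix(c(k, n - k, K - k, N - K - n + k), 2)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

# small reusable fixtures -----------------------------------------------

toy_tree <- function(txt = "((A:1,B:1):2,C:3);")
  read_time_tree(txt, text = TRUE)

small_sim <- function(seed = 42, ...) {
  cfg <- sim_config(seed = seed, n_taxa = 12, n_outgroup = 3,
                    n_genes = 200, ...)
  list(cfg = cfg, st = simulate_time_tree(cfg))
}
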