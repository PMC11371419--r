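# Relative evolutionary rates (RER) and their binary-trait association.
#
# This is a deliberately simplified, self-contained reimplementation of the
# RER construction used in convergence scans: per-gene branch lengths are
# regressed (after a variance-stabilizing transform, optionally with
# inverse-variance weights estimated in master-length bins) on the
# genome-average "master" branch lengths, and the standardized residuals are
# correlated with a 0/1 foreground trait by Kendall's tau-b. Phylogenetic
# covariance of residuals beyond the master-tree regression is not modeled.

#' Construct a rate matrix object
#'
#' @param lengths Numeric matrix, genes x branches (substitutions/site),
#'   `NA` where a branch is absent from a gene's tree.
#' @return An object of class `rate_matrix`.
#' @export
rate_matrix <- function(lengths) {
  stopifnot(is.matrix(lengths), !is.null(rownames(lengths)),
            !is.null(colnames(lengths)))
  if (any(lengths < 0, na.rm = TRUE)) stop("negative branch lengths")
  structure(list(lengths = lengths, genes = rownames(lengths),
                 branches = colnames(lengths), master = NULL),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("rate_matrix: %d genes x %d branches (%.1f%% cells present)\n",
              length(x$genes), length(x$branches),
              100 * mean(!is.na(x$lengths))))
  invisible(x)
}

#' Master (average) branch lengths
#'
#' Per-branch mean branch length across the genes in which the branch is
#' present; branches represented in fewer than `min_genes` genes are
#' excluded (`NA` master) since their average would be too noisy to anchor
#' the rate regression.
#'
#' @param rates A `rate_matrix`.
#' @param min_genes Minimum number of genes per branch (default 5).
#' @return The `rate_matrix` with `master` filled in (named numeric, `NA`
#'   for excluded branches).
#' @export
compute_master_lengths <- function(rates, min_genes = 5) {
  stopifnot(inherits(rates, "rate_matrix"), min_genes >= 2)
  n <- colSums(!is.na(rates$lengths))
  m <- colMeans(rates$lengths, na.rm = TRUE)
  m[n < min_genes] <- NA_real_
  if (all(is.na(m))) stop("no branch is present in >= min_genes genes")
  rates$master <- m
  rates
}

# closed-form (weighted) simple-regression residuals
wls_residuals <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  b <- if (sxx > 0) sum(w * (x - xb) * (y - yb)) / sxx else 0
  y - (yb + b * (x - xb))
}

#' Relative evolutionary rates
#'
#' For each gene, residuals of a (weighted) least-squares regression of
#' transformed gene branch lengths on transformed master lengths,
#' standardized per gene to unit scale. With `weighting = "binned"` the
#' residual variance is estimated in `n_bins` master-length bins from a
#' first unweighted pass, and a second pass uses inverse fitted-variance
#' weights — a simple heteroscedasticity correction, since short branches
#' carry noisier length estimates.
#'
#' @param rates A `rate_matrix` (master lengths computed, or they will be
#'   with defaults).
#' @param transform `"sqrt"` (default) or `"log1p"`.
#' @param weighting `"binned"` (default) or `"none"`.
#' @param min_n Minimum branches present for a gene to be scored
#'   (default 10); genes below it are skipped with a warning.
#' @param n_bins Number of master-length bins for the variance model.
#' @return An object of class `rer_matrix`: list with matrix `rer`
#'   (skipped genes dropped; `NA` mirrors absent cells), `genes`,
#'   `branches`, and `skipped`.
#' @export
compute_rers <- function(rates, transform = c("sqrt", "log1p"),
                         weighting = c("binned", "none"),
                         min_n = 10, n_bins = 10) {
  transform <- match.arg(transform)
  weighting <- match.arg(weighting)
  stopifnot(inherits(rates, "rate_matrix"))
  if (is.null(rates$master)) rates <- compute_master_lengths(rates)
  tf <- switch(transform, sqrt = sqrt, log1p = log1p)
  usable <- !is.na(rates$master)
  L <- rates$lengths[, usable, drop = FALSE]
  mx <- tf(rates$master[usable])
  n_present <- rowSums(!is.na(L))
  skip <- n_present < min_n
  if (any(skip))
    warning(sum(skip), " gene(s) with fewer than ", min_n,
            " branches skipped")
  L <- L[!skip, , drop = FALSE]
  res <- matrix(NA_real_, nrow(L), ncol(L), dimnames = dimnames(L))
  for (g in seq_len(nrow(L))) {
    i <- which(!is.na(L[g, ]))
    res[g, i] <- wls_residuals(mx[i], tf(L[g, i]))
  }
  if (weighting == "binned") {
    br <- stats::quantile(mx, probs = seq(0, 1, length.out = n_bins + 1))
    bin <- cut(mx, breaks = unique(br), include.lowest = TRUE)
    v <- tapply(as.vector(res), bin[col(res)], stats::var, na.rm = TRUE)
    v[is.na(v) | v <= 0] <- stats::var(as.vector(res), na.rm = TRUE)
    w_branch <- 1 / v[as.integer(bin)]
    for (g in seq_len(nrow(L))) {
      i <- which(!is.na(L[g, ]))
      res[g, i] <- wls_residuals(mx[i], tf(L[g, i]), w_branch[i])
    }
  }
  for (g in seq_len(nrow(res))) {
    i <- which(!is.na(res[g, ]))
    s <- stats::sd(res[g, i])
    # an (almost) exact fit means no rate deviation anywhere: keep zeros
    # rather than amplifying float noise by a near-zero scale
    if (!is.finite(s) || s < 1e-9) res[g, i] <- 0
    else res[g, i] <- res[g, i] / s
  }
  structure(list(rer = res, genes = rownames(res), branches = colnames(res),
                 skipped = rownames(rates$lengths)[skip]),
            class = "rer_matrix")
}

#' @export
print.rer_matrix <- function(x, ...) {
  cat(sprintf("rer_matrix: %d genes x %d branches (%d skipped)\n",
              length(x$genes), length(x$branches), length(x$skipped)))
  invisible(x)
}

# all permutations of 1..n as an (n!) x n integer matrix
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1)
  k <- nrow(sub)
  out <- matrix(0L, n * k, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[((i - 1) * k + 1):(i * k), ] <- cbind(i, matrix(rest[sub], k))
  }
  out
}

kendall_S <- function(x, y) {
  sum(sign(outer(x, x, "-")) * sign(outer(y, y, "-"))) / 2
}

#' Kendall rank correlation (tau-b) with exact or approximate p
#'
#' Tie-corrected tau-b with a two-sided p-value. The `"auto"` policy picks
#' the sharpest valid null: for `n <= 9` the exact permutation null of the
#' concordance statistic S is enumerated over all n! orderings (correct
#' under ties); when one variable is binary and the other is tie-free
#' (the rate-vs-trait case), S is a linear map of the Mann-Whitney U
#' statistic, so its exact rank-sum null is used at any n
#' (`"exact_binary"`); otherwise a normal approximation with tie-corrected
#' variance and a continuity correction. The normal tail is noticeably
#' conservative at small foreground sizes, which is why the binary case
#' gets the exact null.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"auto"` (default), `"exact"`, `"exact_binary"`, or
#'   `"normal"`.
#' @return List with `tau`, `p`, `S`, `n`, and `method` used.
#' @export
kendall_tau <- function(x, y, method = c("auto", "exact", "exact_binary",
                                         "normal")) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  if (n1 == n0 || n2 == n0) stop("tau undefined: all values tied in x or y")
  S <- kendall_S(x, y)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  binary_ok <- (length(unique(y)) == 2 && n1 == 0) ||
    (length(unique(x)) == 2 && n2 == 0)
  if (method == "auto")
    method <- if (n <= 9) "exact" else if (binary_ok) "exact_binary"
              else "normal"
  if (method == "exact_binary") {
    if (!binary_ok) stop("exact_binary needs one binary and one tie-free variable")
    if (length(unique(y)) == 2) { grp <- y; val <- x } else { grp <- x; val <- y }
    hi <- grp == max(grp)
    m1 <- sum(hi); m0 <- sum(!hi)
    U <- sum(rank(val)[hi]) - m1 * (m1 + 1) / 2
    p <- min(1, 2 * min(stats::pwilcox(U, m1, m0),
                        stats::pwilcox(m1 * m0 - U, m1, m0)))
  } else if (method == "exact") {
    if (n > 9) stop("exact enumeration limited to n <= 9")
    P <- perm_matrix(n)
    Sall <- numeric(nrow(P))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      Sall <- Sall + sign(x[i] - x[j]) * sign(y[P[, i]] - y[P[, j]])
    }
    p <- mean(abs(Sall) >= abs(S) - 1e-9)
  } else {
    t1 <- sum(tx * (tx - 1) * (2 * tx + 5))
    t2 <- sum(ty * (ty - 1) * (2 * ty + 5))
    vS <- (n * (n - 1) * (2 * n + 5) - t1 - t2) / 18 +
      sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
        (9 * n * (n - 1) * (n - 2)) +
      sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    p <- if (S == 0 || vS <= 0) 1 else
      min(1, 2 * stats::pnorm(-(abs(S) - 1) / sqrt(vS)))
  }
  list(tau = tau, p = p, S = S, n = n, method = method)
}

#' Associate relative rates with a binary foreground trait
#'
#' Per gene, Kendall correlation between the gene's relative evolutionary
#' rates and a 0/1 indicator of foreground membership over the branches
#' present for that gene. The foreground is typically the set of terminal
#' branches of the species in one ecomorph (see
#' [foreground_branches()]). Genes whose present branches are all
#' foreground or all background cannot be scored and are skipped.
#'
#' @param rers A `rer_matrix`.
#' @param foreground Character vector of foreground branch ids.
#' @param alpha Significance threshold on the Kendall p (default 0.01).
#' @return Data frame: `gene`, `tau`, `p`, `n_branches`, `significant`;
#'   skipped genes are listed in attribute `"skipped"`.
#' @export
trait_association <- function(rers, foreground, alpha = 0.01) {
  stopifnot(inherits(rers, "rer_matrix"), length(foreground) > 0)
  fg <- as.numeric(rers$branches %in% foreground)
  rows <- vector("list", length(rers$genes))
  skipped <- character(0)
  for (g in seq_along(rers$genes)) {
    i <- which(!is.na(rers$rer[g, ]))
    f <- fg[i]
    if (length(unique(f)) < 2) {
      skipped <- c(skipped, rers$genes[g])
      next
    }
    kt <- kendall_tau(rers$rer[g, i], f)
    rows[[g]] <- data.frame(gene = rers$genes[g], tau = kt$tau, p = kt$p,
                            n_branches = length(i), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(gene = character(), tau = numeric(), p = numeric(),
                      n_branches = integer())
  out$significant <- out$p <= alpha
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Foreground branch ids for an ecomorph
#'
#' Terminal branches of the species assigned to one ecomorph — the binary
#' trait used in the rate-association scan is defined on extant species
#' with observable phenotypes.
#'
#' @param branch_info Branch metadata (see [make_branch_metadata()]).
#' @param ecomorph Ecomorph label.
#' @return Character vector of branch ids.
#' @export
foreground_branches <- function(branch_info, ecomorph) {
  ids <- branch_info$branch_id[branch_info$is_terminal &
                                 !is.na(branch_info$ecomorph) &
                                 branch_info$ecomorph == ecomorph]
  if (length(ids) == 0) stop("unknown or empty ecomorph: ", ecomorph)
  ids
}

#' Rate-matrix TSV interface
#'
#' Genes as rows; branch columns named by sorted clade tips joined with
#' `"|"`; empty cells for absent branches.
#'
#' @param rates A `rate_matrix`.
#' @param path File path.
#' @export
write_rate_matrix <- function(rates, path) {
  df <- data.frame(gene = rates$genes, rates$lengths, check.names = FALSE)
  write_tsv_schema(df, path)
}

#' @rdname write_rate_matrix
#' @export
read_rate_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  rate_matrix(m)
}
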