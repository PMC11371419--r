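# Shared small helpers: simple-regression summaries and schema-tagged TSV IO.

#' Ordinary least-squares fit of y on x with test statistics
#'
#' Simple linear regression via [stats::lm()], returned in the compact form
#' used throughout the reuse and bias analyses. Degenerate responses are
#' given a defined convention: if `y` has zero variance the fit is reported
#' with slope 0, `r_squared` 0, `f_stat` 0 and `p` 1.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A list of class `regression_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `f_stat`, `df` (numerator, denominator) and
#'   `p`, plus `n`.
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0) stop("zero variance in predictor")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  out <- list(slope = unname(co[2]), intercept = unname(co[1]),
              n = length(x), df = c(1L, length(x) - 2L))
  if (stats::var(y) == 0) {
    out$slope <- 0
    out$r_squared <- 0
    out$f_stat <- 0
    out$p <- 1
  } else {
    # summary.lm warns on exact fits; R^2 = 1 is a legitimate outcome here
    s <- suppressWarnings(summary(fit))
    out$r_squared <- unname(s$r.squared)
    out$f_stat <- unname(s$fstatistic[1])
    out$p <- unname(stats::pf(s$fstatistic[1], s$fstatistic[2],
                              s$fstatistic[3], lower.tail = FALSE))
  }
  class(out) <- "regression_fit"
  out
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): slope = %.4g, intercept = %.4g\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("  R^2 = %.4f, F(%d,%d) = %.4g, P = %.4g\n",
              x$r_squared, x$df[1], x$df[2], x$f_stat, x$p))
  invisible(x)
}

#' Write a data frame as TSV with a schema header comment
#'
#' Every pipeline output table starts with a `# schema:` comment naming its
#' columns so outputs are self-describing and machine-checkable.
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv_schema <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema: ", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_schema()]
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv_schema <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
}
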