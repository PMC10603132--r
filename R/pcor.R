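#' @include AllClasses.R
NULL

#' Linear partial correlation conditional-independence test
#'
#' The linear conditional-independence statistic of the two-stage causal
#' discovery: the Pearson correlation of the OLS residuals of `x` on the
#' conditioning set `Z` and of `y` on `Z` (intercepts included). With an
#' empty `Z` it reduces exactly to the plain Pearson correlation. The
#' p-value is from the two-sided t test
#' `t = rho * sqrt((n - |Z| - 2) / (1 - rho^2))` on `n - |Z| - 2` degrees of
#' freedom; `rho` is clipped to `[-1, 1]`.
#'
#' Rows with any missing value across `x`, `y`, `Z` are dropped (listwise
#' deletion). Collinear conditioners are dropped with a warning; a
#' zero-variance residual yields a degenerate result with `p = 1`.
#'
#' @param x,y numeric vectors of equal length.
#' @param Z optional numeric matrix (or vector) of conditioning series.
#' @return List of class `ciTest`: `rho`, `pvalue`, `n` (effective sample
#'   size), `nConds`, `degenerate`.
#' @examples
#' set.seed(1)
#' z <- rnorm(200); x <- z + rnorm(200); y <- z + rnorm(200)
#' partialCorrelation(x, y, z)$rho     # near 0 given z
#' partialCorrelation(x, y)$rho        # plain correlation, near 0.5
#' @export
partialCorrelation <- function(x, y, Z = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != length(x)) stop("Z must align with x and y")
  }
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(Z)) ok <- ok & rowSums(is.na(Z)) == 0L
  x <- x[ok]; y <- y[ok]
  Zm <- if (is.null(Z)) matrix(numeric(0), length(x), 0)
  else Z[ok, , drop = FALSE]
  if (ncol(Zm) > 0) {
    qz <- qr(scale(Zm, scale = FALSE))
    if (qz$rank < ncol(Zm)) {
      keep <- qz$pivot[seq_len(qz$rank)]
      warning(sprintf("dropping %d redundant conditioner(s)",
                      ncol(Zm) - qz$rank))
      Zm <- Zm[, keep, drop = FALSE]
    }
  }
  n <- length(x)
  if (n - ncol(Zm) - 2 < 10)
    stop("effective sample too small: need n - |Z| - 2 >= 10")
  res <- pcor_engine(x, y, Zm)
  if (ncol(Zm) == 0 && !res[5]) res[1] <- cor(x, y)  # reduce exactly
  structure(list(rho = res[1], pvalue = res[2], n = as.integer(res[3]),
                 nConds = as.integer(res[4]),
                 degenerate = res[5] > 0),
            class = "ciTest")
}

#' @export
print.ciTest <- function(x, ...) {
  cat(sprintf("partial correlation: rho=%+.4f, p=%.3g, n=%d, |Z|=%d%s\n",
              x$rho, x$pvalue, x$n, x$nConds,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# Fast internal test on a panel value matrix. conds is a data.frame with
# columns var (column index) and lag. Rows are aligned at
# t = (maxlag + 1) .. T; listwise deletion only when the panel has NAs.
.pcorIdx <- function(V, xvar, xlag, yvar, conds, hasNA, Tn) {
  L <- max(xlag, if (nrow(conds)) max(conds$lag) else 0L)
  rows <- (L + 1L):Tn
  xv <- V[rows - xlag, xvar]
  yv <- V[rows, yvar]
  Zm <- if (nrow(conds)) {
    vapply(seq_len(nrow(conds)),
           function(k) V[rows - conds$lag[k], conds$var[k]],
           numeric(length(rows)))
  } else matrix(numeric(0), length(rows), 0)
  if (hasNA) {
    ok <- !is.na(xv) & !is.na(yv)
    if (ncol(Zm)) ok <- ok & rowSums(is.na(Zm)) == 0L
    xv <- xv[ok]; yv <- yv[ok]
    Zm <- Zm[ok, , drop = FALSE]
  }
  if (length(xv) - ncol(Zm) - 2 < 10)
    return(c(NA_real_, NA_real_, length(xv), ncol(Zm), 1))
  pcor_engine(xv, yv, Zm)
}
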