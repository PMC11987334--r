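# Spearman rank correlation.

#' Spearman rank correlation with t or exact-permutation p-value
#'
#' The coefficient is the Pearson correlation of the average-ranked data
#' (so ties are handled by midranks).  The p-value uses the
#' t-approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n - 2}
#' degrees of freedom; for small samples (\eqn{n \le 8} by default) an
#' exact two-sided permutation p-value over all \eqn{n!} orderings is
#' computed instead.
#'
#' @param x,y Paired numeric vectors, \eqn{n \ge 3}.
#' @param exact Use the exact permutation null; default `NULL` means
#'   exact iff \eqn{n \le 8}.
#' @return An object of class `correlation_result`: list with `rho`, `p`,
#'   `n`, `method`.
#' @examples
#' spearman_corr(c(1, 2, 3), c(3, 1, 2))$rho  # -0.5
#' @export
spearman_corr <- function(x, y, exact = NULL) {
  if (length(x) != length(y))
    fs_stop("`x` and `y` must have equal length", "shape_error")
  n <- length(x)
  if (n < 3L) fs_stop("need at least 3 pairs", "invalid_argument")
  if (anyNA(x) || anyNA(y))
    fs_stop("missing values are not supported", "invalid_argument")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12)
    fs_stop("a variable has zero rank variance; correlation undefined",
            "undefined_correlation_error")
  rho <- stats::cor(rx, ry)
  if (is.null(exact)) exact <- n <= 8L
  if (exact) {
    perms <- permutations_of(n)
    sy <- ry
    rhos <- apply(perms, 1, function(p) stats::cor(rx, sy[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, p = p, n = n, method = method),
            class = "correlation_result")
}

# all permutations of 1..n as an (n!) x n matrix (n <= 8 in practice)
#' @keywords internal
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- setdiff(seq_len(n), k)
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p, x$n, x$method))
  invisible(x)
}
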