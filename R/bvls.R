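# Small exact solvers for the constrained least-squares subproblems of the
# alternating CHEMTAX scheme. Problems are tiny (<= number of groups or
# stations unknowns), so a dense quadratic program is both exact and fast.

#' Box-constrained least squares
#'
#' Minimizes ||A x - b||^2 subject to lower <= x <= upper, solved as a
#' strictly convex quadratic program (a tiny ridge is added if A'A is
#' numerically singular). Entries with `lower == upper` are fixed and
#' eliminated before the solve.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector length m.
#' @param lower,upper numeric vectors length n; `upper` may be `Inf`.
#' @return Numeric vector x of length n.
#' @keywords internal
bounded_ls <- function(A, b, lower, upper) {
  n <- ncol(A)
  stopifnot(length(lower) == n, length(upper) == n)
  if (any(lower > upper + 1e-15))
    stop("infeasible bounds in bounded_ls", call. = FALSE)
  x <- lower
  fixed <- (upper - lower) <= 1e-15
  free <- which(!fixed)
  if (!length(free)) return(x)
  bf <- b - A[, fixed, drop = FALSE] %*% lower[fixed]
  Af <- A[, free, drop = FALSE]
  D <- crossprod(Af)
  # ridge keeps the QP strictly convex when columns are collinear
  eps <- 1e-10 * max(diag(D), 1)
  diag(D) <- diag(D) + eps
  d <- crossprod(Af, bf)
  k <- length(free)
  Amat <- cbind(diag(k))
  bvec <- lower[free]
  ub <- upper[free]
  fin <- is.finite(ub)
  if (any(fin)) {
    Amat <- cbind(Amat, -diag(k)[, fin, drop = FALSE])
    bvec <- c(bvec, -ub[fin])
  }
  sol <- quadprog::solve.QP(D, d, Amat, bvec)
  xf <- sol$solution
  # clamp solver round-off back into the box
  xf <- pmin(pmax(xf, lower[free]), ub)
  x[free] <- xf
  x
}

#' Non-negative least squares
#'
#' @inheritParams bounded_ls
#' @return Numeric vector x >= 0.
#' @keywords internal
nnls_ls <- function(A, b) {
  bounded_ls(A, b, lower = rep(0, ncol(A)), upper = rep(Inf, ncol(A)))
}
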