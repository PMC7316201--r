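## Simplex geometry primitives: Euclidean projection onto the probability
## simplex and simplex-constrained least squares. These are the workhorses of
## both archetypal fitting and feature extraction.

#' Euclidean projection onto the probability simplex
#'
#' Returns the point of the probability simplex (non-negative entries summing
#' to one) closest in Euclidean distance to `v`, using the closed-form
#' threshold construction: sort, find the largest support size whose shifted
#' cumulative mean stays positive, subtract the threshold and clip at zero.
#' The construction is tie-free; equal entries receive equal weight.
#'
#' @param v Numeric vector with finite entries.
#' @return Numeric vector of the same length on the simplex.
#' @examples
#' project_to_simplex(c(0.2, 0.3, 0.5))  # already on the simplex
#' project_to_simplex(c(2, 0, 0))        # snaps to a vertex
#' @export
project_to_simplex <- function(v) {
  if (length(v) == 0L) fail_input("cannot project an empty vector")
  if (!is.numeric(v) || !all(is.finite(v))) {
    fail_input("projection input must be finite numeric")
  }
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

## Vectorised column-wise simplex projection (same construction per column),
## delegated to compiled code: this is the hot loop of the solver.
project_columns_simplex <- function(M) {
  if (nrow(M) == 1L) return(matrix(1, 1L, ncol(M)))
  .proj_simplex_cols(M)
}

#' Simplex-constrained least squares
#'
#' Minimises `||x - M y||^2` over `y` on the probability simplex by projected
#' gradient descent with the exact Lipschitz step `1 / (2 * sigma_max(M)^2)`,
#' which guarantees a monotonically non-increasing objective. This is the
#' per-sample simplex projection used both inside the archetypal solver and
#' when encoding new samples over a learned dictionary.
#'
#' @param M Numeric matrix, d x m (dictionary; columns are atoms).
#' @param x Numeric vector of length d.
#' @param tol Relative objective-decrease stopping tolerance.
#' @param max_iter Maximum projected-gradient iterations.
#' @return Numeric vector of length m on the simplex.
#' @examples
#' M <- cbind(c(1, 0), c(0, 1))
#' solve_simplex_lsq(M, c(0.3, 0.7))
#' @export
solve_simplex_lsq <- function(M, x, tol = 1e-8, max_iter = 500L) {
  M <- as.matrix(M)
  if (!is.numeric(x) || nrow(M) != length(x)) {
    fail_input("dimension mismatch: nrow(M) = ", nrow(M),
               " but length(x) = ", length(x))
  }
  if (tol <= 0) fail_input("tol must be positive")
  drop(simplex_encode(M, matrix(x, ncol = 1L), tol = tol, max_iter = max_iter))
}

## Matrix form of solve_simplex_lsq: encodes every column of X over the
## dictionary M at once. The problem is separable per column, so a joint
## scheme with step 1/L, L = 2 * sigma_max(M)^2, serves every column
## simultaneously. Uses monotone FISTA: accelerated, but the accepted
## iterate never increases the objective.
simplex_encode <- function(M, X, tol = 1e-8, max_iter = 500L, Y0 = NULL) {
  m <- ncol(M)
  if (nrow(M) != nrow(X)) {
    fail_input("dimension mismatch: dictionary has ", nrow(M),
               " rows but samples have ", nrow(X))
  }
  if (m == 1L) return(matrix(1, 1L, ncol(X)))
  MtM <- crossprod(M)
  MtX <- crossprod(M, X)
  smax <- svd(M, nu = 0L, nv = 0L)$d[1L]
  if (smax <= 0) return(matrix(1 / m, m, ncol(X)))
  step <- 1 / (2 * smax^2)
  cX <- sum(X^2)
  obj <- function(Y) cX - 2 * sum(MtX * Y) + sum(Y * (MtM %*% Y))
  Y <- Y0 %||% matrix(1 / m, m, ncol(X))
  f <- obj(Y)
  Z <- Y; tk <- 1
  for (it in seq_len(max_iter)) {
    Zc <- project_columns_simplex(Z - step * 2 * (MtM %*% Z - MtX))
    fc <- obj(Zc)
    if (fc <= f) {
      t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      Z <- Zc + ((tk - 1) / t_new) * (Zc - Y)
      done <- (f - fc) < tol * max(abs(f), .Machine$double.eps)
      Y <- Zc; f <- fc; tk <- t_new
      if (done) break
    } else {
      Z <- Y                     # overshoot: restart momentum at best point
      tk <- 1
    }
  }
  Y
}

## Validation helpers for the simplex invariants.
is_simplex_vector <- function(v, tol_neg = 1e-9, tol_sum = 1e-8) {
  all(v >= -tol_neg) && abs(sum(v) - 1) <= tol_sum
}

check_simplex_columns <- function(M, tol_neg = 1e-9, tol_sum = 1e-8) {
  all(M >= -tol_neg) && all(abs(colSums(M) - 1) <= tol_sum)
}
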