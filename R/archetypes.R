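## Single-layer archetypal analysis: X ~ X B A with the columns of B and A
## constrained to probability simplices, solved by block-coordinate descent.

#' Archetypal reconstruction objective
#'
#' The squared Frobenius norm `||X - X B A||_F^2` minimised by archetypal
#' analysis: samples are approximated by convex combinations (columns of `A`)
#' of archetypes that are themselves convex combinations (columns of `B`) of
#' the samples.
#'
#' @param X d x n data matrix (columns are samples).
#' @param B n x k matrix of archetype weights.
#' @param A k x n matrix of sample codes.
#' @return Non-negative scalar.
#' @export
aa_objective <- function(X, B, A) {
  X <- as.matrix(X); B <- as.matrix(B); A <- as.matrix(A)
  if (nrow(B) != ncol(X) || ncol(B) != nrow(A) || ncol(A) != ncol(X)) {
    fail_input("non-conformable shapes for ||X - XBA||: X ",
               nrow(X), "x", ncol(X), ", B ", nrow(B), "x", ncol(B),
               ", A ", nrow(A), "x", ncol(A))
  }
  sum((X - (X %*% B) %*% A)^2)
}

#' Initialise archetypes from data columns
#'
#' Builds an n x k matrix `B` whose columns are one-hot indicators of selected
#' data columns, so every initial archetype is an actual sample.
#' `furthest_sum` seeds the first column at random then greedily adds the
#' column maximising the summed Euclidean distance to all columns selected so
#' far, favouring hull-extremal starts; `random_columns` samples k distinct
#' columns. Both are deterministic given `seed`.
#'
#' @param X d x n data matrix.
#' @param k Number of archetypes, 1 <= k <= n.
#' @param method "furthest_sum" or "random_columns".
#' @param seed Integer seed.
#' @return n x k one-hot matrix B.
#' @export
init_archetypes <- function(X, k, method = c("furthest_sum", "random_columns"),
                            seed = 1L) {
  X <- as.matrix(X)
  method <- match.arg(method)
  n <- ncol(X)
  if (k < 1L || k > n) {
    fail_input("k must satisfy 1 <= k <= n (k = ", k, ", n = ", n, ")")
  }
  set.seed(seed)
  if (method == "random_columns") {
    idx <- sample.int(n, k)
  } else {
    idx <- sample.int(n, 1L)
    if (k > 1L) {
      cn <- colSums(X^2)
      grow <- function(idx, times) {
        for (j in seq_len(times)) {
          cross <- crossprod(X, X[, idx, drop = FALSE])    # n x |idx|
          d2 <- outer(cn, cn[idx], "+") - 2 * cross
          tot <- rowSums(sqrt(pmax(d2, 0)))
          tot[idx] <- -Inf
          idx <- c(idx, which.max(tot))
        }
        idx
      }
      idx <- grow(idx, k - 1L)
      # the seed column is usually interior: drop it and re-add greedily
      idx <- grow(idx[-1L], 1L)
    }
  }
  B <- matrix(0, n, k)
  B[cbind(idx, seq_len(k))] <- 1
  B
}

#' Fit single-layer archetypal analysis
#'
#' Solves `min ||X - X B A||_F^2` subject to simplex-constrained columns of
#' `B` and `A` by block-coordinate descent: holding `B` fixed, the code of
#' every sample is a simplex-constrained least-squares problem against the
#' dictionary `D = X B`; holding `A` fixed, `B` is updated by a projected
#' gradient step on the induced subproblem. Both updates use exact Lipschitz
#' step sizes so the objective trace is non-increasing by construction. The
#' outer loop stops when the relative objective decrease falls below `tol`.
#'
#' @param X d x n numeric data matrix (columns are samples), all finite.
#' @param k Number of archetypes, 1 <= k <= n.
#' @param tol Relative objective-decrease tolerance for the outer loop.
#' @param max_iter Maximum outer iterations.
#' @param init Initialisation method, see [init_archetypes()].
#' @param seed Integer seed (initialisation only; the descent is
#'   deterministic).
#' @param inner_iter Projected-gradient iterations per block update.
#' @param inner_tol Relative tolerance for the block updates.
#' @return An object of class `"aa_model"` with elements `B`, `A`, `D = X B`,
#'   `k`, `objective_trace`, `converged`, `n_iterations`, `rss`.
#' @examples
#' X <- cbind(c(0, 0), c(1, 0), c(0, 1))
#' fit <- fit_archetypes(X, k = 3, seed = 1)
#' fit$rss  # ~ 0: each point is its own archetype
#' @export
fit_archetypes <- function(X, k, tol = 1e-6, max_iter = 200L,
                           init = c("furthest_sum", "random_columns"),
                           seed = 1L, inner_iter = 25L, inner_tol = 1e-10) {
  X <- as.matrix(X)
  check_finite_matrix(X, "X")
  init <- match.arg(init)
  n <- ncol(X)
  d <- nrow(X)
  if (k < 1L || k > n) {
    fail_input("k must satisfy 1 <= k <= n (k = ", k, ", n = ", n, ")")
  }
  if (tol <= 0) fail_input("tol must be positive")
  if (max_iter < 1L) fail_input("max_iter must be >= 1")
  if (k > 1L && n > 1L && all(abs(X - X[, 1L]) < 1e-12)) {
    warning("all data columns are identical with k > 1: duplicate atoms expected",
            call. = FALSE)
  }

  B <- init_archetypes(X, k, init, seed)
  A <- matrix(1 / k, k, n)
  sX <- svd(X, nu = 0L, nv = 0L)$d[1L]

  trace <- aa_objective(X, B, A)
  f_prev <- trace[1L]
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    D <- X %*% B
    A <- simplex_encode(D, X, tol = inner_tol, max_iter = inner_iter, Y0 = A)
    B <- update_B(X, A, B, sX, inner_iter, inner_tol)
    f <- sum((X - (X %*% B) %*% A)^2)
    trace <- c(trace, f)
    if ((f_prev - f) < tol * max(f_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    f_prev <- f
  }

  structure(list(
    B = B, A = A, D = X %*% B, k = k, d = d, n = n,
    objective_trace = trace, converged = converged, n_iterations = iters,
    rss = trace[length(trace)], norm_X2 = sum(X^2),
    init = init, seed = seed, tol = tol, call = match.call()
  ), class = "aa_model")
}

## Update of B for fixed A on f(B) = ||X - X B A||_F^2 by monotone
## accelerated projected gradient (FISTA with restart on overshoot).
## Gradient 2 X'(X B A - X) A' is evaluated as O(n d k) products so the cost
## stays linear in the sample count; Lipschitz constant
## 2 smax(X)^2 smax(A)^2.
update_B <- function(X, A, B, sX, iters, tol) {
  sA <- svd(A, nu = 0L, nv = 0L)$d[1L]
  L <- 2 * sX^2 * sA^2
  if (L <= 0) return(B)
  step <- 1 / L
  At <- t(A)
  obj <- function(B) sum((X - (X %*% B) %*% A)^2)
  grad <- function(Z) 2 * crossprod(X, ((X %*% Z) %*% A - X) %*% At)
  f <- obj(B)
  Z <- B; tk <- 1
  for (i in seq_len(iters)) {
    Zc <- project_columns_simplex(Z - step * grad(Z))
    fc <- obj(Zc)
    if (fc <= f) {
      t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      Z <- Zc + ((tk - 1) / t_new) * (Zc - B)
      done <- (f - fc) < tol * max(abs(f), .Machine$double.eps)
      B <- Zc; f <- fc; tk <- t_new
      if (done) break
    } else {
      Z <- B
      tk <- 1
    }
  }
  B
}

#' @export
print.aa_model <- function(x, ...) {
  cat("Archetypal analysis fit\n")
  cat(sprintf("  data: %d dims x %d samples, k = %d archetypes\n",
              x$d, x$n, x$k))
  cat(sprintf("  iterations: %d (%s), RSS = %.6g, relative error = %.4g\n",
              x$n_iterations, if (x$converged) "converged" else "max_iter",
              x$rss, sqrt(x$rss / max(x$norm_X2, .Machine$double.eps))))
  invisible(x)
}

#' @export
coef.aa_model <- function(object, ...) object$A

#' @export
fitted.aa_model <- function(object, ...) object$D %*% object$A

#' @export
residuals.aa_model <- function(object, X, ...) {
  if (missing(X)) fail_input("residuals.aa_model needs the data matrix X")
  as.matrix(X) - fitted(object)
}

#' Encode new samples over a fitted archetypal dictionary
#'
#' @param object An `"aa_model"`.
#' @param newdata d x m matrix of samples (columns).
#' @param ... Passed to the simplex solver (`tol`, `max_iter`).
#' @return k x m matrix of simplex codes.
#' @export
predict.aa_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) != object$d) {
    fail_input("newdata has ", nrow(newdata), " rows; model expects ", object$d)
  }
  simplex_encode(object$D, newdata, ...)
}

#' Simulate samples from a fitted archetypal model
#'
#' Draws simplex weights from a flat Dirichlet over the k archetypes and
#' returns the corresponding convex combinations of the dictionary atoms.
#'
#' @param object An `"aa_model"`.
#' @param nsim Number of samples.
#' @param seed Integer seed.
#' @param alpha Dirichlet concentration (scalar or length-k).
#' @param ... Unused.
#' @return d x nsim matrix.
#' @export
simulate.aa_model <- function(object, nsim = 1, seed = 1L, alpha = 1, ...) {
  set.seed(seed)
  W <- matrix(stats::rgamma(object$k * nsim, shape = alpha), object$k, nsim)
  W <- sweep(W, 2L, colSums(W), "/")
  object$D %*% W
}
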