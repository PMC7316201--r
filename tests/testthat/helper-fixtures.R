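# Shared fixtures and independent oracles, all generated in code.

# Enumerate the probability simplex of dimension m on a grid of step 1/N.
# Returns an m x P matrix of grid points. Used as a brute-force oracle for
# simplex-constrained least squares.
simplex_grid <- function(m, N) {
  if (m == 1L) return(matrix(1, 1L, 1L))
  if (m == 2L) {
    i <- 0:N
    return(rbind(i, N - i) / N)
  }
  if (m == 3L) {
    ij <- expand.grid(i = 0:N, j = 0:N)
    ij <- ij[ij$i + ij$j <= N, ]
    return(rbind(ij$i, ij$j, N - ij$i - ij$j) / N)
  }
  stop("simplex_grid implemented for m <= 3")
}

# Brute-force minimum of ||x - M y||^2 over the simplex grid.
grid_min_objective <- function(M, x, N) {
  G <- simplex_grid(ncol(M), N)
  R <- M %*% G - x
  min(colSums(R^2))
}

# Triangle data: n points with Dirichlet(1,1,1) weights over fixed vertices.
triangle_data <- function(n, seed = 1, include_vertices = FALSE) {
  V <- cbind(c(0, 0), c(1, 0), c(0, 1))
  set.seed(seed)
  W <- matrix(rgamma(3 * n, 1), 3, n)
  W <- sweep(W, 2, colSums(W), "/")
  if (include_vertices) W <- cbind(diag(3), W[, seq_len(n - 3)])
  list(X = V %*% W, V = V, W = W)
}

# Pairwise Mann-Whitney AUC oracle (ties counted one half).
auc_pairwise <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Stub ensemble whose members output fixed probabilities regardless of
# input: zero weights push everything through the output bias.
stub_ensemble <- function(probs, n_features = 2L) {
  members <- lapply(probs, function(p) {
    list(W1 = matrix(0, n_features, 2L), b1 = rep(0, 2L),
         W2 = matrix(0, 2L, 1L), b2 = qlogis(p),
         mu = rep(0, n_features), sd = rep(1, n_features),
         hidden = 2L, p = n_features)
  })
  structure(list(partition = list(seq_along(probs)), members = members,
                 base_spec = base_spec(hidden = 2L), seed = 1L,
                 n_features = n_features),
            class = "bagging_model")
}

# Small cohort with a linear class signal, for classifier tests.
blob_cohort <- function(n = 200, p = 2, shift = 3, prop_pos = 0.5, seed = 1) {
  set.seed(seed)
  n_pos <- round(n * prop_pos)
  y <- c(rep(0L, n - n_pos), rep(1L, n_pos))
  X <- matrix(rnorm(n * p), n, p) + shift * y
  vf_cohort(t(X), y, subject_ids = as.character(seq_len(n)))
}

# A fast base-network spec for tests that exercise plumbing, not learning.
fast_spec <- function() base_spec(hidden = 16L, epochs = 30L)
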