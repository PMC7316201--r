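## Deep (layered) archetypal analysis: repeated archetypal factorization of
## the previous layer's code matrix, composition of per-layer dictionaries,
## correlation-based atom pruning, and convex feature extraction.

#' Fit a deep archetypal analysis model
#'
#' Layer 1 is an archetypal fit of `X`; each subsequent layer `l` is an
#' archetypal fit of the code matrix `A` of layer `l - 1`. The deep
#' dictionary at layer `i` is the composed product `D_1 D_2 ... D_i`, whose
#' columns remain convex combinations of the original data columns (a convex
#' combination of convex combinations is itself convex). With `L = 1` the
#' model reduces exactly to plain archetypal analysis.
#'
#' @param X d x n data matrix (columns are samples).
#' @param k Atom count, either a scalar used at every layer or a vector of
#'   length `L`.
#' @param L Number of layers, >= 1.
#' @param tol,max_iter,init,inner_iter Passed to [fit_archetypes()] at every
#'   layer.
#' @param seed Integer seed; per-layer seeds are derived from it.
#' @return An object of class `"daa_model"` with elements `layers` (list of
#'   `"aa_model"`), `L`, `k_per_layer`, and `composite_dictionaries` (list of
#'   d x k_i matrices).
#' @examples
#' X <- matrix(runif(40), 2, 20)
#' m <- fit_daa(X, k = 3, L = 2, seed = 1)
#' dim(compose_dictionary(m, 2))
#' @export
fit_daa <- function(X, k, L = 1L, tol = 1e-6, max_iter = 200L,
                    init = c("furthest_sum", "random_columns"),
                    seed = 1L, inner_iter = 25L) {
  X <- as.matrix(X)
  check_finite_matrix(X, "X")
  init <- match.arg(init)
  L <- as.integer(L)
  if (L < 1L) fail_input("L must be >= 1")
  k_per_layer <- if (length(k) == 1L) rep(as.integer(k), L) else as.integer(k)
  if (length(k_per_layer) != L) {
    fail_input("k must be a scalar or a vector of length L")
  }
  n <- ncol(X)
  layers <- vector("list", L)
  input <- X
  for (l in seq_len(L)) {
    if (k_per_layer[l] > ncol(input)) {
      fail_input("layer ", l, ": k = ", k_per_layer[l],
                 " exceeds the ", ncol(input), " input columns of that layer")
    }
    layers[[l]] <- fit_archetypes(input, k_per_layer[l], tol = tol,
                                  max_iter = max_iter, init = init,
                                  seed = derive_seed(seed, l),
                                  inner_iter = inner_iter)
    input <- layers[[l]]$A
  }
  composite <- vector("list", L)
  composite[[1L]] <- layers[[1L]]$D
  if (L > 1L) {
    for (i in 2L:L) composite[[i]] <- composite[[i - 1L]] %*% layers[[i]]$D
  }
  structure(list(
    layers = layers, L = L, k_per_layer = k_per_layer,
    composite_dictionaries = composite,
    d = nrow(X), n = n, seed = seed, call = match.call()
  ), class = "daa_model")
}

#' Composed deep dictionary at a given layer
#'
#' Returns `D_1 D_2 ... D_layer`, the d x k_layer dictionary whose atoms are
#' the deep archetypes of that layer expressed in the original measurement
#' space.
#'
#' @param model A `"daa_model"`.
#' @param layer Layer index in `1:L`.
#' @return d x k_layer numeric matrix.
#' @export
compose_dictionary <- function(model, layer) {
  if (!inherits(model, "daa_model")) fail_input("model must be a daa_model")
  if (length(layer) != 1L || layer < 1L || layer > model$L) {
    fail_input("layer must lie in 1..", model$L)
  }
  model$composite_dictionaries[[layer]]
}

## Weights of the deep atoms over the original data columns: the composed
## product B1 (A1 B2) ... (A_{i-1} B_i), an n x k_i matrix with simplex
## columns. Used to assert convex-hull membership of deep atoms.
data_weights <- function(model, layer = model$L) {
  W <- model$layers[[1L]]$B
  if (layer > 1L) {
    for (l in 2L:layer) {
      W <- W %*% (model$layers[[l - 1L]]$A %*% model$layers[[l]]$B)
    }
  }
  W
}

#' Prune mutually correlated dictionary atoms
#'
#' Greedy scan in descending order of atom usage: an atom is retained iff its
#' absolute Pearson correlation with every already-retained atom is below
#' `threshold`. Correlation with a zero-variance atom is taken as 0 (such an
#' atom is retained unless it duplicates a retained atom exactly). At least
#' one atom is always retained; the scan is deterministic (ties in usage are
#' broken by atom index).
#'
#' @param D d x k dictionary matrix.
#' @param usage Non-negative length-k vector of total coefficient mass per
#'   atom (e.g. row sums of the layer's code matrix).
#' @param threshold Absolute-correlation threshold in (0, 1].
#' @return Increasing integer vector of retained atom indices.
#' @export
prune_correlated_atoms <- function(D, usage, threshold = 0.9) {
  D <- as.matrix(D)
  k <- ncol(D)
  if (k < 1L) fail_input("D must have at least one atom")
  if (length(usage) != k || any(usage < 0)) {
    fail_input("usage must be a non-negative vector of length ncol(D)")
  }
  if (threshold <= 0 || threshold > 1) fail_input("threshold must lie in (0, 1]")
  sds <- apply(D, 2L, stats::sd)
  if (any(sds == 0)) vf_log("warn", "%d zero-variance atom(s) in pruning", sum(sds == 0))
  ord <- order(-usage, seq_len(k))
  retained <- integer(0)
  for (j in ord) {
    ok <- TRUE
    for (r in retained) {
      cc <- if (sds[j] == 0 || sds[r] == 0) {
        if (max(abs(D[, j] - D[, r])) == 0) 1 else 0
      } else {
        abs(stats::cor(D[, j], D[, r]))
      }
      if (cc >= threshold) { ok <- FALSE; break }
    }
    if (ok) retained <- c(retained, j)
  }
  sort(retained)
}

#' Convex feature extraction over a deep dictionary
#'
#' Projects each new sample onto the simplex spanned by the (optionally
#' pruned) composed dictionary of the requested layer, i.e. solves a
#' simplex-constrained least-squares problem per sample. No label
#' information is consulted: the representation is fully unsupervised.
#'
#' @param model A `"daa_model"`.
#' @param X_new d x m matrix of samples (columns).
#' @param layer Layer whose composed dictionary is used (default: deepest).
#' @param retained Optional integer vector of atom indices to keep (e.g. from
#'   [prune_correlated_atoms()]); default all atoms.
#' @param tol,max_iter Simplex solver settings.
#' @return An object of class `"daa_features"`: list with `representation`
#'   (k x m matrix of simplex codes), `source_layer`, `atom_ids`.
#' @export
extract_features <- function(model, X_new, layer = model$L, retained = NULL,
                             tol = 1e-8, max_iter = 500L) {
  if (!inherits(model, "daa_model")) fail_input("model must be a daa_model")
  X_new <- as.matrix(X_new)
  if (nrow(X_new) != model$d) {
    fail_input("X_new has ", nrow(X_new), " rows; model expects ", model$d)
  }
  D <- compose_dictionary(model, layer)
  atom_ids <- retained %||% seq_len(ncol(D))
  if (length(atom_ids) == 0L) fail_input("retained atom set is empty")
  if (any(atom_ids < 1L) || any(atom_ids > ncol(D))) {
    fail_input("retained indices out of range 1..", ncol(D))
  }
  codes <- simplex_encode(D[, atom_ids, drop = FALSE], X_new,
                          tol = tol, max_iter = max_iter)
  rownames(codes) <- paste0("atom", atom_ids)
  structure(list(representation = codes, source_layer = layer,
                 atom_ids = atom_ids),
            class = "daa_features")
}

#' @export
print.daa_features <- function(x, ...) {
  cat(sprintf("Convex codes: %d atoms x %d samples (layer %d)\n",
              nrow(x$representation), ncol(x$representation), x$source_layer))
  invisible(x)
}

#' Encode new samples with a deep archetypal model
#'
#' Convenience wrapper around [extract_features()] returning the code matrix.
#'
#' @param object A `"daa_model"`.
#' @param newdata d x m matrix.
#' @param layer,retained,... Passed to [extract_features()].
#' @return k x m matrix of simplex codes.
#' @export
predict.daa_model <- function(object, newdata, layer = object$L,
                              retained = NULL, ...) {
  extract_features(object, newdata, layer = layer, retained = retained,
                   ...)$representation
}

#' @export
print.daa_model <- function(x, ...) {
  cat("Deep archetypal analysis fit\n")
  cat(sprintf("  data: %d dims x %d samples, %d layer(s), k = %s\n",
              x$d, x$n, x$L, paste(x$k_per_layer, collapse = "/")))
  rel <- vapply(seq_len(x$L), function(i) {
    sqrt(x$layers[[i]]$rss / max(x$layers[[i]]$norm_X2, .Machine$double.eps))
  }, numeric(1))
  cat(sprintf("  per-layer relative error: %s\n",
              paste(sprintf("%.3g", rel), collapse = ", ")))
  invisible(x)
}

#' @export
summary.daa_model <- function(object, ...) {
  tab <- data.frame(
    layer = seq_len(object$L),
    k = object$k_per_layer,
    iterations = vapply(object$layers, function(l) l$n_iterations, integer(1)),
    converged = vapply(object$layers, function(l) l$converged, logical(1)),
    rss = vapply(object$layers, function(l) l$rss, numeric(1))
  )
  structure(list(table = tab, d = object$d, n = object$n),
            class = "summary.daa_model")
}

#' @export
print.summary.daa_model <- function(x, ...) {
  cat(sprintf("Deep archetypal fit on %d x %d data\n", x$d, x$n))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.daa_model <- function(object, ...) object$layers[[object$L]]$A

#' Plot deep archetype atoms
#'
#' Draws the atoms of the composed dictionary of a layer as profiles over the
#' measurement dimensions.
#'
#' @param x A `"daa_model"`.
#' @param layer Layer index.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.daa_model <- function(x, layer = x$L, ...) {
  D <- compose_dictionary(x, layer)
  graphics::matplot(D, type = "l", lty = 1,
                    xlab = "measurement location",
                    ylab = "sensitivity (dB)",
                    main = sprintf("Deep archetypes, layer %d", layer), ...)
  invisible(x)
}
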