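## Class-balanced bagging: the majority (negative) class is split into
## non-overlapping subsets roughly the size of the minority class; one small
## feed-forward network is trained per subset on all minority samples plus
## that subset; prediction combines members by majority vote.

#' Labelled cohort container
#'
#' Bundles a feature matrix (columns = samples) with the per-sample binary
#' outcome, subject identifier and eye identifier. The subject is the unit of
#' cross-validation grouping.
#'
#' @param features d x m numeric matrix, columns are samples.
#' @param labels Binary vector (1 = develops disease) of length m.
#' @param subject_ids,eye_ids Character/integer vectors of length m.
#' @return An object of class `"vf_cohort"`.
#' @export
vf_cohort <- function(features, labels, subject_ids, eye_ids = NULL) {
  features <- as.matrix(features)
  m <- ncol(features)
  labels <- as.integer(labels)
  eye_ids <- eye_ids %||% as.character(seq_len(m))
  if (length(labels) != m || length(subject_ids) != m || length(eye_ids) != m) {
    fail_input("labels, subject_ids and eye_ids must all have length ncol(features)")
  }
  if (!all(labels %in% c(0L, 1L))) fail_input("labels must be 0/1")
  structure(list(features = features, labels = labels,
                 subject_ids = as.character(subject_ids),
                 eye_ids = as.character(eye_ids)),
            class = "vf_cohort")
}

#' @export
print.vf_cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d samples x %d measurements, %d subjects, %d positive samples\n",
              ncol(x$features), nrow(x$features),
              length(unique(x$subject_ids)), sum(x$labels)))
  invisible(x)
}

#' Partition the negative class into balanced subsets
#'
#' Shuffles the indices of the negative (label 0) class under `seed` and
#' splits them into `n_subsets` contiguous blocks whose sizes differ by at
#' most one, so that no sample is discarded. With `n_subsets = "auto"` the
#' count is `max(1, round(n_neg / n_pos))`; at the study's 5,820:724 class
#' sizes this yields 8 subsets.
#'
#' @param labels Binary vector.
#' @param n_subsets Integer or "auto".
#' @param seed Integer seed.
#' @return List of disjoint integer index vectors whose union is all
#'   negative-class indices.
#' @export
partition_negatives <- function(labels, n_subsets = "auto", seed = 1L) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  neg_idx <- which(labels == 0L)
  n_neg <- length(neg_idx)
  if (n_pos < 1L || n_neg < 1L) fail_input("both classes must be present")
  if (identical(n_subsets, "auto")) {
    n_subsets <- max(1L, as.integer(round(n_neg / n_pos)))
  }
  n_subsets <- as.integer(n_subsets)
  if (n_subsets > n_neg) {
    fail_input("n_subsets = ", n_subsets, " exceeds the ", n_neg,
               " negative samples")
  }
  set.seed(seed)
  shuffled <- neg_idx[sample.int(n_neg)]
  sizes <- rep(n_neg %/% n_subsets, n_subsets)
  extra <- n_neg %% n_subsets
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  unname(split(shuffled, rep(seq_len(n_subsets), times = sizes)))
}

## ---- base learner: single-hidden-layer network trained with Adam ---------

## Inputs are z-scored with training-set statistics; hidden layer uses
## rectified-linear activation, output is logistic, loss is cross-entropy.
mlp_fit <- function(X, y, hidden = 200L, lr = 1e-4, epochs = 200L,
                    batch = 32L, seed = 1L) {
  X <- as.matrix(X)                      # samples x features
  n <- nrow(X); p <- ncol(X)
  if (length(unique(y)) < 2L) fail_input("single-class training set")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")

  set.seed(seed)
  W1 <- matrix(stats::rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1L)
  b2 <- 0

  adam <- function() list(m = 0, v = 0)
  st <- list(W1 = adam(), b1 = adam(), W2 = adam(), b2 = adam())
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L

  upd <- function(s, g) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    s
  }
  apply_upd <- function(par, s) {
    mhat <- s$m / (1 - beta1^t_step)
    vhat <- s$v / (1 - beta2^t_step)
    par - lr * mhat / (sqrt(vhat) + eps)
  }

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch)) {
      ib <- ord[start:min(start + batch - 1L, n)]
      Xb <- Xs[ib, , drop = FALSE]
      yb <- y[ib]
      nb <- length(ib)
      Z1 <- sweep(Xb %*% W1, 2L, b1, "+")
      H <- pmax(Z1, 0)
      logit <- drop(H %*% W2) + b2
      pr <- 1 / (1 + exp(-logit))
      dl <- (pr - yb) / nb
      gW2 <- crossprod(H, dl)
      gb2 <- sum(dl)
      dH <- tcrossprod(dl, W2) * (Z1 > 0)
      gW1 <- crossprod(Xb, dH)
      gb1 <- colSums(dH)
      t_step <- t_step + 1L
      st$W1 <- upd(st$W1, gW1); st$b1 <- upd(st$b1, gb1)
      st$W2 <- upd(st$W2, gW2); st$b2 <- upd(st$b2, gb2)
      W1 <- apply_upd(W1, st$W1); b1 <- apply_upd(b1, st$b1)
      W2 <- apply_upd(W2, st$W2); b2 <- apply_upd(b2, st$b2)
    }
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, mu = mu, sd = sdv,
       hidden = hidden, p = p)
}

mlp_prob <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != net$p) {
    fail_input("feature dimension ", ncol(X), " does not match the ",
               net$p, " the network was trained on")
  }
  Xs <- sweep(sweep(X, 2L, net$mu, "-"), 2L, net$sd, "/")
  H <- pmax(sweep(Xs %*% net$W1, 2L, net$b1, "+"), 0)
  drop(1 / (1 + exp(-(H %*% net$W2 + net$b2))))
}

#' Default base-network specification
#'
#' Single hidden layer of 200 rectified-linear units, logistic output with
#' cross-entropy loss, Adam optimiser at a fixed step size of 0.0001,
#' 200 epochs, mini-batches of 32.
#'
#' @param hidden,lr,epochs,batch Override any default.
#' @return Named list.
#' @export
base_spec <- function(hidden = 200L, lr = 1e-4, epochs = 200L, batch = 32L) {
  list(hidden = as.integer(hidden), lr = lr,
       epochs = as.integer(epochs), batch = as.integer(batch))
}

#' Train a class-balanced bagging ensemble
#'
#' Partitions the negative class via [partition_negatives()] and trains one
#' base network per subset on all positive samples plus that subset, so every
#' member sees an approximately balanced training set while no negative
#' sample is discarded. Deterministic given `seed`.
#'
#' @param cohort A [vf_cohort()] (features d x m, columns = samples).
#' @param spec Base-network settings, see [base_spec()].
#' @param n_subsets Integer or "auto" (`round(n_neg / n_pos)`).
#' @param seed Integer seed.
#' @return An object of class `"bagging_model"` with elements `partition`,
#'   `members`, `base_spec`, `seed`, `n_features`.
#' @export
train_ensemble <- function(cohort, spec = base_spec(), n_subsets = "auto",
                           seed = 1L) {
  if (!inherits(cohort, "vf_cohort")) fail_input("cohort must be a vf_cohort")
  check_finite_matrix(cohort$features, "features")
  labels <- cohort$labels
  if (length(unique(labels)) < 2L) fail_input("both classes must be present")
  partition <- partition_negatives(labels, n_subsets, seed = seed)
  pos_idx <- which(labels == 1L)
  Xall <- t(cohort$features)             # samples x features
  members <- vector("list", length(partition))
  for (i in seq_along(partition)) {
    idx <- c(pos_idx, partition[[i]])
    members[[i]] <- mlp_fit(Xall[idx, , drop = FALSE], labels[idx],
                            hidden = spec$hidden, lr = spec$lr,
                            epochs = spec$epochs, batch = spec$batch,
                            seed = derive_seed(seed, i))
  }
  structure(list(partition = partition, members = members, base_spec = spec,
                 seed = seed, n_features = nrow(cohort$features)),
            class = "bagging_model")
}

#' @export
print.bagging_model <- function(x, ...) {
  cat(sprintf("Class-balanced bagging: %d members, %d input features\n",
              length(x$members), x$n_features))
  cat(sprintf("  base network: %d hidden units, Adam step %g, %d epochs, batch %d\n",
              x$base_spec$hidden, x$base_spec$lr, x$base_spec$epochs,
              x$base_spec$batch))
  invisible(x)
}

## members x samples matrix of positive-class probabilities
member_probs <- function(model, features) {
  features <- as.matrix(features)
  if (nrow(features) != model$n_features) {
    fail_input("feature dimension ", nrow(features),
               " does not match the ", model$n_features, " used in training")
  }
  Xt <- t(features)
  do.call(rbind, lapply(model$members, function(net) mlp_prob(net, Xt)))
}

#' Predict with a class-balanced bagging ensemble
#'
#' @param object A `"bagging_model"`.
#' @param newdata d x m feature matrix (columns = samples).
#' @param type "prob" for the mean member probability, "vote" for the
#'   fraction of members voting positive, "label" for the majority-vote
#'   label (an exact tie resolves to positive).
#' @param ... Unused.
#' @return Numeric (prob/vote) or integer (label) vector of length m.
#' @export
predict.bagging_model <- function(object, newdata,
                                  type = c("prob", "vote", "label"), ...) {
  type <- match.arg(type)
  P <- member_probs(object, newdata)
  switch(type,
         prob = colMeans(P),
         vote = colMeans(P >= 0.5),
         label = as.integer(colMeans(P >= 0.5) >= 0.5))
}

#' Majority-vote predictions
#'
#' Each member casts a hard vote (positive iff its probability is >= 0.5);
#' the returned label is positive iff at least half the members vote
#' positive (an exact tie resolves to positive, favouring sensitivity).
#'
#' @param model A `"bagging_model"`.
#' @param features d x m feature matrix.
#' @return List with `vote_fraction` and `label`.
#' @export
predict_votes <- function(model, features) {
  P <- member_probs(model, features)
  frac <- colMeans(P >= 0.5)
  list(vote_fraction = frac, label = as.integer(frac >= 0.5))
}

#' Continuous ensemble scores
#'
#' The mean of the member positive-class probabilities, a smoother score
#' than the vote fraction and the default input to ROC analysis. Note that
#' thresholding this score at 0.5 need not reproduce the majority-vote
#' labels of [predict_votes()].
#'
#' @param model A `"bagging_model"`.
#' @param features d x m feature matrix.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(model, features) {
  colMeans(member_probs(model, features))
}
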