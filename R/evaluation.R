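## Subject-grouped stratified cross-validation, ROC/AUC, and the experiment
## runner comparing raw features vs single-layer vs deep archetypal codes.

#' Subject-grouped stratified fold assignment
#'
#' Assigns every subject (not sample) to exactly one of `n_folds` folds:
#' within each label stratum (a subject is positive if any of its samples is
#' positive) subjects are shuffled under `seed` and dealt round-robin, so
#' per-fold positive-subject counts differ from perfect stratification by at
#' most one and no subject can appear in two folds.
#'
#' @param subject_ids Per-sample subject identifiers.
#' @param labels Per-sample binary labels.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return An object of class `"fold_assignment"`: list with `n_folds` and
#'   `fold_of_subject` (named integer vector).
#' @export
make_folds <- function(subject_ids, labels, n_folds = 10L, seed = 1L) {
  subject_ids <- as.character(subject_ids)
  labels <- as.integer(labels)
  if (length(subject_ids) != length(labels)) {
    fail_input("subject_ids and labels must have equal length")
  }
  subj <- unique(subject_ids)
  subj_lab <- vapply(split(labels, factor(subject_ids, levels = subj)),
                     max, integer(1))
  if (n_folds > length(subj)) {
    fail_input("n_folds = ", n_folds, " exceeds the ", length(subj), " subjects")
  }
  set.seed(seed)
  fold <- integer(length(subj))
  assigned <- 0L
  for (lab in c(1L, 0L)) {
    ids <- which(subj_lab == lab)
    if (length(ids) == 0L) next
    ids <- ids[sample.int(length(ids))]
    # continue the rotation across strata so overall fold sizes stay even
    fold[ids] <- ((assigned + seq_along(ids) - 1L) %% n_folds) + 1L
    assigned <- assigned + length(ids)
  }
  structure(list(n_folds = as.integer(n_folds),
                 fold_of_subject = stats::setNames(fold, subj)),
            class = "fold_assignment")
}

#' Fold index of each sample
#'
#' @param folds A `"fold_assignment"`.
#' @param subject_ids Per-sample subject identifiers.
#' @return Integer vector of fold indices per sample.
#' @export
fold_of_samples <- function(folds, subject_ids) {
  f <- folds$fold_of_subject[as.character(subject_ids)]
  if (anyNA(f)) fail_input("subject_ids contain subjects absent from the fold assignment")
  unname(f)
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("Fold assignment: %d subjects in %d folds\n",
              length(x$fold_of_subject), x$n_folds))
  print(table(fold = x$fold_of_subject))
  invisible(x)
}

#' Receiver operating characteristic curve and AUC
#'
#' Builds the ROC curve from the sorted unique score thresholds; the AUC is
#' the trapezoidal area of the stored curve, which equals the normalised
#' Mann-Whitney U statistic (probability that a random positive outscores a
#' random negative, ties counted one half).
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels; both classes must be present.
#' @return An object of class `"roc_curve"`: `thresholds`, `fpr`, `tpr`
#'   (each starting at the (0,0) corner), `auc`, `n_pos`, `n_neg`.
#' @examples
#' compute_roc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
#' @export
compute_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    fail_input("scores and labels must have equal length")
  }
  if (!all(is.finite(scores))) fail_input("scores must be finite")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) fail_input("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)   # last index of each unique score
  tpr <- c(0, cumsum(y == 1L)[keep] / n_pos)
  fpr <- c(0, cumsum(y == 0L)[keep] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, s[keep]), fpr = fpr, tpr = tpr,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Sensitivity at a fixed specificity
#'
#' Linear interpolation of the ROC curve at false-positive rate
#' `1 - specificity`.
#'
#' @param roc A `"roc_curve"`.
#' @param specificity Target specificity in (0, 1).
#' @return Sensitivity (true-positive rate) at that operating point.
#' @export
sensitivity_at_specificity <- function(roc, specificity = 0.8) {
  stats::approx(roc$fpr, roc$tpr, xout = 1 - specificity,
                ties = max, rule = 2)$y
}

#' Default experiment configuration
#'
#' Settings for [run_experiment()]. The dictionary size and depth default to
#' a desk-scale configuration; the reference configuration of the framework
#' (128 atoms, 7 layers) is available through the command-line `fit-daa`
#' defaults and can be requested here explicitly.
#'
#' @param n_folds Cross-validation folds (default 10).
#' @param k Atoms per layer.
#' @param L Layers for the deep model.
#' @param layer Layer whose composed dictionary feeds the classifier
#'   (default: deepest).
#' @param aa_tol,aa_max_iter,inner_iter Archetypal solver settings.
#' @param spec Base-network settings, see [base_spec()].
#' @param n_subsets Ensemble subset count or "auto".
#' @param transductive If `TRUE`, fit the dictionary once on all samples
#'   before splitting (the study's original protocol); default `FALSE`
#'   refits per training fold so no test sample influences the dictionary.
#' @param prune_threshold Optional absolute-correlation pruning threshold
#'   applied to the dictionary before feature extraction.
#' @return Named list of class `"experiment_config"`.
#' @export
experiment_config <- function(n_folds = 10L, k = 16L, L = 2L, layer = NULL,
                              aa_tol = 1e-5, aa_max_iter = 100L,
                              inner_iter = 25L, spec = base_spec(),
                              n_subsets = "auto", transductive = FALSE,
                              prune_threshold = NULL) {
  structure(list(n_folds = as.integer(n_folds), k = as.integer(k),
                 L = as.integer(L), layer = layer, aa_tol = aa_tol,
                 aa_max_iter = as.integer(aa_max_iter),
                 inner_iter = as.integer(inner_iter), spec = spec,
                 n_subsets = n_subsets, transductive = isTRUE(transductive),
                 prune_threshold = prune_threshold),
            class = "experiment_config")
}

## Fit a dictionary on training features and return train/test codes.
encode_fold <- function(mode, F_train, F_test, config, seed) {
  if (mode == "raw") {
    return(list(train = F_train, test = F_test))
  }
  L <- if (mode == "aa") 1L else config$L
  model <- fit_daa(F_train, k = config$k, L = L, tol = config$aa_tol,
                   max_iter = config$aa_max_iter,
                   inner_iter = config$inner_iter, seed = seed)
  layer <- config$layer %||% model$L
  retained <- NULL
  if (!is.null(config$prune_threshold)) {
    D <- compose_dictionary(model, layer)
    usage <- rowSums(model$layers[[layer]]$A)
    retained <- prune_correlated_atoms(D, usage, config$prune_threshold)
  }
  list(train = predict(model, F_train, layer = layer, retained = retained),
       test = predict(model, F_test, layer = layer, retained = retained),
       model = model)
}

#' Cross-validated prediction experiment
#'
#' For each subject-grouped stratified fold: fit the dictionary (modes "aa"
#' and "daa") on training samples only, encode train and test samples as
#' convex codes, train the class-balanced ensemble on the training codes and
#' score the held-out samples. Reports per-fold AUCs (mean and SD) and the
#' AUC of the pooled out-of-fold scores. Disjointness of train and test
#' subjects is asserted at run time for every fold. Fully reproducible from
#' `(config, seed)`.
#'
#' @param cohort A [vf_cohort()].
#' @param feature_mode "raw" (input columns as features), "aa" (single-layer
#'   codes) or "daa" (deep codes).
#' @param config An [experiment_config()].
#' @param seed Integer seed.
#' @return An object of class `"vf_experiment"` with per-fold AUCs, pooled
#'   AUC, per-sample out-of-fold scores, configuration echo and seed.
#' @export
run_experiment <- function(cohort, feature_mode = c("daa", "aa", "raw"),
                           config = experiment_config(), seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  if (!inherits(cohort, "vf_cohort")) fail_input("cohort must be a vf_cohort")
  t0 <- proc.time()[["elapsed"]]
  folds <- make_folds(cohort$subject_ids, cohort$labels,
                      n_folds = config$n_folds, seed = seed)
  sample_fold <- fold_of_samples(folds, cohort$subject_ids)
  m <- ncol(cohort$features)
  scores <- rep(NA_real_, m)
  votes <- rep(NA_real_, m)
  fold_auc <- rep(NA_real_, config$n_folds)

  trans_model <- NULL
  if (config$transductive && feature_mode != "raw") {
    L <- if (feature_mode == "aa") 1L else config$L
    trans_model <- fit_daa(cohort$features, k = config$k, L = L,
                           tol = config$aa_tol, max_iter = config$aa_max_iter,
                           inner_iter = config$inner_iter,
                           seed = derive_seed(seed, 0L))
  }

  for (f in seq_len(config$n_folds)) {
    test <- which(sample_fold == f)
    train <- which(sample_fold != f)
    stopifnot(length(intersect(cohort$subject_ids[train],
                               cohort$subject_ids[test])) == 0L)
    if (length(test) == 0L) next
    if (length(unique(cohort$labels[train])) < 2L) {
      warning(sprintf("fold %d has a single-class training set; fold skipped", f),
              call. = FALSE)
      next
    }
    fseed <- derive_seed(seed, f)
    if (!is.null(trans_model)) {
      layer <- config$layer %||% trans_model$L
      enc <- list(train = predict(trans_model, cohort$features[, train, drop = FALSE],
                                  layer = layer),
                  test = predict(trans_model, cohort$features[, test, drop = FALSE],
                                 layer = layer))
    } else {
      enc <- encode_fold(feature_mode, cohort$features[, train, drop = FALSE],
                         cohort$features[, test, drop = FALSE], config, fseed)
    }
    train_cohort <- vf_cohort(enc$train, cohort$labels[train],
                              cohort$subject_ids[train], cohort$eye_ids[train])
    ens <- train_ensemble(train_cohort, spec = config$spec,
                          n_subsets = config$n_subsets, seed = fseed)
    scores[test] <- predict_scores(ens, enc$test)
    votes[test] <- predict_votes(ens, enc$test)$vote_fraction
    y_test <- cohort$labels[test]
    if (length(unique(y_test)) < 2L) {
      warning(sprintf("fold %d has a single-class test set; AUC undefined and excluded", f),
              call. = FALSE)
    } else {
      fold_auc[f] <- compute_roc(scores[test], y_test)$auc
    }
    vf_log("info", "fold %d/%d (%s): test n = %d, AUC = %s",
           f, config$n_folds, feature_mode, length(test),
           format(fold_auc[f], digits = 3))
  }

  scored <- !is.na(scores)
  pooled <- if (length(unique(cohort$labels[scored])) < 2L) {
    warning("pooled scores cover a single class; pooled AUC undefined",
            call. = FALSE)
    list(auc = NA_real_)
  } else {
    compute_roc(scores[scored], cohort$labels[scored])
  }
  structure(list(
    feature_mode = feature_mode,
    per_fold_auc = fold_auc,
    mean_auc = mean(fold_auc, na.rm = TRUE),
    sd_auc = stats::sd(fold_auc[!is.na(fold_auc)]),
    pooled_auc = pooled$auc,
    pooled_roc = pooled,
    scores = data.frame(subject_id = cohort$subject_ids,
                        eye_id = cohort$eye_ids,
                        label = cohort$labels,
                        fold = sample_fold,
                        score = scores,
                        vote_fraction = votes,
                        stringsAsFactors = FALSE),
    folds = folds, config = config, seed = seed,
    elapsed = proc.time()[["elapsed"]] - t0
  ), class = "vf_experiment")
}

#' @export
print.vf_experiment <- function(x, ...) {
  cat(sprintf("Cross-validated experiment (%s features, %d folds)\n",
              x$feature_mode, x$config$n_folds))
  cat(sprintf("  per-fold AUC: %.3f +/- %.3f  (pooled AUC: %.3f)\n",
              x$mean_auc, x$sd_auc, x$pooled_auc))
  invisible(x)
}
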