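test_that("fold assignment is subject-grouped and stratified", {
  # 10 subjects, 10 folds: one subject each
  ids <- sprintf("S%02d", 1:10)
  f <- make_folds(ids, rep(c(0L, 1L), 5), n_folds = 10, seed = 1)
  expect_setequal(unname(f$fold_of_subject), 1:10)
  # 20 positive + 80 negative subjects, 3 samples each, exact divisibility
  subj <- sprintf("S%03d", 1:100)
  lab_subj <- c(rep(1L, 20), rep(0L, 80))
  ids3 <- rep(subj, each = 3)
  lab3 <- rep(lab_subj, each = 3)
  fa <- make_folds(ids3, lab3, n_folds = 10, seed = 4)
  fold_lab <- split(lab_subj, fa$fold_of_subject[subj])
  expect_true(all(vapply(fold_lab, function(l) sum(l == 1), 0L) == 2L))
  expect_true(all(lengths(fold_lab) == 10L))
  expect_error(make_folds(ids, rep(0:1, 5), n_folds = 11),
               class = "daavf_input_error")
})

test_that("no subject ever lands in two folds", {
  subj <- rep(sprintf("S%02d", 1:23), times = rep(2:3, length.out = 23))
  lab <- as.integer(as.integer(factor(subj)) %% 4 == 0)
  for (s in 1:20) {
    fa <- make_folds(subj, lab, n_folds = 5, seed = s)
    per_sample <- fold_of_samples(fa, subj)
    expect_true(all(tapply(per_sample, subj, function(x) length(unique(x))) == 1))
  }
})

test_that("ROC agrees with hand-enumerated pairs and degenerate cases", {
  # 4 positive-negative pairs: 3 wins, 1 loss
  r <- compute_roc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(compute_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(compute_roc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(compute_roc(1:4, rep(1, 4)), class = "daavf_input_error")
})

test_that("ROC curve spans (0,0) to (1,1), is monotone, and equals its trapezoid", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    labels <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    scores <- round(rnorm(n), sample(0:2, 1))   # induce ties
    r <- compute_roc(scores, labels)
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    trap <- sum(diff(r$fpr) * (r$tpr[-1] + r$tpr[-length(r$tpr)]) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
    # pairwise Mann-Whitney oracle
    expect_equal(r$auc, auc_pairwise(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(32)
  scores <- rnorm(40)
  labels <- rep(c(0L, 1L), 20)
  a0 <- compute_roc(scores, labels)$auc
  expect_equal(compute_roc(exp(scores), labels)$auc, a0)
  expect_equal(compute_roc(rank(scores), labels)$auc, a0)
})

test_that("ROC matches an independent reference implementation", {
  set.seed(33)
  scores <- round(rnorm(60), 1)
  labels <- sample(c(0L, 1L), 60, replace = TRUE)
  labels[1:2] <- c(0L, 1L)
  ours <- compute_roc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("sensitivity at fixed specificity interpolates the curve", {
  r <- compute_roc(c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1),
                   c(1, 1, 1, 0, 1, 0, 0, 0))
  expect_equal(sensitivity_at_specificity(r, 1), 0.75)
  expect_equal(sensitivity_at_specificity(r, 0), 1)
})

test_that("cross-validated experiment is reproducible and leak-free", {
  syn <- sample_cohort(vf_spec(d = 20L, n_subjects = 60L, k_true = 3L,
                               seed = 2))
  cfg <- experiment_config(n_folds = 3, k = 4, L = 2, aa_max_iter = 15,
                           inner_iter = 8, spec = fast_spec())
  e1 <- run_experiment(syn$cohort, "daa", cfg, seed = 5)
  e2 <- run_experiment(syn$cohort, "daa", cfg, seed = 5)
  expect_identical(e1$pooled_auc, e2$pooled_auc)
  expect_identical(e1$scores$score, e2$scores$score)
  expect_true(e1$pooled_auc >= 0 && e1$pooled_auc <= 1)
  # every sample is scored exactly once, in its own fold
  expect_false(anyNA(e1$scores$score))
  expect_equal(e1$scores$fold,
               fold_of_samples(e1$folds, syn$cohort$subject_ids))
})

test_that("raw mode bypasses the dictionary stages", {
  syn <- sample_cohort(vf_spec(d = 12L, n_subjects = 40L, k_true = 3L,
                               seed = 3))
  cfg <- experiment_config(n_folds = 2, k = 3, L = 1, spec = fast_spec())
  e <- run_experiment(syn$cohort, "raw", cfg, seed = 1)
  # member networks consume the full measurement dimension, not k codes
  expect_s3_class(e, "vf_experiment")
  expect_equal(e$feature_mode, "raw")
})

test_that("single-class test folds are excluded with a warning", {
  # two positive subjects across three folds: one fold tests negatives only
  set.seed(40)
  feats <- matrix(rnorm(4 * 14), 4, 14)
  labels <- c(rep(1L, 4), rep(0L, 10))
  ids <- rep(sprintf("S%d", 1:7), each = 2)
  co <- vf_cohort(feats, labels, ids)
  cfg <- experiment_config(n_folds = 3, spec = fast_spec(), n_subsets = 1)
  expect_warning(e <- run_experiment(co, "raw", cfg, seed = 1),
                 "single-class")
  expect_true(sum(is.na(e$per_fold_auc)) >= 1)
  expect_true(is.finite(e$pooled_auc))
})
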