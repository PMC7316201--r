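test_that("planted atoms carve full-depth defects out of the normal field", {
  # flat normal field at 30 dB with 30 dB defects: blocks drop exactly to 0
  spec <- vf_spec(k_true = 3L, defect_depth = 30, hill_slope = 0,
                  noise_sigma = 0, seed = 5)
  atoms <- make_archetypes(spec)
  expect_equal(atoms[, 1], rep(30, 76))
  for (j in 2:3) {
    n_zero <- sum(atoms[, j] == 0)
    expect_gt(n_zero, 0)
    expect_true(all(atoms[, j] %in% c(0, 30)))
  }
  # distinct blocks: atoms are not perfectly correlated
  C <- cor(atoms[, 2:3])
  expect_lt(C[1, 2], 1)
})

test_that("archetype generation is deterministic and clips impossible depths", {
  spec <- vf_spec(seed = 9)
  expect_identical(make_archetypes(spec), make_archetypes(spec))
  deep <- vf_spec(defect_depth = 40, seed = 2)
  expect_warning(atoms <- make_archetypes(deep), "clipping")
  expect_true(all(atoms >= 0))
})

test_that("the 30-2 style grid has 76 locations split across hemifields", {
  coords <- daavf:::vf_grid_coords(76L)
  expect_equal(nrow(coords), 76L)
  expect_equal(sum(coords[, "y"] > 0), 38L)
  expect_equal(sum(coords[, "y"] < 0), 38L)
})

test_that("noiseless draws reconstruct exactly from atoms and weights", {
  spec <- vf_spec(n_subjects = 30L, noise_sigma = 0, seed = 3)
  syn <- sample_cohort(spec)
  expect_equal(syn$cohort$features,
               syn$true_archetypes %*% syn$true_weights, tolerance = 1e-12)
  expect_true(daavf:::check_simplex_columns(syn$true_weights))
})

test_that("cohort structure carries subjects, eyes and labels coherently", {
  syn <- sample_cohort(vf_spec(n_subjects = 40L, seed = 7))
  co <- syn$cohort
  # samples of one subject share its label and weight vector
  for (s in unique(co$subject_ids)) {
    idx <- which(co$subject_ids == s)
    expect_length(unique(co$labels[idx]), 1L)
    expect_true(length(idx) >= min(syn$spec$samples_per_subject) &&
                  length(idx) <= max(syn$spec$samples_per_subject))
    if (length(idx) > 1) {
      expect_equal(syn$true_weights[, idx[1]], syn$true_weights[, idx[2]])
    }
  }
  expect_false(any(duplicated(co$eye_ids)))
  expect_true(all(co$features >= 0))
})

test_that("positive prevalence follows the imbalance ratio", {
  syn <- sample_cohort(vf_spec(n_subjects = 900L, imbalance = 8, seed = 11))
  n_pos <- sum(syn$cohort$labels[!duplicated(syn$cohort$subject_ids)])
  # binomial 99% interval at n = 900, p = 1/9
  bounds <- qbinom(c(0.005, 0.995), 900, 1 / 9)
  expect_gte(n_pos, bounds[1])
  expect_lte(n_pos, bounds[2])
})

test_that("noiseless fits recover the planted archetypes", {
  # hull-covering draw: U-shaped defect mass, sparse split, no noise
  spec <- vf_spec(n_subjects = 300L, k_true = 4L, noise_sigma = 0,
                  defect_mass = 0.4, alpha_normal = 0.8, alpha_defect = 0.3,
                  seed = 13)
  syn <- sample_cohort(spec)
  fit <- fit_archetypes(syn$cohort$features, 4, seed = 1)
  matched <- match_archetypes(fit$D, syn$true_archetypes)
  expect_true(all(matched > 0.99))
})

test_that("recovery degrades as noise rises", {
  mean_cor <- vapply(c(0, 2, 5), function(ns) {
    cors <- vapply(1:2, function(s) {
      syn <- sample_cohort(vf_spec(n_subjects = 120L, k_true = 3L,
                                   noise_sigma = ns, defect_mass = 0.4,
                                   alpha_normal = 0.8, alpha_defect = 0.3,
                                   seed = 20 + s))
      fit <- fit_archetypes(syn$cohort$features, 3, max_iter = 80, seed = 1)
      mean(match_archetypes(fit$D, syn$true_archetypes))
    }, numeric(1))
    mean(cors)
  }, numeric(1))
  expect_true(all(diff(mean_cor) < 0))
})

test_that("spec validation catches impossible settings", {
  expect_error(vf_spec(d = 1), class = "daavf_input_error")
  expect_error(vf_spec(k_true = 1), class = "daavf_input_error")
  expect_error(vf_spec(imbalance = 0.5), class = "daavf_input_error")
  expect_error(vf_spec(noise_sigma = -1), class = "daavf_input_error")
})

test_that("classification separability rises with the focality dial", {
  cfg <- experiment_config(n_folds = 3, k = 12, L = 2, aa_max_iter = 40,
                           inner_iter = 15, transductive = TRUE)
  mean_auc <- vapply(c(0, 5), function(lev) {
    mean(vapply(1:3, function(s) {
      syn <- sample_cohort(vf_spec(n_subjects = 250, signal_strength = lev,
                                   seed = 60 + s))
      run_experiment(syn$cohort, "daa", cfg, seed = s)$pooled_auc
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean_auc[2], mean_auc[1])
})
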