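test_that("one layer reduces to plain archetypal analysis", {
  td <- triangle_data(60, seed = 1)
  m <- fit_daa(td$X, k = 3, L = 1, seed = 5)
  aa <- fit_archetypes(td$X, 3, seed = daavf:::derive_seed(5, 1))
  expect_identical(m$layers[[1]]$D, aa$D)
  expect_identical(compose_dictionary(m, 1), m$layers[[1]]$D)
})

test_that("layer stacking feeds codes forward and composes dictionaries", {
  td <- triangle_data(80, seed = 2)
  m <- fit_daa(td$X, k = 3, L = 2, seed = 1)
  # layer 2 was fitted on the codes of layer 1
  expect_equal(m$layers[[2]]$n, ncol(m$layers[[1]]$A))
  # columns of D2 live on the simplex of layer-1 codes
  expect_true(daavf:::check_simplex_columns(m$layers[[2]]$D))
  expect_equal(compose_dictionary(m, 2),
               m$layers[[1]]$D %*% m$layers[[2]]$D, tolerance = 1e-10)
})

test_that("dictionary composition is associative", {
  set.seed(8)
  X <- matrix(runif(4 * 60), 4, 60)
  m <- fit_daa(X, k = c(5, 4, 3), L = 3, max_iter = 40, seed = 2)
  D1 <- m$layers[[1]]$D; D2 <- m$layers[[2]]$D; D3 <- m$layers[[3]]$D
  expect_equal((D1 %*% D2) %*% D3, D1 %*% (D2 %*% D3), tolerance = 1e-10)
  expect_equal(compose_dictionary(m, 3), D1 %*% (D2 %*% D3), tolerance = 1e-10)
})

test_that("every deep atom lies in the convex hull of the data", {
  set.seed(9)
  X <- matrix(runif(3 * 50), 3, 50)
  m <- fit_daa(X, k = 4, L = 3, max_iter = 40, seed = 3)
  for (l in 1:3) {
    W <- daavf:::data_weights(m, l)
    expect_true(daavf:::check_simplex_columns(W))
    expect_equal(X %*% W, compose_dictionary(m, l), tolerance = 1e-8)
  }
})

test_that("reconstruction error is non-decreasing with depth", {
  set.seed(10)
  X <- matrix(rnorm(5 * 80), 5, 80)
  m <- fit_daa(X, k = 4, L = 3, max_iter = 40, seed = 1)
  errs <- vapply(1:3, function(i) {
    sum((X - compose_dictionary(m, i) %*% m$layers[[i]]$A)^2)
  }, numeric(1))
  expect_true(all(diff(errs) >= -1e-6))
})

test_that("deep layers add interior atoms while keeping extremal ones", {
  td <- triangle_data(200, seed = 3)
  m <- fit_daa(td$X, k = 3, L = 2, seed = 4)
  D2 <- compose_dictionary(m, 2)
  # distance of a 2-d point to each edge of the triangle (0,0),(1,0),(0,1)
  edge_dists <- function(p) c(p[2], p[1], (1 - p[1] - p[2]) / sqrt(2))
  interior <- apply(D2, 2, function(p) min(edge_dists(p)) > 0.01)
  near_vertex <- apply(D2, 2, function(p) {
    min(sqrt(colSums((td$V - p)^2))) < 0.1
  })
  expect_true(any(interior))
  expect_true(any(near_vertex))
})

test_that("layer bounds and atom counts are validated", {
  td <- triangle_data(20, seed = 4)
  expect_error(fit_daa(td$X, k = 30, L = 1), class = "daavf_input_error")
  err <- tryCatch(fit_daa(td$X, k = c(3, 25), L = 2, seed = 1),
                  error = identity)
  expect_s3_class(err, "daavf_input_error")
  expect_match(conditionMessage(err), "layer 2")
  m <- fit_daa(td$X, k = 3, L = 1, seed = 1)
  expect_error(compose_dictionary(m, 2), class = "daavf_input_error")
})

test_that("correlation pruning keeps one of each near-duplicate group", {
  D_same <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)
  # exactly one survives: the one with the highest usage
  expect_equal(prune_correlated_atoms(D_same, usage = c(1, 2, 3)), 3L)
  D_orth <- diag(4)
  expect_equal(prune_correlated_atoms(D_orth, usage = rep(1, 4), 0.9), 1:4)
  # atoms 1 and 2 correlate at ~0.995; usage order 1, 2, 3
  b <- c(1, 2, 3, 4, 5)
  D <- cbind(b, b + c(0.1, -0.1, 0, 0.1, -0.1), c(5, 1, 4, 2, 3))
  expect_gt(abs(cor(D[, 1], D[, 2])), 0.9)
  expect_equal(prune_correlated_atoms(D, usage = c(3, 2, 1), 0.9), c(1L, 3L))
  # higher-usage duplicate wins regardless of column order
  expect_equal(prune_correlated_atoms(D, usage = c(2, 3, 1), 0.9), c(2L, 3L))
})

test_that("pruning handles zero-variance atoms as uncorrelated", {
  D <- cbind(rep(1, 4), c(1, 2, 3, 4), rep(1, 4))
  kept <- prune_correlated_atoms(D, usage = c(3, 2, 1), 0.9)
  expect_equal(kept, c(1L, 2L))   # third is an exact duplicate of the first
  expect_error(prune_correlated_atoms(D, usage = c(1, 2), 0.9),
               class = "daavf_input_error")
})

test_that("feature extraction returns one-hot codes for atoms and round-trips", {
  td <- triangle_data(80, seed = 5, include_vertices = TRUE)
  m <- fit_daa(td$X, k = 3, L = 1, seed = 2)
  D <- compose_dictionary(m, 1)
  fs <- extract_features(m, D)
  expect_equal(fs$representation, diag(3), tolerance = 1e-5,
               ignore_attr = TRUE)
  # re-encoding training data reconstructs it within solver tolerance
  fs2 <- extract_features(m, td$X)
  expect_lt(sqrt(sum((D %*% fs2$representation - td$X)^2)) / sqrt(sum(td$X^2)),
            0.05)
  expect_error(extract_features(m, td$X, retained = integer(0)),
               class = "daavf_input_error")
  expect_error(extract_features(m, matrix(0, 5, 2)),
               class = "daavf_input_error")
})

test_that("codes match the grid oracle and respect permutations", {
  set.seed(12)
  X <- matrix(runif(3 * 40), 3, 40)
  m <- fit_daa(X, k = 3, L = 2, max_iter = 40, seed = 6)
  D <- compose_dictionary(m, 2)
  for (i in 1:5) {
    x <- runif(3)
    y <- predict(m, matrix(x), layer = 2)
    expect_lte(sum((x - D %*% y)^2), grid_min_objective(D, x, 200) + 1e-3)
  }
  # permutation equivariance in samples
  Xn <- matrix(runif(3 * 6), 3, 6)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(predict(m, Xn)[, perm], predict(m, Xn[, perm]))
  # atom reordering permutes the code rows correspondingly
  fs_perm <- extract_features(m, Xn, retained = c(2L, 3L, 1L))
  fs_all <- extract_features(m, Xn)
  expect_equal(fs_perm$representation,
               fs_all$representation[c(2, 3, 1), ],
               tolerance = 1e-6, ignore_attr = TRUE)
})
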