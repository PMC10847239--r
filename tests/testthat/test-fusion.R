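test_that("systematic 3:1 split keeps validation inside the calibration range", {
  withr::with_seed(31, y <- runif(104, 0.15, 0.73))
  sp <- split_calibration_validation(y)
  expect_length(sp$calibration, 78)
  expect_length(sp$validation, 26)
  expect_length(intersect(sp$calibration, sp$validation), 0)
  expect_setequal(c(sp$calibration, sp$validation), 1:104)
  expect_gte(min(y[sp$validation]), min(y[sp$calibration]))
  expect_lte(max(y[sp$validation]), max(y[sp$calibration]))
  expect_error(split_calibration_validation(runif(5)), "at least 8")
  spr <- split_calibration_validation(y, method = "random", seed = 2)
  expect_identical(spr,
                   split_calibration_validation(y, method = "random", seed = 2))
})

test_that("pixel fusion concatenates blocks with provenance labels", {
  ids <- sprintf("s%02d", 1:6)
  b1 <- feature_block(matrix(rnorm(6 * 224), 6, 224), ids, "spectra")
  b2 <- feature_block(matrix(rnorm(6 * 26), 6, 26), ids, "image")
  b3 <- feature_block(matrix(rnorm(6 * 10), 6, 10), ids, "enose")
  fused <- pixel_fusion(list(spectra = b1, image = b2, enose = b3))
  expect_equal(ncol(block_matrix(fused)), 260)
  expect_equal(fused$sample_id, ids)
  hsi <- pixel_fusion(list(spectra = b1, image = b2))
  expect_equal(ncol(block_matrix(hsi)), 250)
  vars <- colnames(block_matrix(fused))
  expect_equal(anyDuplicated(vars), 0)
  expect_equal(sum(startsWith(vars, "spectra_")), 224)
  # sample order mismatch is an error
  b2_shuffled <- b2[c(2, 1, 3:6), ]
  expect_error(pixel_fusion(list(spectra = b1, image = b2_shuffled)),
               "order")
})

test_that("feature fusion keeps only the selected columns, in order", {
  ids <- sprintf("s%02d", 1:8)
  b1 <- feature_block(matrix(rnorm(8 * 30), 8, 30), ids, "spectra")
  b2 <- feature_block(matrix(rnorm(8 * 12), 8, 12), ids, "image")
  fused <- feature_fusion(list(spectra = b1, image = b2),
                          list(c(14, 2, 9), c(5, 6)))
  m <- block_matrix(fused)
  expect_equal(ncol(m), 5)
  expect_equal(colnames(m)[1:3], paste0("spectra_V", c(2, 9, 14)))
  expect_error(feature_fusion(list(spectra = b1), list(integer(0))),
               "empty")
})

test_that("decision fusion reproduces the least-squares oracle", {
  withr::with_seed(32, {
    y <- runif(30, 0.2, 0.7)
    preds <- list(spectra = y,  # perfect spectral model
                  image = rnorm(30), enose = rnorm(30))
  })
  w <- decision_fusion_fit(y, preds)
  A <- cbind(1, as.matrix(as.data.frame(preds)))
  oracle <- drop(solve(crossprod(A), crossprod(A, y)))
  expect_equal(unname(w$coefficients), unname(oracle), tolerance = 1e-8)
  fused <- decision_fusion_apply(w, preds)
  expect_equal(fused, y, tolerance = 1e-8)  # zero calibration residual
  expect_equal(unname(w$coefficients), c(0, 1, 0, 0), tolerance = 1e-6)
})

test_that("collinear predictions fall back to the minimum-norm solution", {
  withr::with_seed(33, y <- runif(40, 0.2, 0.7))
  preds <- list(spectra = y, image = y, enose = y)
  expect_warning(w <- decision_fusion_fit(y, preds), "collinear")
  k <- unname(w$coefficients)
  expect_equal(k[1], 0, tolerance = 1e-4)
  expect_equal(k[2:4], rep(1 / 3, 3), tolerance = 1e-4)
  expect_equal(decision_fusion_apply(w, preds), y, tolerance = 1e-6)
})

test_that("decision-fusion application is affine in its inputs", {
  w <- structure(list(coefficients = c(b = 0.1, k_a = 1, k_b = 0, k_c = 0),
                      blocks = c("a", "b", "c")),
                 class = "fusion_weights")
  p <- list(a = c(1, 2), b = c(5, 5), c = c(9, 9))
  expect_equal(decision_fusion_apply(w, p), c(1.1, 2.1))
  w0 <- structure(list(coefficients = c(b = 0.3, k_a = 0, k_b = 0, k_c = 0),
                       blocks = c("a", "b", "c")),
                  class = "fusion_weights")
  expect_equal(decision_fusion_apply(w0, p), c(0.3, 0.3))
  expect_error(decision_fusion_apply(w, list(x = 1:2, y = 1:2, z = 1:2)),
               "match")
})

test_that("E-nose PCA + Ward clustering separates distinct drying stages", {
  spec <- enose_spec(noise = FALSE)
  stages_mc <- seq(0.70, 0.20, length.out = 7)
  # 8 replicates per stage with tiny within-stage MC spread
  mc <- rep(stages_mc, each = 8) +
    withr::with_seed(34, rnorm(56, 0, 0.004))
  m <- t(vapply(mc, function(x) generate_enose(x, spec), numeric(10)))
  truth <- rep(seq_len(7), each = 8)
  res <- enose_explore(m, n_clusters = 7)
  expect_equal(mclust::adjustedRandIndex(res$scores$cluster, truth), 1)
  expect_true(all(diff(res$var_ratio) <= 1e-12))
  expect_equal(sum(res$var_ratio), 1, tolerance = 1e-12)
  one <- enose_explore(m, n_clusters = 1)
  expect_equal(length(unique(one$scores$cluster)), 1)
})
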