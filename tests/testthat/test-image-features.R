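test_that("colour moments match hand-computed values on a two-pixel region", {
  img <- array(0, dim = c(1, 2, 3))
  img[1, 1, 1] <- 0.2
  img[1, 2, 1] <- 0.4  # red channel {0.2, 0.4}; green/blue zero
  mask <- matrix(TRUE, 1, 2)
  cm <- color_moments(img, mask)
  expect_length(cm, 18)
  expect_equal(cm[["mean_R"]], 0.3)
  expect_equal(cm[["sd_R"]], 0.1)  # population SD
  expect_equal(cm[["skew_R"]], 0)
})

test_that("constant-colour regions have zero second and third moments", {
  img <- array(0.6, dim = c(4, 4, 3))
  cm <- color_moments(img, matrix(TRUE, 4, 4))
  expect_equal(unname(cm[7:18]), rep(0, 12))
})

test_that("colour moments ignore pixels outside the mask", {
  withr::with_seed(8, img <- array(runif(5 * 5 * 3), dim = c(5, 5, 3)))
  mask <- matrix(FALSE, 5, 5); mask[2:4, 2:4] <- TRUE
  cm1 <- color_moments(img, mask)
  img2 <- img
  for (k in 1:3) {
    plane <- img2[, , k]; plane[!mask] <- 0.99; img2[, , k] <- plane
  }
  expect_equal(color_moments(img2, mask), cm1)
  expect_error(color_moments(img, mask & FALSE), "empty")
})

test_that("PCA score images reproduce a brute-force eigendecomposition", {
  # 3-pixel, 2-band toy cube against the 2x2 covariance eigen solve
  px <- matrix(c(1, 2, 4,
                 1, 3, 2), ncol = 2)
  a <- array(0, dim = c(1, 3, 2))
  a[1, , 1] <- px[, 1]; a[1, , 2] <- px[, 2]
  cube <- hsi_cube(a, c(500, 600))
  mask <- matrix(TRUE, 1, 3)
  res <- pca_score_images(cube, mask, cum_var = 0.99)
  ev <- eigen(stats::cov(px), symmetric = TRUE)
  expect_equal(res$var_ratio, ev$values / sum(ev$values), tolerance = 1e-12)
  # scores match the eigen projection up to sign, after min-max rescaling
  cen <- sweep(px, 2, colMeans(px))
  for (j in 1:2) {
    sc <- drop(cen %*% ev$vectors[, j])
    rescale <- function(x) (x - min(x)) / (max(x) - min(x))
    got <- res$images[[j]][1, ]
    expect_true(isTRUE(all.equal(got, rescale(sc), tolerance = 1e-8)) ||
                isTRUE(all.equal(got, rescale(-sc), tolerance = 1e-8)))
  }
})

test_that("rank-1 cubes put all variance on PC1 but still return two PCs", {
  sp <- c(1, 2, 3, 1)
  scal <- matrix(seq(0.5, 1.5, length.out = 12), 3, 4)
  a <- array(0, dim = c(3, 4, 4))
  for (b in 1:4) a[, , b] <- scal * sp[b]
  res <- pca_score_images(hsi_cube(a, c(4, 5, 6, 7) * 100),
                          matrix(TRUE, 3, 4))
  expect_equal(res$var_ratio[1], 1, tolerance = 1e-12)
  expect_equal(res$n_retained, 2L)
  expect_true(all(diff(res$var_ratio) <= 1e-12))
  expect_lte(sum(res$var_ratio), 1 + 1e-12)
})

test_that("GLCM matches the 2x2 checkerboard oracle at 0 degrees", {
  board <- matrix(c(0, 1, 1, 0), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  g <- glcm_features(board, mask, levels = 2, d = 1, angles = 0)
  # brute force: horizontal pairs (0,1) and (1,0) -> P = [[0,.5],[.5,0]]
  expect_equal(g[["contrast"]], 1)
  expect_equal(g[["energy"]], 0.5)
  expect_equal(g[["homogeneity"]], 0.5)
  expect_equal(g[["correlation"]], -1)
})

test_that("GLCM of a constant region is the degenerate single-cell case", {
  g <- glcm_features(matrix(5, 4, 4), matrix(TRUE, 4, 4), levels = 8)
  expect_equal(g[["contrast"]], 0)
  expect_equal(g[["energy"]], 1)
  expect_equal(g[["homogeneity"]], 1)
  expect_equal(g[["correlation"]], 0)  # 0/0 convention
})

test_that("GLCM energy is a probability sum of squares in (0, 1]", {
  withr::with_seed(5, img <- matrix(runif(100), 10, 10))
  mask <- matrix(FALSE, 10, 10); mask[2:9, 2:9] <- TRUE
  g <- glcm_features(img, mask)
  expect_gt(g[["energy"]], 0)
  expect_lte(g[["energy"]], 1)
  expect_gte(g[["homogeneity"]], 0)
  expect_lte(g[["homogeneity"]], 1)
  expect_gte(g[["correlation"]], -1)
  expect_lte(g[["correlation"]], 1)
})

test_that("GLCM ignores masked-out pixels entirely", {
  withr::with_seed(6, img <- matrix(runif(64), 8, 8))
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE
  g1 <- glcm_features(img, mask)
  img2 <- img; img2[!mask] <- 0.123
  expect_equal(glcm_features(img2, mask), g1)
})

test_that("direction-averaged GLCM is invariant to 90-degree rotation", {
  withr::with_seed(7, img <- matrix(runif(49), 7, 7))
  mask <- matrix(TRUE, 7, 7)
  g1 <- glcm_features(img, mask, levels = 8)
  rot <- t(img[nrow(img):1, ])  # 90-degree rotation
  g2 <- glcm_features(rot, mask, levels = 8)
  expect_equal(g1[c("contrast", "energy", "homogeneity")],
               g2[c("contrast", "energy", "homogeneity")],
               tolerance = 1e-12)
  expect_equal(g1[["correlation"]], g2[["correlation"]], tolerance = 1e-8)
})

test_that("the image feature vector has 26 uniquely labelled entries", {
  spec <- cube_spec(height = 32, width = 32)
  sim <- generate_cube(0.4, spec, seed = 17)
  cube <- reflectance_correct(sim$raw, sim$white, sim$black)
  fv <- image_feature_vector(cube, sim$mask)
  expect_length(fv, 26)
  expect_equal(anyDuplicated(names(fv)), 0)
  expect_equal(sum(startsWith(names(fv), "col_")), 18)
  expect_equal(sum(startsWith(names(fv), "tex_")), 8)
  # determinism on the identical cube
  expect_identical(fv, image_feature_vector(cube, sim$mask))
})
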