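test_that("black-and-white correction satisfies the defining identities", {
  withr::with_seed(1, {
    white <- array(runif(5 * 4 * 3, 0.8, 1.0), dim = c(5, 4, 3))
    black <- array(runif(5 * 4 * 3, 0.0, 0.1), dim = c(5, 4, 3))
  })
  expect_equal(reflectance_correct(white, white, black)$data,
               array(1, dim = c(5, 4, 3)), tolerance = 1e-12)
  expect_equal(reflectance_correct(black, white, black)$data,
               array(0, dim = c(5, 4, 3)), tolerance = 1e-12)
  mid <- black + 0.5 * (white - black)
  expect_equal(reflectance_correct(mid, white, black)$data,
               array(0.5, dim = c(5, 4, 3)), tolerance = 1e-12)
})

test_that("correction is invariant to a shared affine sensor transform", {
  withr::with_seed(2, {
    raw <- array(runif(6 * 6 * 4, 0.2, 0.7), dim = c(6, 6, 4))
  })
  white <- array(0.9, dim = c(6, 6, 4))
  black <- array(0.05, dim = c(6, 6, 4))
  r1 <- reflectance_correct(raw, white, black)
  r2 <- reflectance_correct(3 * raw + 0.2, 3 * white + 0.2, 3 * black + 0.2)
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
})

test_that("clipping is bounded, recorded, and fails loudly when excessive", {
  white <- array(1, dim = c(4, 4, 2))
  black <- array(0, dim = c(4, 4, 2))
  raw <- array(0.5, dim = c(4, 4, 2))
  raw[1, 1, 1] <- 1.9  # one hot pixel -> ratio 1.9, clipped to 1.5
  r <- reflectance_correct(raw, white, black)
  expect_equal(max(r$data), 1.5)
  expect_equal(attr(r, "clip_fraction"), 1 / 32)
  raw_bad <- array(2, dim = c(4, 4, 2))
  expect_error(reflectance_correct(raw_bad, white, black), "clip")
  # degenerate reference frames name the offending band
  white_flat <- white; white_flat[, , 2] <- 0
  expect_error(reflectance_correct(raw, white_flat, black), "band")
})

test_that("nearest_band matches a brute-force scan and handles edges", {
  wl <- cube_wavelengths(cube_spec())
  target <- 685.5
  expect_equal(nearest_band(wl, target), which.min(abs(wl - target)))
  expect_equal(nearest_band(wl, wl[1]), 1)
  expect_equal(nearest_band(wl, wl[224]), 224)
  expect_error(nearest_band(wl, 1003.81 + 2 * diff(wl)[1]), "outside")
  # ties break toward the lower index
  expect_equal(nearest_band(c(1, 2, 3), 1.5), 1)
})

test_that("ROI segmentation recovers the exact synthetic foreground", {
  spec <- cube_spec(noise = FALSE)
  sim <- generate_cube(0.45, spec, seed = 13)
  cube <- reflectance_correct(sim$raw, sim$white, sim$black)
  mask <- segment_roi(cube)
  expect_identical(mask, sim$mask)
  # idempotence: zeroing the background and re-segmenting gives the same ROI
  a <- cube$data
  bg <- !mask
  for (b in seq_len(dim(a)[3])) {
    plane <- a[, , b]; plane[bg] <- 0; a[, , b] <- plane
  }
  expect_identical(segment_roi(hsi_cube(a, cube$wavelengths)), mask)
})

test_that("segmentation fails on contrast-free images", {
  flat <- hsi_cube(array(0.5, dim = c(8, 8, 3)), c(400, 686, 900))
  expect_error(segment_roi(flat), "contrast")
})

test_that("mean_spectrum averages exactly over the mask", {
  toy <- toy_cube()
  a <- toy$cube$data
  one <- matrix(FALSE, dim(a)[1], dim(a)[2]); one[5, 5] <- TRUE
  expect_equal(unname(mean_spectrum(toy$cube, one)), a[5, 5, ])
  two <- one; two[6, 6] <- TRUE
  expect_equal(unname(mean_spectrum(toy$cube, two)),
               (a[5, 5, ] + a[6, 6, ]) / 2)
  full <- matrix(TRUE, dim(a)[1], dim(a)[2])
  expect_equal(unname(mean_spectrum(toy$cube, full)),
               apply(a, 3, mean))
  expect_error(mean_spectrum(toy$cube, full & FALSE), "empty")
})

test_that("RGB composite picks the nearest bands and clips to [0, 1]", {
  wl <- seq(400, 1000, length.out = 20)
  withr::with_seed(3, a <- array(runif(6 * 5 * 20, -0.1, 1.2),
                                 dim = c(6, 5, 20)))
  cube <- hsi_cube(a, wl)
  rgb <- rgb_composite(cube)
  clip01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
  expect_equal(rgb[, , 1], clip01(a[, , nearest_band(wl, 647)]))
  expect_equal(rgb[, , 3], clip01(a[, , nearest_band(wl, 460)]))
  expect_true(all(rgb >= 0 & rgb <= 1))
  zero <- hsi_cube(array(0, dim = c(3, 3, 20)), wl)
  expect_true(all(rgb_composite(zero) == 0))
})

test_that("stronger drying darkening lowers the red channel of dry samples", {
  mean_red <- function(darkening) {
    spec <- cube_spec(noise = FALSE, darkening = darkening)
    sim <- generate_cube(0.2, spec, seed = 4)  # dry sample
    rgb <- rgb_composite(sim$reflectance)
    mean(rgb[, , 1][sim$mask])
  }
  expect_gt(mean_red(0.1), mean_red(0.5))
})
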