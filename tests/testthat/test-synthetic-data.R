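test_that("dataset size is stages x replicates and generation is seeded", {
  ds <- generate_dataset(drying_design(), seed = 7)
  expect_equal(nrow(ds$samples), 104)
  ds2 <- generate_dataset(drying_design(), seed = 7)
  expect_identical(ds$samples, ds2$samples)
  small <- generate_dataset(drying_design(stage_times = c(0, 6),
                                          replicates_per_stage = 1),
                            seed = 3)
  expect_equal(nrow(small$samples), 2)
})

test_that("stage means track the drying curve and replicate SD is calibrated", {
  # single-stage design with many replicates: sample SD of MC must match
  # the configured between-replicate SD within 3 standard errors
  curve <- drying_curve_params()
  ds <- generate_dataset(drying_design(stage_times = 5,
                                       replicates_per_stage = 1200),
                         curve = curve, seed = 11)
  s_obs <- sd(ds$samples$mc_true)
  se <- curve$replicate_sd / sqrt(2 * (1200 - 1))
  expect_lt(abs(s_obs - curve$replicate_sd), 3 * se)
  expect_equal(mean(ds$samples$mc_true), mc_curve(5, curve),
               tolerance = 3 * curve$replicate_sd / sqrt(1200) /
                 mc_curve(5, curve))

  # expectation is monotone nonincreasing across the default stages
  expect_true(all(diff(mc_curve(0:12, curve)) <= 0))
})

test_that("noise-free cubes equal the closed-form foreground spectrum", {
  spec <- cube_spec(noise = FALSE)
  sim <- generate_cube(0.5, spec, seed = 3)
  expected <- shrimp_spectrum(0.5, spec = spec)
  px <- sim$reflectance$data
  fg_rows <- which(sim$mask)
  dim(px) <- c(prod(dim(sim$mask)), spec$n_bands)
  fg_px <- px[fg_rows, , drop = FALSE]
  expect_equal(max(abs(sweep(fg_px, 2, expected))), 0, tolerance = 1e-12)
  # and black-and-white correction recovers it through the raw cube
  r <- reflectance_correct(sim$raw, sim$white, sim$black)
  expect_equal(mean_spectrum(r, sim$mask), expected, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("water-band depth increases with moisture content", {
  spec <- cube_spec(noise = FALSE)
  wl <- cube_wavelengths(spec)
  b960 <- which.min(abs(wl - 960))
  wet <- shrimp_spectrum(0.70, wl, spec)
  dry <- shrimp_spectrum(0.20, wl, spec)
  expect_lt(wet[b960], dry[b960])
  # depth is strictly increasing in MC along a grid
  depths <- vapply(seq(0.1, 0.7, by = 0.1), function(mc) {
    sp <- shrimp_spectrum(mc, wl, spec)
    base <- shrimp_spectrum(0, wl, spec)
    base[b960] - sp[b960]
  }, numeric(1))
  expect_true(all(diff(depths) > 0))
})

test_that("foreground outshines background at the segmentation band", {
  spec <- cube_spec(noise = FALSE)
  sim <- generate_cube(0.4, spec, seed = 5)
  b <- nearest_band(sim$reflectance, 685.5)
  plane <- sim$reflectance$data[, , b]
  expect_gt(min(plane[sim$mask]), max(plane[!sim$mask]))
})

test_that("cube generation rejects nonpositive dimensions", {
  expect_error(cube_spec(height = 0), "positive")
  expect_error(cube_spec(n_bands = 1), "positive")
})

test_that("e-nose vectors are 10-long, deterministic and MC-monotone", {
  spec <- enose_spec(noise = FALSE)
  v <- generate_enose(0.5, spec)
  expect_length(v, 10)
  expect_named(v, paste0("S", 1:10))
  expect_identical(v, generate_enose(0.5, spec, seed = 99))
  # rank correlation of sensor 1 with MC over a noise-free grid is -1:
  # volatiles accumulate as moisture is lost
  grid <- seq(0.16, 0.72, length.out = 25)
  s1 <- vapply(grid, function(mc) generate_enose(mc, spec)[["S1"]],
               numeric(1))
  expect_equal(cor(s1, grid, method = "spearman"), -1)
})

test_that("the manifest records the ground truth needed for recovery", {
  ds <- generate_dataset(drying_design(stage_times = c(0, 3),
                                       replicates_per_stage = 2),
                         seed = 21)
  m <- ds$manifest
  expect_equal(m$seed, 21)
  expect_equal(m$curve$mc_start, 0.7275)
  expect_equal(nrow(m$samples), 4)
  expect_true(all(c("sample_id", "mc_true", "cube_seed") %in%
                    names(m$samples)))
})
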