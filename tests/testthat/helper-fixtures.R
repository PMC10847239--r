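# small in-code fixtures shared across test files

# tiny calibrated cube with a bright rectangle on a dark background
toy_cube <- function(H = 12, W = 10, B = 6, fg_val = 0.8, bg_val = 0.1,
                     wl = seq(400, 1000, length.out = B)) {
  a <- array(bg_val, dim = c(H, W, B))
  mask <- matrix(FALSE, H, W)
  mask[4:9, 3:7] <- TRUE
  for (b in seq_len(B)) {
    plane <- a[, , b]
    plane[mask] <- fg_val
    a[, , b] <- plane
  }
  list(cube = hsi_cube(a, wl), mask = mask)
}

# planted-signal regression data: p variables, two informative
planted_data <- function(seed, n = 80, p = 100,
                         informative = c(ceiling(p / 10), ceiling(p / 2)),
                         noise_sd = 0.05) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    y <- 2 * X[, informative[1]] + 1.5 * X[, informative[2]] +
      rnorm(n, 0, noise_sd)
    list(X = X, y = y, informative = informative)
  })
}

# synthetic tabular blocks with the pipeline's statistical structure but no
# imaging cost: spectra strongly MC-driven, image weakly, e-nose moderately
toy_blocks <- function(seed, n = 60, p_spec = 40, p_img = 12, p_nose = 10) {
  withr::with_seed(seed, {
    y <- runif(n, 0.15, 0.73)
    mk <- function(p, strength, noise) {
      load <- rnorm(p)
      base <- matrix(rnorm(n * p, sd = noise), n, p)
      m <- outer(y, load) * strength + base
      colnames(m) <- paste0("v", seq_len(p))
      m
    }
    ids <- sprintf("s%03d", seq_len(n))
    list(
      blocks = list(
        spectra = feature_block(mk(p_spec, 1.0, 0.05), ids, "spectra"),
        image = feature_block(mk(p_img, 0.4, 0.15), ids, "image"),
        enose = feature_block(mk(p_nose, 0.7, 0.08), ids, "enose")),
      y = y)
  })
}
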