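#' Synthetic hyperspectral cube settings
#'
#' Controls the simulated push-broom cube of one shrimp sample: an
#' elliptical shrimp on a dark background, imaged over 224 bands spanning
#' 397.66-1003.81 nm (linearly spaced; the instrument's true band centers
#' are not published). The foreground spectrum is a smooth reflectance
#' baseline minus water-absorption bands at 750 and 960 nm whose depth
#' increases with moisture content, with drying-dependent darkening of the
#' visible range. Noise terms emulate what the preprocessing steps are
#' there to remove: a per-sample multiplicative scattering factor and
#' additive offset (motivating SNV), a smooth within-shrimp texture field
#' that strengthens as the sample dries, and white sensor noise.
#'
#' @param height,width Spatial cube dimensions in pixels.
#' @param n_bands Number of spectral bands.
#' @param wl_range Wavelength range in nm (length 2).
#' @param bg_reflectance Flat background reflectance.
#' @param depth_scale Water-band depth per unit MC; absorption depth is
#'   `depth_scale * mc`, strictly increasing in MC.
#' @param darkening Maximum fractional darkening of the visible range at
#'   full dryness (colour change during drying).
#' @param mc_hi,mc_lo MC anchors (boiled / fully dried) used to normalize
#'   dryness for the darkening, shrinkage and texture terms.
#' @param scatter_sd SD of the per-sample log multiplicative scattering
#'   factor.
#' @param offset_sd SD of the per-sample additive baseline offset.
#' @param noise_sd SD of per-pixel, per-band white noise (also applied to
#'   the white/black reference frames).
#' @param texture_amp Amplitude of the smooth within-shrimp texture field.
#' @param center_jitter Max random shift of the shrimp center, pixels.
#' @param noise If `FALSE`, zero all five noise terms, making the cube an
#'   exact closed form of MC (see [shrimp_spectrum()]).
#' @return A list of class `cube_spec`.
#' @export
cube_spec <- function(height = 96L, width = 96L, n_bands = 224L,
                      wl_range = c(397.66, 1003.81),
                      bg_reflectance = 0.06,
                      depth_scale = 0.45, darkening = 0.35,
                      mc_hi = 0.7275, mc_lo = 0.1567,
                      scatter_sd = 0.08, offset_sd = 0.03,
                      noise_sd = 0.004, texture_amp = 0.06,
                      center_jitter = 3, noise = TRUE) {
  if (height <= 0 || width <= 0 || n_bands <= 1) {
    abort("cube dimensions must be positive (and n_bands > 1)")
  }
  if (!noise) {
    scatter_sd <- offset_sd <- noise_sd <- texture_amp <- center_jitter <- 0
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_bands = as.integer(n_bands), wl_range = wl_range,
         bg_reflectance = bg_reflectance, depth_scale = depth_scale,
         darkening = darkening, mc_hi = mc_hi, mc_lo = mc_lo,
         scatter_sd = scatter_sd, offset_sd = offset_sd,
         noise_sd = noise_sd, texture_amp = texture_amp,
         center_jitter = center_jitter),
    class = "cube_spec"
  )
}

#' @rdname cube_spec
#' @param spec A `cube_spec`.
#' @export
cube_wavelengths <- function(spec = cube_spec()) {
  seq(spec$wl_range[1], spec$wl_range[2], length.out = spec$n_bands)
}

# dryness in [0, 1]: 0 = boiled, 1 = fully dried
.dryness <- function(mc, spec) {
  pmin(1, pmax(0, (spec$mc_hi - mc) / (spec$mc_hi - spec$mc_lo)))
}

#' Closed-form shrimp foreground spectrum
#'
#' The noise-free reflectance spectrum of shrimp tissue at moisture content
#' `mc`: a smooth baseline (dip near 480 nm, rise through the visible,
#' plateau at 700-900 nm, gentle roll-off past 930 nm) darkened in the
#' visible range as the sample dries, minus Gaussian water-absorption bands
#' centered at 750 nm and (stronger) 960 nm with depth
#' `depth_scale * mc`.
#'
#' @param mc Moisture content, mass fraction.
#' @param wavelengths Wavelengths in nm.
#' @param spec A [cube_spec()].
#' @return Reflectance vector, same length as `wavelengths`.
#' @export
shrimp_spectrum <- function(mc, wavelengths = cube_wavelengths(spec),
                            spec = cube_spec()) {
  wl <- wavelengths
  base <- 0.30 + 0.32 * stats::plogis((wl - 560) / 60) -
    0.08 * exp(-((wl - 480) / 28)^2) -
    0.05 * stats::plogis((wl - 930) / 40)
  vis <- stats::plogis((700 - wl) / 30)
  dark <- base * (1 - spec$darkening * .dryness(mc, spec) * vis)
  bands <- 0.5 * exp(-((wl - 750) / 28)^2) + exp(-((wl - 960) / 45)^2)
  dark - spec$depth_scale * mc * bands
}

# elliptical foreground mask; the shrimp shrinks slightly as it dries
.shrimp_mask <- function(mc, spec, jitter = c(0, 0)) {
  shrink <- 0.85 + 0.15 * (1 - .dryness(mc, spec))
  cy <- (spec$height + 1) / 2 + jitter[1]
  cx <- (spec$width + 1) / 2 + jitter[2]
  ry <- 0.28 * spec$height * shrink
  rx <- 0.36 * spec$width * shrink
  row <- matrix(seq_len(spec$height), spec$height, spec$width)
  col <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  ((row - cy) / ry)^2 + ((col - cx) / rx)^2 <= 1
}

#' Simulate one hyperspectral acquisition
#'
#' Generates the raw cube plus white/black reference frames for one sample,
#' such that black-and-white correction of `raw` recovers the designed
#' reflectance cube. With `spec` noise disabled the foreground pixels equal
#' [shrimp_spectrum()] exactly.
#'
#' @param sample Either a numeric MC (mass fraction) or a one-row sample
#'   record (list/tibble row) with `mc_true` and optionally `cube_seed`.
#' @param spec A [cube_spec()].
#' @param seed Seed for the per-sample noise draws; overrides
#'   `sample$cube_seed` when given.
#' @return A list of class `hsi_sim` with elements `raw`, `white`, `black`
#'   (each an [hsi_cube()]), `reflectance` (the designed cube the
#'   correction should recover), `mask` (true foreground), `mc`.
#' @export
generate_cube <- function(sample, spec = cube_spec(), seed = NULL) {
  if (is.numeric(sample)) {
    mc <- sample[[1]]
  } else {
    mc <- sample$mc_true[[1]]
    seed <- seed %||% sample$cube_seed[[1]]
  }
  seed <- seed %||% 1L
  withr::with_seed(as.integer(seed), {
    H <- spec$height; W <- spec$width; B <- spec$n_bands
    wl <- cube_wavelengths(spec)
    jitter <- if (spec$center_jitter > 0) {
      runif(2, -spec$center_jitter, spec$center_jitter)
    } else c(0, 0)
    mask <- .shrimp_mask(mc, spec, jitter)
    fg <- shrimp_spectrum(mc, wl, spec)

    # per-sample scattering artefacts (what SNV removes)
    alpha <- exp(rnorm(1, 0, spec$scatter_sd))
    offset <- rnorm(1, 0, spec$offset_sd)

    # smooth texture field, stronger in drier samples
    tex <- matrix(0, H, W)
    if (spec$texture_amp > 0) {
      ry <- matrix(seq_len(H) / H, H, W)
      rx <- matrix(seq_len(W) / W, H, W, byrow = TRUE)
      for (k in 1:3) {
        f <- runif(2, 1.5, 5); ph <- runif(2, 0, 2 * pi)
        tex <- tex + sin(2 * pi * f[1] * ry + ph[1]) *
          cos(2 * pi * f[2] * rx + ph[2])
      }
      amp <- spec$texture_amp * (0.3 + 0.7 * .dryness(mc, spec))
      tex <- 1 + amp * tex / 3
    } else {
      tex <- tex + 1
    }

    refl <- array(spec$bg_reflectance, dim = c(H, W, B))
    fg_scaled <- alpha * fg + offset
    fg_idx <- which(mask)
    refl[outer(fg_idx, (seq_len(B) - 1L) * (H * W), `+`)] <-
      outer(tex[fg_idx], fg_scaled)
    if (spec$noise_sd > 0) {
      refl <- refl + rnorm(length(refl), 0, spec$noise_sd)
    }

    # reference frames are frame-averaged by the acquisition software, so
    # they are spatially uniform with only residual per-band noise and are
    # returned as per-band vectors (reflectance_correct broadcasts them)
    white_bands <- 0.94 - 0.06 * ((wl - 700) / 300)^2
    black_bands <- rep(0.04, B)
    if (spec$noise_sd > 0) {
      white_bands <- white_bands + rnorm(B, 0, spec$noise_sd / 10)
      black_bands <- black_bands + rnorm(B, 0, spec$noise_sd / 10)
    }
    off <- rep(black_bands, each = H * W)
    raw <- off + refl * (rep(white_bands, each = H * W) - off)
    dim(raw) <- c(H, W, B)

    structure(
      list(raw = hsi_cube(raw, wl), white = white_bands,
           black = black_bands, reflectance = hsi_cube(refl, wl),
           mask = mask, mc = mc, spec = spec),
      class = "hsi_sim"
    )
  })
}

#' Electronic-nose simulation settings
#'
#' The 10-sensor array is modeled as saturating (Michaelis-Menten-like)
#' responses to a volatile latent variable that grows as the sample dries:
#' `response_i = base_i + sign_i * amp_i * v / (v + K_i)` with
#' `v = dryness(mc)`. Sensor constants are fixed; some sensors respond
#' positively and some negatively, as in a metal-oxide array reporting
#' conductance ratios. Drift multiplies each sample's vector by a
#' log-normal gain.
#'
#' @param drift_sd SD of the per-sample log gain drift.
#' @param noise_sd SD of additive per-sensor noise.
#' @param noise If `FALSE`, zero both, making the response a deterministic
#'   function of MC.
#' @return A list of class `enose_spec` including the sensor constant table.
#' @export
enose_spec <- function(drift_sd = 0.02, noise_sd = 0.01, noise = TRUE) {
  if (!noise) drift_sd <- noise_sd <- 0
  sensors <- tibble(
    sensor = paste0("S", 1:10),
    base = c(1.00, 1.10, 1.60, 0.90, 1.40, 1.20, 1.00, 1.50, 1.10, 0.95),
    sign = c(1, 1, -1, 1, -1, 1, 1, -1, 1, 1),
    amp  = c(2.00, 1.20, 0.60, 1.60, 0.80, 2.60, 1.00, 0.50, 1.80, 1.40),
    K    = c(0.35, 0.80, 0.50, 1.20, 0.30, 0.60, 1.50, 0.90, 0.45, 0.70)
  )
  structure(list(drift_sd = drift_sd, noise_sd = noise_sd,
                 sensors = sensors, mc_hi = 0.7275, mc_lo = 0.1567),
            class = "enose_spec")
}

#' Simulate one E-nose measurement
#'
#' @param sample Numeric MC or a sample record with `mc_true` and
#'   optionally `enose_seed`.
#' @param spec An [enose_spec()].
#' @param seed Seed for drift/noise draws.
#' @return Named numeric vector of 10 steady-state sensor responses.
#' @export
generate_enose <- function(sample, spec = enose_spec(), seed = NULL) {
  if (is.numeric(sample)) {
    mc <- sample[[1]]
  } else {
    mc <- sample$mc_true[[1]]
    seed <- seed %||% sample$enose_seed[[1]]
  }
  seed <- seed %||% 1L
  v <- max(0, (spec$mc_hi - mc) / (spec$mc_hi - spec$mc_lo))
  sn <- spec$sensors
  resp <- sn$base + sn$sign * sn$amp * v / (v + sn$K)
  withr::with_seed(as.integer(seed), {
    gain <- exp(rnorm(1, 0, spec$drift_sd))
    resp <- resp * gain + rnorm(10, 0, spec$noise_sd)
  })
  setNames(resp, sn$sensor)
}

#' Generate a full synthetic drying dataset
#'
#' Draws the complete experiment: per-stage replicate MC values around the
#' drying curve, an E-nose vector per sample, and per-sample seeds from
#' which each hyperspectral cube is generated on demand (cubes are large,
#' so they are not materialized here; see [dataset_cube()]). The same seed
#' always reproduces the identical dataset.
#'
#' @param design A [drying_design()].
#' @param curve A [drying_curve_params()].
#' @param cube A [cube_spec()].
#' @param enose An [enose_spec()].
#' @param seed Master seed; defaults to `design$seed`.
#' @return A list of class `drying_dataset` with the sample tibble
#'   (`sample_id`, `stage_h`, `mc_true`, `cube_seed`, `enose_seed`,
#'   `S1..S10`), the component specs, and a `manifest` list recording every
#'   ground-truth parameter.
#' @export
#' @examples
#' ds <- generate_dataset(drying_design(), seed = 7)
#' nrow(ds$samples)  # 104
generate_dataset <- function(design = drying_design(),
                             curve = drying_curve_params(),
                             cube = cube_spec(),
                             enose = enose_spec(),
                             seed = design$seed) {
  withr::with_seed(as.integer(seed), {
    grid <- tidyr::expand_grid(stage_h = design$stage_times,
                               rep = seq_len(design$replicates_per_stage))
    n <- nrow(grid)
    mc <- mc_curve(grid$stage_h, curve) +
      rnorm(n, 0, curve$replicate_sd)
    mc <- pmin(0.98, pmax(0.02, mc))
    samples <- tibble(
      sample_id = sprintf("s%03d", seq_len(n)),
      stage_h = grid$stage_h,
      mc_true = mc,
      cube_seed = sample.int(.Machine$integer.max - 1L, n),
      enose_seed = sample.int(.Machine$integer.max - 1L, n)
    )
    resp <- purrr::map(seq_len(n), function(i) {
      generate_enose(samples[i, ], enose)
    })
    samples <- dplyr::bind_cols(samples, dplyr::bind_rows(resp))
    manifest <- list(
      seed = as.integer(seed),
      design = unclass(design), curve = unclass(curve),
      cube_spec = unclass(cube),
      enose_spec = c(unclass(enose)[c("drift_sd", "noise_sd")],
                     list(sensors = as.data.frame(enose$sensors))),
      samples = as.data.frame(samples[c("sample_id", "stage_h", "mc_true",
                                        "cube_seed", "enose_seed")])
    )
    structure(
      list(samples = samples, design = design, curve = curve,
           cube_spec = cube, enose_spec = enose, seed = as.integer(seed),
           manifest = manifest),
      class = "drying_dataset"
    )
  })
}

#' @export
print.drying_dataset <- function(x, ...) {
  cat(sprintf(
    "<drying_dataset> %d samples (%d stages x %d replicates), seed %d\n",
    nrow(x$samples), length(x$design$stage_times),
    x$design$replicates_per_stage, x$seed))
  cat(sprintf("  MC range %.3f-%.3f; cube %dx%dx%d\n",
              min(x$samples$mc_true), max(x$samples$mc_true),
              x$cube_spec$height, x$cube_spec$width, x$cube_spec$n_bands))
  invisible(x)
}

#' Materialize the cube of one dataset sample
#'
#' @param dataset A [generate_dataset()] result.
#' @param i Sample index or `sample_id`.
#' @return The [generate_cube()] bundle for that sample.
#' @export
dataset_cube <- function(dataset, i) {
  if (is.character(i)) i <- match(i, dataset$samples$sample_id)
  generate_cube(dataset$samples[i, ], dataset$cube_spec)
}

#' E-nose feature block of a dataset
#'
#' @param dataset A [generate_dataset()] result.
#' @return A feature-block tibble (role `"enose"`) with sensors S1..S10.
#' @export
enose_block <- function(dataset) {
  s <- dataset$samples
  feature_block(as.matrix(s[paste0("S", 1:10)]), s$sample_id, role = "enose")
}
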