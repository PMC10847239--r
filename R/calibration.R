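#' Hyperspectral cube container
#'
#' A thin container for an H x W x B reflectance (or raw-count) array plus
#' its strictly increasing wavelength axis in nm. Coordinates are 0-free R
#' conventions: `data[row, col, band]`, origin top-left.
#'
#' @param data Numeric array, H x W x B.
#' @param wavelengths Numeric vector of length B, strictly increasing (nm).
#' @return A list of class `hsi_cube`.
#' @export
hsi_cube <- function(data, wavelengths) {
  if (length(dim(data)) != 3) abort("cube data must be a 3-d array")
  if (dim(data)[3] != length(wavelengths)) {
    abort("length(wavelengths) must equal the number of bands")
  }
  if (any(diff(wavelengths) <= 0)) abort("wavelengths must be strictly increasing")
  structure(list(data = data, wavelengths = as.numeric(wavelengths)),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> %d x %d px, %d bands (%.2f-%.2f nm)\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$data)

.cube_array <- function(x) if (inherits(x, "hsi_cube")) x$data else x

#' Black-and-white reflectance correction
#'
#' Converts a raw cube to reflectance with the standard two-point
#' correction `R = (raw - black) / (white - black)` per pixel per band,
#' removing light-source non-uniformity and dark current. `white` and
#' `black` may be full cubes, single-band spatial frames recycled over
#' bands, or per-band vectors recycled over pixels. Values are clipped to
#' `[0, 1.5]` (noise can push the ratio outside `[0, 1]`); the clipped
#' fraction is recorded in the `"clip_fraction"` attribute and more than 5%
#' clipping is an error.
#'
#' @param raw Raw cube ([hsi_cube()] or array).
#' @param white,black Reference frames (cube, array, or length-B vector).
#' @param eps Minimum allowed `white - black` dynamic range.
#' @return Calibrated [hsi_cube()] with values in `[0, 1.5]`.
#' @export
reflectance_correct <- function(raw, white, black, eps = 1e-6) {
  wl <- if (inherits(raw, "hsi_cube")) raw$wavelengths else NULL
  raw <- .cube_array(raw)
  d <- dim(raw)
  as_bands <- function(x) {
    x <- .cube_array(x)
    if (is.null(dim(x)) && length(x) == d[3]) x
    else if (identical(dim(x), d)) NULL
    else abort("reference frame shape incompatible with the raw cube")
  }
  wb <- as_bands(white); bb <- as_bands(black)
  if (!is.null(wb) && !is.null(bb)) {
    # per-band reference vectors: broadcast without materializing frames
    denom_b <- wb - bb
    if (min(denom_b) < eps) {
      abort(sprintf(
        "calibration frames have no dynamic range (white - black < %g) at band(s) %s",
        eps, paste(head(which(denom_b < eps), 5), collapse = ", ")))
    }
    npx <- d[1] * d[2]
    r <- (raw - rep(bb, each = npx)) * rep(1 / denom_b, each = npx)
    dim(r) <- d
  } else {
    white <- if (is.null(wb)) .cube_array(white) else
      array(rep(wb, each = d[1] * d[2]), dim = d)
    black <- if (is.null(bb)) .cube_array(black) else
      array(rep(bb, each = d[1] * d[2]), dim = d)
    denom <- white - black
    if (min(denom) < eps) {
      bad <- which(apply(denom, 3, min) < eps)
      abort(sprintf(
        "calibration frames have no dynamic range (white - black < %g) at band(s) %s",
        eps, paste(head(bad, 5), collapse = ", ")))
    }
    r <- (raw - black) / denom
  }
  clipped <- (sum(r < 0) + sum(r > 1.5)) / length(r)
  if (clipped > 0.05) {
    abort(sprintf("%.1f%% of pixels clip outside [0, 1.5]; calibration frames suspect",
                  100 * clipped))
  }
  r[r < 0] <- 0
  r[r > 1.5] <- 1.5
  out <- hsi_cube(r, wl %||% seq_len(d[3]))
  attr(out, "clip_fraction") <- clipped
  out
}

#' Band index nearest a target wavelength
#'
#' Nearest-neighbour lookup on the wavelength axis (no interpolation); ties
#' break toward the lower index. Targets outside the axis range by more
#' than half the local band spacing are rejected.
#'
#' @param cube An [hsi_cube()] or a numeric wavelength vector.
#' @param target_nm Target wavelength in nm.
#' @return Integer band index.
#' @export
nearest_band <- function(cube, target_nm) {
  wl <- if (inherits(cube, "hsi_cube")) cube$wavelengths else as.numeric(cube)
  half <- if (length(wl) > 1) diff(range(wl)) / (length(wl) - 1) / 2 else Inf
  if (target_nm < min(wl) - half || target_nm > max(wl) + half) {
    abort(sprintf("target %.2f nm outside wavelength axis [%.2f, %.2f]",
                  target_nm, min(wl), max(wl)))
  }
  which.min(abs(wl - target_nm))
}

#' Segment the sample region of interest
#'
#' Thresholds the single-band image at the wavelength of maximal
#' sample/background contrast (685.5 nm by default) with Otsu's method,
#' takes the side with the higher mean reflectance as foreground, and
#' keeps the largest connected component.
#'
#' @param cube Calibrated [hsi_cube()].
#' @param band_nm Segmentation wavelength (nm).
#' @return Logical H x W matrix, `TRUE` on the sample.
#' @export
segment_roi <- function(cube, band_nm = 685.5) {
  img <- .cube_array(cube)[, , nearest_band(cube, band_nm)]
  rng <- range(img)
  if (diff(rng) < 1e-9) abort("segmentation failure: band image has no contrast")
  scaled <- (img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  fg <- scaled > thr
  if (mean(img[fg]) < mean(img[!fg])) fg <- !fg
  if (!any(fg)) abort("segmentation failure: empty foreground")
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- EBImage::imageData(lab)
  counts <- tabulate(lab[lab > 0])
  mask <- lab == which.max(counts)
  if (!any(mask)) abort("segmentation failure: empty foreground")
  mask
}

#' Mean spectrum over a region of interest
#'
#' @param cube An [hsi_cube()].
#' @param mask Logical H x W matrix with at least one `TRUE` pixel.
#' @return Named numeric vector, the per-band arithmetic mean of the masked
#'   pixels.
#' @export
mean_spectrum <- function(cube, mask) {
  if (!any(mask)) abort("empty mask")
  wl <- if (inherits(cube, "hsi_cube")) cube$wavelengths
        else seq_len(dim(.cube_array(cube))[3])
  setNames(colMeans(.mask_pixels(cube, mask)), sprintf("wl_%.2f", wl))
}

# foreground pixels as an n_px x B matrix
.mask_pixels <- function(cube, mask) {
  a <- .cube_array(cube)
  d <- dim(a)
  dim(a) <- c(d[1] * d[2], d[3])
  a[which(mask), , drop = FALSE]
}

#' RGB composite from a hyperspectral cube
#'
#' Builds a true-colour-style composite from the bands nearest 647 (R),
#' 550 (G) and 460 (B) nm, clipped to `[0, 1]`.
#'
#' @param cube Calibrated [hsi_cube()].
#' @param rgb_nm Wavelengths of the three channels.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
rgb_composite <- function(cube, rgb_nm = c(647, 550, 460)) {
  a <- .cube_array(cube)
  idx <- vapply(rgb_nm, function(t) nearest_band(cube, t), integer(1))
  out <- a[, , idx, drop = FALSE]
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
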