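#' Colour moments of the masked sample image
#'
#' Computes the classic 18 colour-moment descriptors: for each of the six
#' channels R, G, B, H, S, V (hue scaled to `[0, 1]`), the mean, the
#' population standard deviation, and the skewness defined as the signed
#' cube root of the third central moment. The result is moments-major:
#' all six means, then the six SDs, then the six skewnesses.
#'
#' @param rgb_image H x W x 3 array in `[0, 1]`.
#' @param mask Logical H x W matrix; moments are computed over `TRUE`
#'   pixels only.
#' @return Named numeric vector of length 18.
#' @export
color_moments <- function(rgb_image, mask) {
  if (!any(mask)) abort("empty mask")
  rgb <- vapply(1:3, function(k) rgb_image[, , k][mask],
                numeric(sum(mask)))
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
  ch <- cbind(rgb, hsv)
  colnames(ch) <- c("R", "G", "B", "H", "S", "V")
  m1 <- colMeans(ch)
  cen <- sweep(ch, 2, m1)
  m2 <- sqrt(colMeans(cen^2))
  m3c <- colMeans(cen^3)
  m3c[abs(m3c) < 1e-14] <- 0  # cube root would amplify cancellation error
  m3 <- sign(m3c) * abs(m3c)^(1 / 3)
  out <- c(m1, m2, m3)
  names(out) <- paste(rep(c("mean", "sd", "skew"), each = 6),
                      rep(colnames(ch), 3), sep = "_")
  out
}

#' Principal-component score images of the masked cube
#'
#' Runs PCA over the foreground pixels, treating the spectral bands as
#' variables (mean-centered, unscaled). Retains the smallest number of
#' components whose cumulative explained variance reaches `cum_var`, but
#' always at least 2 so that PC1 and PC2 texture is available. Scores are
#' min-max rescaled to `[0, 1]` per component and painted back onto the
#' spatial grid with background 0.
#'
#' @param cube Calibrated [hsi_cube()].
#' @param mask Logical foreground mask with >= 2 pixels.
#' @param cum_var Cumulative explained-variance target.
#' @return List with `images` (list of H x W score matrices),
#'   `var_ratio` (explained-variance ratios of all components), and
#'   `n_retained`.
#' @export
pca_score_images <- function(cube, mask, cum_var = 0.99) {
  px <- .mask_pixels(cube, mask)
  if (nrow(px) < 2) abort("need at least 2 foreground pixels for PCA")
  if (all(apply(px, 2, stats::var) < 1e-18)) {
    abort("degenerate foreground: zero variance in every band")
  }
  # PCA via the band covariance eigendecomposition (bands << pixels, so
  # this is much cheaper than an SVD of the pixel matrix)
  cen <- sweep(px, 2, colMeans(px))
  ev <- eigen(crossprod(cen) / (nrow(cen) - 1), symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  ratio <- vals / sum(vals)
  k <- max(2L, which(cumsum(ratio) >= cum_var)[1])
  k <- min(k, ncol(cen))
  scores <- cen %*% ev$vectors[, seq_len(k), drop = FALSE]
  images <- lapply(seq_len(k), function(j) {
    sc <- scores[, j]
    rng <- range(sc)
    sc <- if (diff(rng) > 0) (sc - rng[1]) / diff(rng) else rep(0, length(sc))
    img <- matrix(0, nrow(mask), ncol(mask))
    img[mask] <- sc
    img
  })
  names(images) <- paste0("PC", seq_len(k))
  list(images = images, var_ratio = ratio, n_retained = k)
}

# offsets (drow, dcol) for the four GLCM directions in image coordinates
.glcm_offsets <- function(d) {
  list(`0` = c(0, d), `45` = c(-d, d), `90` = c(-d, 0), `135` = c(-d, -d))
}

#' Grey-level co-occurrence texture statistics
#'
#' Quantizes the masked pixels to `levels` grey levels (min-max over the
#' mask), builds the symmetric normalized co-occurrence matrix at offset
#' distance `d` for each requested direction counting only pixel pairs
#' with both ends inside the mask, computes contrast, correlation, energy
#' and homogeneity, and averages over directions. Correlation of a
#' zero-variance (single-level) region is defined as 0.
#'
#' @param gray_image H x W numeric matrix.
#' @param mask Logical H x W matrix.
#' @param levels Number of grey levels.
#' @param d Pixel offset distance.
#' @param angles Directions in degrees, subset of `c(0, 45, 90, 135)`.
#' @return Named numeric vector `(contrast, correlation, energy,
#'   homogeneity)`.
#' @export
glcm_features <- function(gray_image, mask, levels = 32L, d = 1L,
                          angles = c(0, 45, 90, 135)) {
  if (!any(mask)) abort("empty mask")
  rng <- range(gray_image[mask])
  q <- matrix(1L, nrow(gray_image), ncol(gray_image))
  if (diff(rng) > 0) {
    q <- floor((gray_image - rng[1]) / diff(rng) * levels) + 1L
    q[q > levels] <- levels
    q[q < 1L] <- 1L
  }
  H <- nrow(q); W <- ncol(q)
  offs <- .glcm_offsets(d)[as.character(angles)]
  if (any(vapply(offs, is.null, logical(1)))) {
    abort("angles must be a subset of 0, 45, 90, 135")
  }
  stats_one <- function(off) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(H, H - dr)
    c1 <- max(1, 1 - dc):min(W, W - dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(ok)) abort("mask admits no valid pixel pairs for the GLCM")
    i <- a[ok]; j <- b[ok]
    # symmetric counts: each ordered pair and its transpose
    counts <- tabulate(c((j - 1L) * levels + i, (i - 1L) * levels + j),
                       nbins = levels * levels)
    P <- matrix(counts / sum(counts), levels, levels)
    lev <- seq_len(levels)
    pi_ <- rowSums(P)
    mu <- sum(lev * pi_)
    sig2 <- sum((lev - mu)^2 * pi_)
    ii <- matrix(lev, levels, levels)
    jj <- t(ii)
    contrast <- sum(P * (ii - jj)^2)
    energy <- sum(P^2)
    homogeneity <- sum(P / (1 + (ii - jj)^2))
    correlation <- if (sig2 < 1e-15) 0 else {
      sum((ii - mu) * (jj - mu) * P) / sig2
    }
    c(contrast = contrast, correlation = correlation,
      energy = energy, homogeneity = homogeneity)
  }
  res <- vapply(offs, stats_one, numeric(4))
  rowMeans(res)
}

#' The 26-variable image feature vector
#'
#' Concatenates the 18 colour moments of the RGB composite with the four
#' GLCM statistics of each of the PC1 and PC2 score images (8 texture
#' values), matching the image-variable block of the drying study.
#'
#' @param cube Calibrated [hsi_cube()].
#' @param mask Logical foreground mask.
#' @param levels,d GLCM quantization levels and offset distance.
#' @return Named numeric vector of length 26 with stable labels
#'   (`col_*`, `tex_*`).
#' @export
image_feature_vector <- function(cube, mask, levels = 32L, d = 1L) {
  cm <- color_moments(rgb_composite(cube), mask)
  sc <- pca_score_images(cube, mask)
  tex <- unlist(lapply(c("PC1", "PC2"), function(pc) {
    g <- glcm_features(sc$images[[pc]], mask, levels = levels, d = d)
    setNames(g, paste("tex", names(g), pc, sep = "_"))
  }))
  c(setNames(cm, paste0("col_", names(cm))), tex)
}
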