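#' Standard normal variate transform
#'
#' Centers every sample row to mean 0 and scales it to unit sample
#' standard deviation, removing per-sample multiplicative scatter and
#' additive baseline effects. Operates on the variable columns of a
#' feature block (or a plain matrix) row by row, so no information flows
#' between samples.
#'
#' @param block Feature-block tibble or numeric matrix (samples x
#'   variables, >= 2 variables).
#' @return Object of the same shape with SNV-transformed rows.
#' @export
snv <- function(block) {
  m <- block_matrix(block)
  if (ncol(m) < 2) abort("SNV needs at least 2 variables per row")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  bad <- which(s < 1e-12)
  if (length(bad)) {
    ids <- rownames(m)[bad] %||% bad
    abort(paste0("zero-variance rows cannot be SNV-scaled: ",
                 paste(head(ids, 5), collapse = ", ")))
  }
  out <- (m - mu) / s
  block_rebuild(block, out, colnames(m))
}

#' Savitzky-Golay derivative filtering
#'
#' Applies a per-row Savitzky-Golay derivative of order 1 or 2 (local
#' least-squares polynomial fit of degree `polyorder` in a sliding window
#' of `window` points). Output has the same shape; window ends are handled
#' by the polynomial-fit extension, so polynomials of degree <=
#' `polyorder` are differentiated exactly everywhere including the edges.
#'
#' @param block Feature-block tibble or matrix.
#' @param deriv_order Derivative order, 1 or 2.
#' @param window Odd window length, `<= n_variables`.
#' @param polyorder Polynomial degree, `>= deriv_order` and `< window`.
#' @return Same shape as `block`, filtered row-wise.
#' @export
savgol_derivative <- function(block, deriv_order = 1L, window = 11L,
                              polyorder = 2L) {
  if (!deriv_order %in% 1:2) abort("deriv_order must be 1 or 2")
  if (window %% 2 == 0) abort("window must be odd")
  if (polyorder >= window) abort("polyorder must be < window")
  if (polyorder < deriv_order) abort("polyorder must be >= deriv_order")
  m <- block_matrix(block)
  if (ncol(m) < window) {
    abort(sprintf("window (%d) exceeds the number of variables (%d)",
                  window, ncol(m)))
  }
  out <- t(apply(m, 1, function(r) {
    signal::sgolayfilt(r, p = polyorder, n = window, m = deriv_order, ts = 1)
  }))
  block_rebuild(block, out, colnames(m))
}

.recipes <- c("RAW", "FD-SNV", "SD-SNV", "SNV", "SNV-FD", "SNV-SD")

#' Apply a named preprocessing recipe
#'
#' The six recipes screened for every block in the drying study: `RAW`
#' (identity), `SNV`, and the four derivative/SNV composites. Hyphenated
#' names read left to right as application order, so `FD-SNV` is the
#' first Savitzky-Golay derivative followed by SNV. The default window of
#' 11 points suits the 224-band spectra; blocks with fewer variables than
#' the window (the 10-sensor E-nose block) automatically fall back to a
#' 5-point window.
#'
#' @param block Feature-block tibble or matrix.
#' @param name One of `r paste(.recipes, collapse = ", ")`.
#' @param window,polyorder Savitzky-Golay settings for the derivative
#'   steps.
#' @return Preprocessed block, same shape and sample order; the recipe
#'   name is recorded in the `"recipe"` attribute.
#' @export
apply_recipe <- function(block, name, window = 11L, polyorder = 2L) {
  if (!name %in% .recipes) {
    abort(sprintf("unknown recipe '%s' (expected one of %s)", name,
                  paste(.recipes, collapse = ", ")))
  }
  p <- ncol(block_matrix(block))
  if (p < window) window <- 5L
  step <- function(x, op) {
    switch(op,
      FD = savgol_derivative(x, 1L, window, polyorder),
      SD = savgol_derivative(x, 2L, window, polyorder),
      SNV = snv(x))
  }
  out <- block
  if (name != "RAW") {
    for (op in strsplit(name, "-")[[1]]) out <- step(out, op)
  }
  attr(out, "recipe") <- name
  attr(out, "role") <- attr(block, "role")
  out
}
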