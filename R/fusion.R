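#' Split samples into calibration and validation sets
#'
#' Default `"systematic"` method: samples are ranked by reference MC and
#' every `ratio + 1`-th rank (the 3rd of each block of 4 under the default
#' 3:1 ratio) goes to validation, so the validation MC range sits strictly
#' inside the calibration range and both sets span every drying stage.
#' `"random"` draws the validation set uniformly with the given seed.
#'
#' @param y Reference MC values (or a sample tibble with `mc_true`).
#' @param ratio Calibration:validation ratio (default 3).
#' @param method `"systematic"` or `"random"`.
#' @param seed Seed for the random method.
#' @return List with integer index vectors `calibration` and `validation`
#'   (disjoint, covering all samples).
#' @export
#' @examples
#' sp <- split_calibration_validation(runif(104))
#' lengths(sp)  # 78, 26
split_calibration_validation <- function(y, ratio = 3,
                                         method = c("systematic", "random"),
                                         seed = 1L) {
  method <- match.arg(method)
  if (is.data.frame(y)) y <- y$mc_true
  n <- length(y)
  if (n < 8) abort("need at least 8 samples to split")
  block <- ratio + 1
  if (method == "systematic") {
    ord <- order(y, seq_len(n))
    val_pos <- seq(ratio, n, by = block)
    val <- sort(ord[val_pos])
  } else {
    n_val <- max(2L, floor(n / block))
    val <- withr::with_seed(as.integer(seed),
                            sort(sample.int(n, n_val)))
  }
  list(calibration = setdiff(seq_len(n), val), validation = val)
}

#' Pixel-level fusion: concatenate preprocessed blocks
#'
#' Joins the preprocessed variable matrices of two or more blocks column
#' wise (samples must be identical and in the same order); labels are
#' prefixed with the block role so provenance is never lost.
#'
#' @param blocks Named list of feature blocks (names become prefixes; a
#'   block's `"role"` attribute is used when the list is unnamed).
#' @return A fused feature block (role `"fused"`).
#' @export
pixel_fusion <- function(blocks) {
  stopifnot(length(blocks) >= 2)
  roles <- names(blocks) %||% rep(NA_character_, length(blocks))
  roles <- purrr::imap_chr(blocks, function(b, i) {
    nm <- if (is.character(i) && nzchar(i)) i else attr(b, "role")
    nm %||% paste0("block", i)
  })
  ids <- lapply(blocks, function(b) {
    if (is.data.frame(b) && "sample_id" %in% names(b)) b$sample_id else NULL
  })
  ref <- ids[[1]]
  mats <- lapply(blocks, block_matrix)
  nr <- vapply(mats, nrow, integer(1))
  if (length(unique(nr)) != 1) abort("blocks have different sample counts")
  for (id in ids) {
    if (!is.null(ref) && !is.null(id) && !identical(id, ref)) {
      abort("blocks disagree on sample order")
    }
  }
  fused <- do.call(cbind, purrr::map2(mats, roles, function(m, r) {
    colnames(m) <- paste(r, colnames(m) %||% seq_len(ncol(m)), sep = "_")
    m
  }))
  out <- if (!is.null(ref)) feature_block(fused, ref, role = "fused") else fused
  out
}

#' Feature-level fusion: concatenate CARS-selected columns
#'
#' @param blocks Named list of (preprocessed) feature blocks.
#' @param selections List of the same length: `cars_result` objects or
#'   integer column-index vectors giving each block's selected variables.
#' @return A fused feature block containing only the selected columns,
#'   role-prefixed, in block order then within-block index order.
#' @export
feature_fusion <- function(blocks, selections) {
  stopifnot(length(blocks) == length(selections))
  reduced <- purrr::map2(blocks, selections, function(b, sel) {
    if (inherits(sel, "cars_result")) sel <- sel$selected
    if (length(sel) == 0) abort("empty CARS selection in a fused block")
    m <- block_matrix(b)[, sort(sel), drop = FALSE]
    if (is.data.frame(b)) {
      out <- feature_block(m, b$sample_id, role = attr(b, "role"))
      attr(out, "role") <- attr(b, "role")
      out
    } else m
  })
  pixel_fusion(setNames(reduced, names(blocks)))
}

#' Fit decision-level fusion weights
#'
#' Ordinary least squares of the calibration reference values on the
#' per-block calibration predictions plus an intercept, giving the fused
#' predictor `y = b + k1 x_spectra + k2 x_image + k3 x_enose`. If the
#' prediction vectors are collinear (rank-deficient design) a small ridge
#' penalty (1e-8) is used instead, which returns the minimum-norm exact
#' solution, with a warning.
#'
#' @param y_cal Calibration reference values.
#' @param preds_cal Named list or data frame of calibration prediction
#'   vectors (2 or 3 blocks).
#' @param ridge Ridge penalty used for the collinear fallback.
#' @return An object of class `fusion_weights`: named coefficients
#'   `b, k_<block>...`.
#' @export
decision_fusion_fit <- function(y_cal, preds_cal, ridge = 1e-8) {
  P <- as.matrix(as.data.frame(preds_cal))
  if (nrow(P) < 5) abort("need >= 5 calibration samples for decision fusion")
  if (nrow(P) != length(y_cal)) abort("prediction/reference length mismatch")
  A <- cbind(`(Intercept)` = 1, P)
  qr_A <- qr(A)
  if (qr_A$rank < ncol(A)) {
    warn("collinear block predictions; using ridge (minimum-norm) fusion weights")
    coefs <- drop(solve(crossprod(A) + ridge * diag(ncol(A)), crossprod(A, y_cal)))
  } else {
    coefs <- qr.coef(qr_A, y_cal)
  }
  names(coefs) <- c("b", paste0("k_", colnames(P)))
  structure(list(coefficients = coefs, blocks = colnames(P)),
            class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat("<fusion_weights> ")
  cat(paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fusion_weights <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' Apply decision-fusion weights to block predictions
#'
#' @param weights A [decision_fusion_fit()] result.
#' @param preds Named list or data frame of prediction vectors for the
#'   same blocks (validation or calibration).
#' @return Fused prediction vector.
#' @export
decision_fusion_apply <- function(weights, preds) {
  P <- as.matrix(as.data.frame(preds))
  if (!identical(colnames(P), weights$blocks)) {
    if (!setequal(colnames(P), weights$blocks)) {
      abort("prediction blocks do not match the fitted fusion weights")
    }
    P <- P[, weights$blocks, drop = FALSE]
  }
  drop(cbind(1, P) %*% weights$coefficients)
}

#' Explore E-nose structure with PCA and hierarchical clustering
#'
#' Autoscales the 10-sensor block, runs PCA, and cuts a Ward-linkage
#' (Euclidean) dendrogram of the autoscaled sensors at `n_clusters`
#' groups, mirroring the flavour-stage exploration of the drying study
#' (where seven drying-stage regions separate in the score space).
#'
#' @param block E-nose feature block or matrix.
#' @param n_clusters Number of clusters to cut.
#' @return Object of class `enose_explore`: `scores` tibble (sample_id,
#'   PC scores, cluster), `var_ratio`, `hclust`.
#' @export
enose_explore <- function(block, n_clusters = 7L) {
  m <- block_matrix(block)
  if (nrow(m) < n_clusters) abort("need at least n_clusters samples")
  s <- apply(m, 2, sd)
  if (all(s < 1e-12)) abort("degenerate block: all sensors constant")
  Z <- scale(m[, s > 1e-12, drop = FALSE])
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  hc <- stats::hclust(dist(Z), method = "ward.D2")
  cl <- stats::cutree(hc, k = n_clusters)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  scores <- dplyr::bind_cols(
    tibble(sample_id = ids),
    as_tibble(pc$x[, seq_len(min(4, ncol(pc$x))), drop = FALSE]),
    tibble(cluster = factor(cl))
  )
  structure(list(scores = scores,
                 var_ratio = pc$sdev^2 / sum(pc$sdev^2),
                 hclust = hc, n_clusters = n_clusters),
            class = "enose_explore")
}

#' @export
print.enose_explore <- function(x, ...) {
  cat(sprintf("<enose_explore> PC1 %.1f%%, PC2 %.1f%%; %d clusters\n",
              100 * x$var_ratio[1], 100 * x$var_ratio[2], x$n_clusters))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.enose_explore <- function(x, ...) x$scores

#' @exportS3Method ggplot2::autoplot
autoplot.enose_explore <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$cluster)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_ratio[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_ratio[2]),
      title = "E-nose PCA scores with Ward clusters")
}
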