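#' Fit a PLS1 regression by NIPALS
#'
#' Partial least squares regression of a single response on an autoscaled
#' predictor matrix (each column centered and scaled to unit sample SD;
#' the response is centered). Components are extracted by the NIPALS
#' deflation scheme; regression coefficients are back-transformed to the
#' original units, and the whole coefficient path (1..`n_components`) is
#' stored so cross-validation can score every latent-variable count from
#' one fit.
#'
#' @param X Feature-block tibble or numeric matrix (n x p).
#' @param y Numeric response, length n.
#' @param n_components Number of latent variables, `1 <= A <= min(n-1, p)`.
#' @param on_zero_var `"error"` (default) rejects zero-variance columns;
#'   `"ignore"` keeps them inert (used internally during resampling).
#' @return An object of class `plsr_fit`.
#' @export
fit_plsr <- function(X, y, n_components,
                     on_zero_var = c("error", "ignore")) {
  on_zero_var <- match.arg(on_zero_var)
  m <- block_matrix(X)
  y <- as.numeric(y)
  n <- nrow(m); p <- ncol(m)
  if (length(y) != n) abort("length(y) must equal nrow(X)")
  if (any(!is.finite(m))) abort("X contains non-finite values")
  A <- as.integer(n_components)
  if (A < 1 || A > min(n - 1, p)) {
    abort(sprintf("n_components must be in [1, min(n-1, p)] = [1, %d]",
                  min(n - 1, p)))
  }
  xm <- colMeans(m)
  xs <- apply(m, 2, sd)
  zv <- xs < 1e-12
  if (any(zv)) {
    if (on_zero_var == "error") {
      abort(paste0("zero-variance column(s): ",
                   paste(head(colnames(m)[zv] %||% which(zv), 5),
                         collapse = ", ")))
    }
    xs[zv] <- 1  # centered column is all zero; stays inert
  }
  Xd <- sweep(sweep(m, 2, xm), 2, xs, "/")
  ym <- mean(y)
  yc <- y - ym

  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  A_eff <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- crossprod(Xd, t_a) / tt
    q_a <- sum(yc * t_a) / tt
    Xd <- Xd - t_a %*% t(p_a)
    yc <- yc - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    A_eff <- a
  }
  if (A_eff == 0L) abort("response has no covariance with X")

  # coefficient path in autoscaled space: B_a = W_a (P_a' W_a)^{-1} q_a
  Bs <- matrix(0, p, A)
  for (a in seq_len(A_eff)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    Bs[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
  }
  if (A_eff < A) for (a in (A_eff + 1L):A) Bs[, a] <- Bs[, A_eff]
  coef_path <- Bs / xs
  int_path <- ym - drop(crossprod(coef_path, xm))

  labels <- colnames(m) %||% paste0("x", seq_len(p))
  structure(
    list(coefficients = setNames(coef_path[, A], labels),
         intercept = int_path[A],
         coef_path = coef_path, intercept_path = int_path,
         x_center = xm, x_scale = xs, y_center = ym,
         weights = W[, seq_len(A_eff), drop = FALSE],
         loadings = P[, seq_len(A_eff), drop = FALSE],
         scores = Tm[, seq_len(A_eff), drop = FALSE],
         y_loadings = q[seq_len(A_eff)],
         n_components = A, n_effective = A_eff,
         labels = labels, n = n),
    class = "plsr_fit"
  )
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("<plsr_fit> %d latent variable(s), %d predictors, n = %d\n",
              x$n_components, length(x$coefficients), x$n))
  invisible(x)
}

#' Predict from a fitted PLSR model
#'
#' @param object A `plsr_fit`.
#' @param newdata Feature block or matrix with the training columns;
#'   single rows are allowed.
#' @param ncomp Latent-variable count to predict with (defaults to the
#'   fitted count; any value along the stored path is allowed).
#' @param ... Unused.
#' @return Numeric vector of predictions in original response units.
#' @export
predict.plsr_fit <- function(object, newdata, ncomp = NULL, ...) {
  m <- block_matrix(newdata)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  if (ncol(m) != length(object$x_center)) {
    abort(sprintf("newdata has %d columns; model expects %d",
                  ncol(m), length(object$x_center)))
  }
  a <- ncomp %||% object$n_components
  drop(m %*% object$coef_path[, a] + object$intercept_path[a])
}

# contiguous-stratified CV folds: samples are sorted by the response and
# fold labels are dealt within each consecutive group of k, so every fold
# spans the full moisture range (no drying-stage leakage)
.mc_folds <- function(y, k, seed = 1L) {
  n <- length(y)
  if (k < 2 || k > n) abort("cv_folds must be in [2, n]")
  ord <- order(y, seq_len(n))
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    for (start in seq(1, n, by = k)) {
      idx <- ord[start:min(start + k - 1, n)]
      fold[idx] <- sample(k)[seq_along(idx)]
    }
  })
  fold
}

#' Cross-validated RMSE over a latent-variable path
#'
#' @param X Feature block or matrix.
#' @param y Response.
#' @param max_lv Largest latent-variable count to score.
#' @param cv_folds Number of folds (contiguous-stratified by `y`).
#' @param seed Fold-assignment seed.
#' @return Numeric vector of RMSECV for 1..`max_lv` components.
#' @export
plsr_rmsecv <- function(X, y, max_lv = 10L, cv_folds = 5L, seed = 1L) {
  m <- block_matrix(X)
  n <- nrow(m)
  fold <- .mc_folds(y, cv_folds, seed)
  sse <- numeric(max_lv)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    A <- min(max_lv, sum(tr) - 1L, ncol(m))
    fit <- fit_plsr(m[tr, , drop = FALSE], y[tr], A, on_zero_var = "ignore")
    pred <- m[!tr, , drop = FALSE] %*% fit$coef_path +
      matrix(fit$intercept_path, sum(!tr), A, byrow = TRUE)
    if (A < max_lv) {
      pred <- cbind(pred, matrix(pred[, A], sum(!tr), max_lv - A))
    }
    sse <- sse + colSums((pred - y[!tr])^2)
  }
  sqrt(sse / n)
}

#' Choose the latent-variable count by cross-validation
#'
#' Scores 1..`max_lv` components by contiguous-stratified k-fold RMSECV
#' and returns the minimizer; ties break toward fewer components.
#'
#' @inheritParams plsr_rmsecv
#' @return Integer LV count with the RMSECV path attached as the
#'   `"rmsecv"` attribute.
#' @export
choose_lvs <- function(X, y, max_lv = 10L, cv_folds = 5L, seed = 1L) {
  max_lv <- min(max_lv, nrow(block_matrix(X)) - 1L, ncol(block_matrix(X)))
  r <- plsr_rmsecv(X, y, max_lv, cv_folds, seed)
  structure(which.min(r), rmsecv = r)
}

#' Calibration/validation evaluation report
#'
#' The standard chemometric summary of a regression model:
#' `R^2 = 1 - SS_res / SS_tot` and RMSE on both sets, and the residual
#' predictive deviation `RPD = SD(y_val) / RMSEV` (sample SD). A perfect
#' validation fit reports `RPD = Inf`.
#'
#' @param y_cal,yhat_cal Reference and predicted values, calibration set.
#' @param y_val,yhat_val Reference and predicted values, validation set
#'   (>= 2 samples).
#' @param model,recipe Labels carried into the report row.
#' @param n_vars,lvs Variable and latent-variable counts for the row.
#' @return One-row tibble: `model`, `recipe`, `n_vars`, `lvs`, `r2_cal`,
#'   `rmsec`, `r2_val`, `rmsev`, `rpd`.
#' @export
evaluate_predictions <- function(y_cal, yhat_cal, y_val, yhat_val,
                                 model = "", recipe = "RAW",
                                 n_vars = NA_integer_, lvs = NA_integer_) {
  stopifnot(length(y_cal) == length(yhat_cal),
            length(y_val) == length(yhat_val))
  if (length(y_val) < 2) abort("need >= 2 validation samples")
  stat <- function(y, yh) {
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot < 1e-24) abort("response has zero variance; R^2 undefined")
    c(r2 = 1 - sum((y - yh)^2) / ss_tot,
      rmse = sqrt(mean((y - yh)^2)))
  }
  cal <- stat(y_cal, yhat_cal)
  val <- stat(y_val, yhat_val)
  rpd <- if (val["rmse"] == 0) Inf else sd(y_val) / val[["rmse"]]
  tibble(model = model, recipe = recipe,
         n_vars = as.integer(n_vars), lvs = as.integer(lvs),
         r2_cal = cal[["r2"]], rmsec = cal[["rmse"]],
         r2_val = val[["r2"]], rmsev = val[["rmse"]], rpd = rpd)
}

#' @exportS3Method generics::tidy
tidy.plsr_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", x$labels),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @exportS3Method generics::glance
glance.plsr_fit <- function(x, ...) {
  tibble(n = x$n, n_vars = length(x$coefficients),
         lvs = x$n_components, lvs_effective = x$n_effective)
}
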