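#' Competitive adaptive reweighted sampling variable selection
#'
#' The canonical CARS loop for picking informative variables before PLSR
#' modeling. At each of `n_runs` Monte Carlo runs it (1) fits a PLSR model
#' (latent variables chosen by cross-validation, capped at `max_lv`) on a
#' random `mc_fraction` subset of the samples using the currently retained
#' variables, (2) turns the absolute regression coefficients into
#' normalized weights, (3) applies the exponentially decreasing function
#' so run i keeps `ceiling(p * exp(-k (i - 1)))` variables (all p at run
#' 1, two at the last run), enforced by (4) a weighted draw without
#' replacement (variables with zero weight are never retained), then (5)
#' records the cross-validated RMSE of a PLSR on the retained set over all
#' samples. The winning run minimizes RMSECV; ties break toward fewer
#' variables, then the earlier run.
#'
#' @param X Feature block or matrix of candidate variables (p >= 2).
#' @param y Moisture-content response.
#' @param n_runs Number of Monte Carlo runs.
#' @param cv_folds Folds for RMSECV scoring.
#' @param mc_fraction Fraction of samples drawn at each run.
#' @param max_lv Latent-variable ceiling.
#' @param seed Seed for all sampling in the loop.
#' @return An object of class `cars_result`: `selected` (sorted column
#'   indices of the winning run), `labels`, `runs` (tibble of run,
#'   n_retained, rmsecv), `best_run`, `sets` (retained indices per run),
#'   and the call settings.
#' @export
cars_select <- function(X, y, n_runs = 50L, cv_folds = 5L,
                        mc_fraction = 0.8, max_lv = 10L, seed = 1L) {
  m <- block_matrix(X)
  n <- nrow(m); p <- ncol(m)
  if (p < 2) abort("CARS needs at least 2 candidate variables")
  if (sd(y) < 1e-12) abort("degenerate response: zero variance")
  if (n < cv_folds) abort("need n_samples >= cv_folds")
  zv <- apply(m, 2, sd) < 1e-12
  if (any(zv)) {
    abort(paste0("zero-variance candidate column(s): ",
                 paste(head(which(zv), 5), collapse = ", ")))
  }
  labels <- colnames(m) %||% paste0("x", seq_len(p))
  k_edf <- log(p / 2) / (n_runs - 1)
  # small epsilon guards the ceiling against floating-point overshoot
  target <- pmax(2L, as.integer(
    ceiling(p * exp(-k_edf * (seq_len(n_runs) - 1)) - 1e-9)))

  sets <- vector("list", n_runs)
  rmsecv <- numeric(n_runs)
  retained <- integer(n_runs)
  current <- seq_len(p)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n_runs)) {
      sub <- sort(sample.int(n, max(cv_folds + 1L, round(mc_fraction * n))))
      Xi <- m[sub, current, drop = FALSE]
      lv <- choose_lvs(Xi, y[sub], max_lv = max_lv, cv_folds = cv_folds,
                       seed = sample.int(.Machine$integer.max - 1L, 1))
      fit <- fit_plsr(Xi, y[sub], as.integer(lv), on_zero_var = "ignore")
      w <- abs(fit$coefficients)
      w <- w / sum(w)
      keep_n <- min(target[i], length(current), sum(w > 0))
      keep_n <- max(keep_n, 1L)
      current <- sort(current[sample.int(length(current), keep_n,
                                         prob = w, replace = FALSE)])
      sets[[i]] <- current
      retained[i] <- length(current)
      cv <- plsr_rmsecv(m[, current, drop = FALSE], y,
                        max_lv = min(max_lv, length(current), n - 1L),
                        cv_folds = cv_folds,
                        seed = sample.int(.Machine$integer.max - 1L, 1))
      rmsecv[i] <- min(cv)
    }
  })
  ord <- order(rmsecv, retained, seq_len(n_runs))
  best <- ord[1]
  structure(
    list(selected = sets[[best]], labels = labels[sets[[best]]],
         runs = tibble(run = seq_len(n_runs), n_retained = retained,
                       rmsecv = rmsecv),
         best_run = best, sets = sets,
         settings = list(n_runs = n_runs, cv_folds = cv_folds,
                         mc_fraction = mc_fraction, max_lv = max_lv,
                         seed = as.integer(seed)),
         all_labels = labels),
    class = "cars_result"
  )
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf("<cars_result> %d/%d variables selected at run %d (RMSECV %.4g)\n",
              length(x$selected), length(x$all_labels), x$best_run,
              x$runs$rmsecv[x$best_run]))
  invisible(x)
}

#' Diagnostics table of a CARS run
#'
#' One row per Monte Carlo run with the retained-variable count and the
#' cross-validated RMSE, ready for plotting.
#'
#' @param x A `cars_result`.
#' @param ... Unused.
#' @return Tibble with columns `run`, `n_retained`, `rmsecv`, `best`.
#' @exportS3Method generics::tidy
tidy.cars_result <- function(x, ...) {
  dplyr::mutate(x$runs, best = .data$run == x$best_run)
}

#' @exportS3Method generics::glance
glance.cars_result <- function(x, ...) {
  tibble(n_selected = length(x$selected), best_run = x$best_run,
         rmsecv = x$runs$rmsecv[x$best_run],
         n_runs = x$settings$n_runs, seed = x$settings$seed)
}

#' @exportS3Method ggplot2::autoplot
autoplot.cars_result <- function(object, ...) {
  d <- tidy(object)
  long <- tidyr::pivot_longer(d, c("n_retained", "rmsecv"),
                              names_to = "panel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$run, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_run, linetype = 2,
                        colour = "red") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          n_retained = "retained variables",
                          rmsecv = "RMSECV"))) +
    ggplot2::labs(x = "Monte Carlo run", y = NULL,
                  title = "CARS sampling path")
}
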