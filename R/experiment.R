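#' Extract the three raw feature blocks from a synthetic dataset
#'
#' For every sample: materialize its cube, black-and-white correct it,
#' segment the shrimp ROI, and compute (a) the 224-band mean ROI spectrum,
#' (b) the 26 colour/texture image variables; the 10 E-nose responses are
#' taken from the sample table. Cubes are generated one at a time and
#' discarded, so memory stays flat.
#'
#' @param dataset A [generate_dataset()] result.
#' @return List with feature blocks `spectra` (224), `image` (26),
#'   `enose` (10), the response `y` (`mc_true`), and the sample tibble.
#' @export
extract_features <- function(dataset) {
  s <- dataset$samples
  n <- nrow(s)
  res <- purrr::map(seq_len(n), function(i) {
    sim <- dataset_cube(dataset, i)
    cube <- reflectance_correct(sim$raw, sim$white, sim$black)
    mask <- segment_roi(cube)
    list(spectrum = mean_spectrum(cube, mask),
         image = image_feature_vector(cube, mask))
  })
  spectra <- feature_block(do.call(rbind, purrr::map(res, "spectrum")),
                           s$sample_id, role = "spectra")
  image <- feature_block(do.call(rbind, purrr::map(res, "image")),
                         s$sample_id, role = "image")
  list(spectra = spectra, image = image, enose = enose_block(dataset),
       y = s$mc_true, samples = s)
}

# drop columns that are constant over the calibration rows (CARS cannot
# weight them); decided from calibration statistics only
.informative_cols <- function(m, cal) {
  which(apply(m[cal, , drop = FALSE], 2, sd) > 1e-10)
}

.fit_block_model <- function(m, y, cal, val, max_lv, cv_folds, seed,
                             model, recipe) {
  lv <- as.integer(choose_lvs(m[cal, , drop = FALSE], y[cal],
                              max_lv = max_lv, cv_folds = cv_folds,
                              seed = seed))
  fit <- fit_plsr(m[cal, , drop = FALSE], y[cal], lv, on_zero_var = "ignore")
  pc <- predict(fit, m[cal, , drop = FALSE])
  pv <- predict(fit, m[val, , drop = FALSE])
  list(fit = fit, pred_cal = pc, pred_val = pv,
       row = evaluate_predictions(y[cal], pc, y[val], pv, model = model,
                                  recipe = recipe, n_vars = ncol(m),
                                  lvs = lv))
}

#' Run the multi-sensor fusion pipeline
#'
#' Executes the modeling stage on extracted feature blocks: per-block
#' preprocessing recipe, CARS selection (calibration rows only),
#' single-block PLSR feature models, and pixel-, feature- and
#' decision-level fusion for the HSI-only (spectra + image) and, when an
#' E-nose block is supplied, the full three-block combination. Every
#' fitted quantity (preprocessing is per-sample, column scaling, CARS,
#' latent-variable choice, fusion weights) depends on calibration rows
#' only.
#'
#' @param blocks Named list with feature blocks `spectra`, `image`, and
#'   optionally `enose`.
#' @param y Reference MC values (mass fraction), one per sample.
#' @param recipes Named character vector of preprocessing recipes per
#'   block; the defaults follow the study's screening conclusions
#'   (derivative-then-SNV for the optical blocks, SNV for the E-nose).
#' @param split Optional precomputed [split_calibration_validation()]
#'   result; computed systematically from `y` otherwise.
#' @param n_runs,cv_folds,mc_fraction,max_lv CARS and PLSR settings.
#' @param seed Master seed; per-block CARS seeds are derived from it.
#' @param split_method Passed to [split_calibration_validation()].
#' @return Object of class `fusion_pipeline` with `report` (one
#'   evaluation row per model variant), `cars`, `models`, `weights`,
#'   `split`, `predictions` (long tibble), and the settings.
#' @export
run_fusion_pipeline <- function(blocks, y,
                                recipes = c(spectra = "FD-SNV",
                                            image = "FD-SNV",
                                            enose = "SNV"),
                                split = NULL,
                                n_runs = 50L, cv_folds = 5L,
                                mc_fraction = 0.8, max_lv = 10L,
                                seed = 1L,
                                split_method = "systematic") {
  stopifnot(all(c("spectra", "image") %in% names(blocks)))
  use <- intersect(c("spectra", "image", "enose"), names(blocks))
  split <- split %||% split_calibration_validation(y, method = split_method,
                                                   seed = seed)
  cal <- split$calibration; val <- split$validation

  pp <- purrr::imap(blocks[use], function(b, nm) {
    apply_recipe(b, recipes[[nm]])
  })
  mats <- purrr::map(pp, block_matrix)
  mats <- purrr::map(mats, function(m) {
    m[, .informative_cols(m, cal), drop = FALSE]
  })

  cars <- purrr::imap(mats, function(m, nm) {
    cars_select(m[cal, , drop = FALSE], y[cal],
                n_runs = n_runs, cv_folds = cv_folds,
                mc_fraction = mc_fraction, max_lv = max_lv,
                seed = seed + 1000L * match(nm, use))
  })

  rows <- list(); models <- list(); preds <- list()
  add <- function(label, res) {
    rows[[label]] <<- res$row
    models[[label]] <<- res$fit
    preds[[label]] <<- list(cal = res$pred_cal, val = res$pred_val)
  }

  for (nm in use) {
    sel <- cars[[nm]]$selected
    res <- .fit_block_model(mats[[nm]][, sel, drop = FALSE], y, cal, val,
                            max_lv, cv_folds, seed,
                            model = paste0(nm, "_feature"),
                            recipe = recipes[[nm]])
    res$row$n_vars <- length(sel)
    add(paste0(nm, "_feature"), res)
  }

  weights <- list()
  fuse_set <- function(members, tag) {
    fused_pp <- pixel_fusion(pp[members])
    add(paste0(tag, "_pixel"),
        .fit_block_model(block_matrix(fused_pp), y, cal, val, max_lv,
                         cv_folds, seed, paste0(tag, "_pixel"), "mixed"))
    fused_feat <- do.call(cbind, purrr::map(members, function(nm) {
      m <- mats[[nm]][, cars[[nm]]$selected, drop = FALSE]
      colnames(m) <- paste(nm, colnames(m), sep = "_")
      m
    }))
    add(paste0(tag, "_feature"),
        .fit_block_model(fused_feat, y, cal, val, max_lv, cv_folds, seed,
                         paste0(tag, "_feature"), "mixed"))
    pc <- purrr::map(members, function(nm) preds[[paste0(nm, "_feature")]]$cal)
    pv <- purrr::map(members, function(nm) preds[[paste0(nm, "_feature")]]$val)
    names(pc) <- names(pv) <- members
    w <- decision_fusion_fit(y[cal], pc)
    weights[[tag]] <<- w
    fc <- decision_fusion_apply(w, pc)
    fv <- decision_fusion_apply(w, pv)
    lab <- paste0(tag, "_decision")
    rows[[lab]] <<- evaluate_predictions(
      y[cal], fc, y[val], fv, model = lab, recipe = "decision",
      n_vars = length(members), lvs = NA_integer_)
    preds[[lab]] <<- list(cal = fc, val = fv)
  }

  fuse_set(c("spectra", "image"), "hsi")
  if ("enose" %in% use) fuse_set(use, "full")

  pred_long <- purrr::imap(preds, function(p, lab) {
    dplyr::bind_rows(
      tibble(model = lab, set = "calibration", index = cal,
             observed = y[cal], predicted = p$cal),
      tibble(model = lab, set = "validation", index = val,
             observed = y[val], predicted = p$val))
  })
  structure(
    list(report = dplyr::bind_rows(rows), cars = cars, models = models,
         weights = weights, split = split,
         predictions = dplyr::bind_rows(pred_long),
         recipes = recipes[use],
         settings = list(n_runs = n_runs, cv_folds = cv_folds,
                         mc_fraction = mc_fraction, max_lv = max_lv,
                         seed = as.integer(seed),
                         split_method = split_method)),
    class = "fusion_pipeline"
  )
}

#' @export
print.fusion_pipeline <- function(x, ...) {
  cat(sprintf("<fusion_pipeline> %d model variants, %d cal / %d val samples\n",
              nrow(x$report), length(x$split$calibration),
              length(x$split$validation)))
  print(x$report)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fusion_pipeline <- function(x, ...) x$report

#' @exportS3Method generics::glance
glance.fusion_pipeline <- function(x, ...) {
  best <- x$report[which.max(x$report$rpd), ]
  tibble(n_models = nrow(x$report), best_model = best$model,
         best_r2_val = best$r2_val, best_rpd = best$rpd,
         seed = x$settings$seed)
}

#' @exportS3Method ggplot2::autoplot
autoplot.fusion_pipeline <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted,
                               colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "reference MC (mass fraction)",
                  y = "predicted MC", title = "Observed vs predicted MC")
}

#' Screen preprocessing recipes for one block
#'
#' The Table-style recipe comparison: fits a PLSR model on the full block
#' under each named recipe (LVs by cross-validation on the calibration
#' set) and reports the evaluation row for each.
#'
#' @param block A feature block.
#' @param y Reference MC values.
#' @param split A [split_calibration_validation()] result (computed from
#'   `y` if omitted).
#' @param recipes Recipe names to screen.
#' @param max_lv,cv_folds,seed PLSR settings.
#' @param model Label for the report rows (defaults to the block role).
#' @return Tibble with one evaluation row per recipe.
#' @export
screen_recipes <- function(block, y, split = NULL,
                           recipes = c("RAW", "FD-SNV", "SD-SNV", "SNV",
                                       "SNV-FD", "SNV-SD"),
                           max_lv = 10L, cv_folds = 5L, seed = 1L,
                           model = NULL) {
  model <- model %||% attr(block, "role") %||% "block"
  split <- split %||% split_calibration_validation(y)
  cal <- split$calibration; val <- split$validation
  purrr::map_dfr(recipes, function(rc) {
    m <- block_matrix(apply_recipe(block, rc))
    keep <- .informative_cols(m, cal)
    res <- .fit_block_model(m[, keep, drop = FALSE], y, cal, val,
                            max_lv, cv_folds, seed, model, rc)
    res$row$n_vars <- ncol(block_matrix(block))
    res$row
  })
}

#' Experiment configuration
#'
#' Bundles every knob of the end-to-end experiment; defaults reproduce
#' the study design (13 stages x 8 replicates, 224 bands, 10 sensors,
#' six screening recipes, CARS with 50 runs, PLSR with up to 10 LVs,
#' systematic 3:1 split).
#'
#' @param design,curve,cube,enose Component specs.
#' @param recipes Per-block modeling recipes for the fusion stage.
#' @param screening_recipes Recipes screened per block.
#' @param n_runs,cv_folds,mc_fraction,max_lv CARS / PLSR settings.
#' @param split_method Split method.
#' @param seed Master seed.
#' @param screening Run the recipe-screening grid?
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(design = drying_design(),
                              curve = drying_curve_params(),
                              cube = cube_spec(),
                              enose = enose_spec(),
                              recipes = c(spectra = "FD-SNV",
                                          image = "FD-SNV",
                                          enose = "SNV"),
                              screening_recipes = c("RAW", "FD-SNV",
                                                    "SD-SNV", "SNV",
                                                    "SNV-FD", "SNV-SD"),
                              n_runs = 50L, cv_folds = 5L,
                              mc_fraction = 0.8, max_lv = 10L,
                              split_method = "systematic",
                              seed = 1L, screening = TRUE) {
  structure(as.list(environment()), class = "experiment_config")
}

#' Run the full drying-prediction experiment
#'
#' Generates (or accepts) a dataset, extracts the three feature blocks,
#' optionally screens the six preprocessing recipes per block, then runs
#' the complete fusion pipeline. The returned report holds one row per
#' configured model variant; the manifest records every seed and
#' hyperparameter.
#'
#' @param config An [experiment_config()].
#' @param dataset Optional pre-generated [generate_dataset()] result; by
#'   default one is generated from `config`.
#' @param features Optional pre-extracted [extract_features()] result.
#' @return Object of class `experiment_report` with `report` (screening +
#'   fusion rows), `pipeline`, `screening`, `manifest`.
#' @export
run_full_experiment <- function(config = experiment_config(),
                                dataset = NULL, features = NULL) {
  dataset <- dataset %||% generate_dataset(config$design, config$curve,
                                           config$cube, config$enose,
                                           seed = config$seed)
  features <- features %||% extract_features(dataset)
  split <- split_calibration_validation(features$y,
                                        method = config$split_method,
                                        seed = config$seed)
  screening <- NULL
  if (isTRUE(config$screening)) {
    screening <- purrr::map_dfr(
      c("spectra", "image", "enose"),
      function(nm) screen_recipes(features[[nm]], features$y, split,
                                  recipes = config$screening_recipes,
                                  max_lv = config$max_lv,
                                  cv_folds = config$cv_folds,
                                  seed = config$seed, model = nm))
  }
  pipeline <- run_fusion_pipeline(
    features[c("spectra", "image", "enose")], features$y,
    recipes = config$recipes, split = split,
    n_runs = config$n_runs, cv_folds = config$cv_folds,
    mc_fraction = config$mc_fraction, max_lv = config$max_lv,
    seed = config$seed, split_method = config$split_method)
  report <- dplyr::bind_rows(
    if (!is.null(screening)) dplyr::mutate(screening, stage = "screening"),
    dplyr::mutate(pipeline$report, stage = "fusion"))
  manifest <- list(
    seed = config$seed,
    dataset = dataset$manifest[c("seed", "design", "curve")],
    recipes = as.list(config$recipes),
    cars = list(n_runs = config$n_runs, cv_folds = config$cv_folds,
                mc_fraction = config$mc_fraction),
    plsr = list(max_lv = config$max_lv),
    split = list(method = config$split_method,
                 n_cal = length(split$calibration),
                 n_val = length(split$validation)))
  structure(list(report = report, screening = screening,
                 pipeline = pipeline, manifest = manifest,
                 config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d rows (seed %d)\n",
              nrow(x$report), x$config$seed))
  print(x$report, n = Inf)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.experiment_report <- function(x, ...) x$report

#' Write an experiment report to CSV
#'
#' Serializes the report with study-style column names (Model,
#' Pre-processing, Variables, LVs, R2c, RMSEC, R2v, RMSEV, RPD) plus the
#' YAML manifest alongside.
#'
#' @param x An `experiment_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- x$report
  names(out) <- c("Model", "Pre-processing", "Variables", "LVs",
                  "R2c", "RMSEC", "R2v", "RMSEV", "RPD", "Stage")[
                    seq_along(names(out))]
  write.csv(out, file.path(dir, "report.csv"), row.names = FALSE)
  yaml::write_yaml(x$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Spectra overlay plot
#'
#' @param block Spectral feature block (columns `wl_*`).
#' @param mc Optional MC vector for colouring.
#' @return A ggplot object.
#' @export
plot_spectra <- function(block, mc = NULL) {
  m <- block_matrix(block)
  wl <- as.numeric(sub("^wl_", "", colnames(m)))
  d <- tibble(sample = rep(seq_len(nrow(m)), each = ncol(m)),
              wavelength = rep(wl, nrow(m)),
              reflectance = as.numeric(t(m)),
              mc = if (is.null(mc)) NA_real_ else rep(mc, each = ncol(m)))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$wavelength,
                                       y = .data$reflectance,
                                       group = .data$sample))
  p <- if (is.null(mc)) p + ggplot2::geom_line(alpha = 0.4) else
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$mc), alpha = 0.6) +
      ggplot2::scale_colour_viridis_c(name = "MC")
  p + ggplot2::labs(x = "wavelength (nm)", y = "reflectance",
                    title = "Mean ROI spectra")
}
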