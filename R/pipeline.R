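# YAML-configured end-to-end driver: synthesize -> tile -> fit the selected
# models -> evaluate -> write reports, under a self-describing run directory.

run_config_defaults <- function() {
  list(
    seed = 1L,
    output_dir = tempdir(),
    log_level = "info",
    data = list(n_images = 10L, height = 64L, width = 64L, patch_size = 64L,
                test_fraction = 0.3),
    models = "threshold",
    threshold = list(a_values = seq(0, 40, 10), b_values = seq(80, 130, 10)),
    rf = list(n_trees = 25L, max_depth = 12L, n_pixels_per_image = 200L),
    net = list(profile = "desk"),
    bagging = list(n_estimators = 3L, train_fraction = 0.8),
    evaluation = list(estimator_counts = NULL, sample_sizes = NULL,
                      n_repeats = 2L)
  )
}

#' Validate a YAML run configuration
#'
#' Reads the file, rejects unknown keys, fills documented defaults, and
#' checks every field range, reporting per-field messages.
#'
#' @param path YAML file, or a list with the same structure.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) {
      stop_bagseg(sprintf("config file not found: %s", path), "bagseg_validation_error")
    }
    yaml::read_yaml(path)
  } else {
    path
  }
  defaults <- run_config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop_bagseg(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
                "bagseg_validation_error")
  }
  cfg <- modifyList(defaults, raw)
  problems <- character(0)
  if (!is.null(raw$output_dir) && !dir.exists(dirname(cfg$output_dir))) {
    problems <- c(problems, sprintf("output_dir parent does not exist: %s",
                                    dirname(cfg$output_dir)))
  }
  bad_models <- setdiff(cfg$models, c("threshold", "rf", "dcnn", "bagging"))
  if (length(bad_models) > 0) {
    problems <- c(problems, sprintf("unknown models: %s",
                                    paste(bad_models, collapse = ", ")))
  }
  if (cfg$data$n_images < 1) problems <- c(problems, "data.n_images must be >= 1")
  if (cfg$data$patch_size > min(cfg$data$height, cfg$data$width)) {
    problems <- c(problems, "data.patch_size exceeds the scene dimensions")
  }
  if (cfg$data$test_fraction <= 0 || cfg$data$test_fraction >= 1) {
    problems <- c(problems, "data.test_fraction must lie in (0, 1)")
  }
  grid <- expand.grid(a = cfg$threshold$a_values, b = cfg$threshold$b_values)
  if (!any(grid$a < grid$b)) {
    problems <- c(problems, "threshold grid has no combination with a < b")
  }
  dr <- cfg$net$dropout_rate
  if (!is.null(dr) && (dr < 0 || dr >= 1)) {
    problems <- c(problems, "net.dropout_rate must lie in [0, 1)")
  }
  if (cfg$bagging$n_estimators < 1) {
    problems <- c(problems, "bagging.n_estimators must be >= 1")
  }
  if (length(problems) > 0) {
    stop_bagseg(paste0("invalid configuration:\n  - ",
                       paste(problems, collapse = "\n  - ")),
                "bagseg_validation_error")
  }
  structure(cfg, class = "run_config")
}

pipeline_log <- function(con, level, stage, ...) {
  msg <- sprintf("level=%s stage=%s %s", level, stage,
                 paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                       collapse = " "))
  writeLines(msg, con)
}

#' Run the full pipeline
#'
#' Generates the synthetic dataset, tiles it, splits patches into a
#' train/validation pool and a held-out test set, fits the selected models
#' (`threshold`, `rf`, `dcnn`, `bagging`), evaluates everything on the
#' test set, and (optionally) computes the estimator-count and sample-size
#' curves. All artifacts - the resolved config, a structured log, reports
#' as CSV/JSON - land in a timestamped run directory; a rerun with the same
#' config and seed reproduces every deterministic artifact.
#'
#' @param config A validated `run_config` (see [validate_config()]) or a
#'   path to a YAML file.
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  run_dir <- file.path(config$output_dir,
                       format(Sys.time(), "run-%Y%m%d-%H%M%OS3"))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(run_dir, "config.yaml"))
  log_con <- file(file.path(run_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)

  pipeline_log(log_con, "info", "synth", seed = config$seed,
               n_images = config$data$n_images)
  scenes <- generate_dataset(config$data$n_images,
                             seed = derive_seed(config$seed, "data"),
                             height = config$data$height,
                             width = config$data$width)
  patches <- tile_scenes(scenes, config$data$patch_size)
  n_test <- max(1L, round(config$data$test_fraction * length(patches)))
  test_idx <- with_seed(derive_seed(config$seed, "testsplit"),
                        sample.int(length(patches), n_test))
  testset <- patches[test_idx]
  pool <- patches[-test_idx]
  if (length(pool) < 2) {
    stop_bagseg("too few patches left for training", "bagseg_validation_error")
  }
  pipeline_log(log_con, "info", "tile", pool = length(pool),
               test = length(testset))

  reports <- list()
  rows <- list()

  if ("threshold" %in% config$models) {
    t0 <- proc.time()[3]
    gs <- grid_search_hue(pool, config$threshold$a_values,
                          config$threshold$b_values)
    fit_time <- proc.time()[3] - t0
    jsonlite::write_json(
      list(best = list(a = gs$best$a, b = gs$best$b), sse_table = gs$sse_table),
      file.path(run_dir, "threshold_grid_search.json"), auto_unbox = TRUE,
      digits = NA)
    t0 <- proc.time()[3]
    rep_t <- evaluate_model(function(p) segment_by_hue(p, gs$best), testset)
    pred_time <- (proc.time()[3] - t0) / length(testset)
    reports$threshold <- rep_t
    rows$threshold <- list(model = "Threshold", train_time = sprintf("%.2fs", fit_time),
                           predict_time = sprintf("%.4fs", pred_time), report = rep_t)
    pipeline_log(log_con, "info", "threshold", a = gs$best$a, b = gs$best$b,
                 miou = sprintf("%.4f", rep_t$miou))
  }

  if ("rf" %in% config$models) {
    t0 <- proc.time()[3]
    rcfg <- rf_config(config$rf$n_trees, config$rf$max_depth,
                      config$rf$n_pixels_per_image,
                      seed = derive_seed(config$seed, "rf"))
    train_rows <- sample_training_pixels(pool, rcfg$n_pixels_per_image,
                                         seed = rcfg$seed)
    rf <- train_rf(train_rows, rcfg)
    fit_time <- proc.time()[3] - t0
    t0 <- proc.time()[3]
    rep_rf <- evaluate_model(function(p) predict_patch_rf(rf, p), testset)
    pred_time <- (proc.time()[3] - t0) / length(testset)
    reports$rf <- rep_rf
    rows$rf <- list(model = "RF", train_time = sprintf("%.2fs", fit_time),
                    predict_time = sprintf("%.4fs", pred_time), report = rep_rf)
    pipeline_log(log_con, "info", "rf", miou = sprintf("%.4f", rep_rf$miou))
  }

  net_args <- config$net
  net_args$seed <- derive_seed(config$seed, "net")
  ncfg <- do.call(net_config, net_args)

  estimator <- NULL
  if ("dcnn" %in% config$models) {
    split <- make_splits(pool, bag_spec(1L, config$bagging$train_fraction,
                                        split_seed = derive_seed(config$seed, "dl"),
                                        estimator_config = ncfg))[[1]]
    t0 <- proc.time()[3]
    estimator <- train_estimator(split$train, split$validation, ncfg)
    fit_time <- proc.time()[3] - t0
    t0 <- proc.time()[3]
    rep_dl <- evaluate_model(function(p) predict_patch(estimator, p)$mask, testset)
    pred_time <- (proc.time()[3] - t0) / length(testset)
    reports$dcnn <- rep_dl
    rows$dcnn <- list(model = "DCNN", train_time = sprintf("%.2fs", fit_time),
                      predict_time = sprintf("%.4fs", pred_time), report = rep_dl)
    pipeline_log(log_con, "info", "dcnn",
                 best_val = sprintf("%.4f", estimator$best_val_loss),
                 miou = sprintf("%.4f", rep_dl$miou))
  }

  if ("bagging" %in% config$models) {
    spec <- bag_spec(config$bagging$n_estimators, config$bagging$train_fraction,
                     split_seed = derive_seed(config$seed, "bag"),
                     estimator_config = ncfg)
    t0 <- proc.time()[3]
    ensemble <- train_ensemble(pool, spec)
    fit_time <- proc.time()[3] - t0
    t0 <- proc.time()[3]
    rep_bag <- evaluate_model(function(p) ensemble_predict(ensemble, p), testset)
    pred_time <- (proc.time()[3] - t0) / length(testset)
    reports$bagging <- rep_bag
    rows$bagging <- list(model = "DCNN (bagging)",
                         train_time = sprintf("%.2fs", fit_time),
                         predict_time = sprintf("%.4fs", pred_time),
                         report = rep_bag)
    pipeline_log(log_con, "info", "bagging", miou = sprintf("%.4f", rep_bag$miou))
    counts <- config$evaluation$estimator_counts
    if (!is.null(counts)) {
      curve <- estimator_curve(ensemble, testset, counts)
      write.csv(as_tibble(curve), file.path(run_dir, "estimator_curve.csv"),
                row.names = FALSE)
    }
  }

  sizes <- config$evaluation$sample_sizes
  if (!is.null(sizes)) {
    curve <- sample_size_study(pool, sizes, config$evaluation$n_repeats,
                               testset, base_config = ncfg,
                               master_seed = derive_seed(config$seed, "sss"))
    write.csv(as_tibble(curve), file.path(run_dir, "sample_size_curve.csv"),
              row.names = FALSE)
  }

  jsonlite::write_json(
    lapply(reports, function(r) list(iou_per_class = r$iou_per_class,
                                     miou = r$miou)),
    file.path(run_dir, "reports.json"), auto_unbox = TRUE, digits = NA)
  if (length(rows) > 0) {
    writeLines(report_table(unname(rows)), file.path(run_dir, "table.txt"))
  }
  pipeline_log(log_con, "info", "done", dir = run_dir)
  invisible(run_dir)
}
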