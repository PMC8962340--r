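# One YAML config drives the full workflow: simulate (or load) -> correct ->
# ROI selection -> preprocess -> kidney-level split -> LOOCV over the
# training grid -> final retrain -> held-out test report. Every artifact of a
# run lands in one write-once output directory together with the config hash
# and a log.

#' Read and validate a pipeline configuration
#'
#' See the package vignette for the full key reference. Validation happens
#' here, before any compute: invalid parameters (e.g. an overlap fraction
#' above 1) fail immediately.
#'
#' @param path YAML file, or a list already parsed.
#' @return Validated config list of class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  dflt <- function(x, d) if (is.null(x)) d else x

  cfg$seed <- as.integer(dflt(cfg$seed, 0L))
  cfg$data_origin <- dflt(cfg$data_origin, "absorbance")
  if (!cfg$data_origin %in% c("absorbance", "reflectance")) {
    stop("config: data_origin must be 'absorbance' or 'reflectance'", call. = FALSE)
  }
  if (is.null(cfg$out_dir)) stop("config: out_dir is required", call. = FALSE)

  sc <- dflt(cfg$scene, list())
  cfg$scene <- scene_spec(
    width = dflt(sc$width, 480L), height = dflt(sc$height, 360L),
    wl_from = dflt(sc$wl_from, 500), wl_to = dflt(sc$wl_to, 995),
    wl_step = dflt(sc$wl_step, 5), time_points = dflt(sc$time_points, 14L),
    roi_size = dflt(sc$roi_size, 50L),
    highlight_count = dflt(sc$highlight_count, 3L),
    highlight_radius = dflt(sc$highlight_radius, 4L),
    drift_scale = dflt(sc$drift_scale, 0.02))

  ds <- dflt(cfg$dataset, list())
  cfg$dataset <- list(
    n_per_class = as.integer(dflt(ds$n_per_class, c(4L, 10L, 12L))),
    test_fraction = dflt(ds$test_fraction, 0.25),
    separation = dflt(ds$separation, 1),
    intra_sd = dflt(ds$intra_sd, 0.02),
    pixel_sd = dflt(ds$pixel_sd, 0.01))
  if (length(cfg$dataset$n_per_class) != 3L || any(cfg$dataset$n_per_class < 1L)) {
    stop("config: dataset.n_per_class must be 3 positive counts", call. = FALSE)
  }
  if (cfg$dataset$test_fraction <= 0 || cfg$dataset$test_fraction >= 1) {
    stop("config: dataset.test_fraction must lie in (0, 1)", call. = FALSE)
  }

  roi <- dflt(cfg$roi, list())
  cfg$roi <- list(
    n_per_region = as.integer(dflt(roi$n_per_region, 4L)),
    max_overlap = dflt(roi$max_overlap, 0.5),
    stride = as.integer(dflt(roi$stride, 1L)),
    isosbestic_nm = dflt(roi$isosbestic_nm, 805),
    wl_lo = dflt(roi$wl_lo, 550), wl_hi = dflt(roi$wl_hi, 995))
  if (cfg$roi$max_overlap <= 0 || cfg$roi$max_overlap > 1) {
    stop("config: roi.max_overlap must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$roi$n_per_region < 1L || cfg$roi$stride < 1L) {
    stop("config: roi.n_per_region and roi.stride must be >= 1", call. = FALSE)
  }

  pp <- dflt(cfg$preprocess, list())
  cfg$preprocess <- list(savgol_window = as.integer(dflt(pp$savgol_window, 9L)),
                         savgol_order = as.integer(dflt(pp$savgol_order, 3L)))
  if (cfg$preprocess$savgol_window %% 2L != 1L ||
      cfg$preprocess$savgol_order >= cfg$preprocess$savgol_window) {
    stop("config: preprocess.savgol_window must be odd and > savgol_order", call. = FALSE)
  }

  tr <- dflt(cfg$train, list())
  grid_raw <- dflt(tr$grid, list(list(dropout_rate = 0, weight_decay = 0, lr_decay = 0)))
  cfg$train <- list(
    base_lr = dflt(tr$base_lr, 1e-3), batch_size = as.integer(dflt(tr$batch_size, 32L)),
    max_epochs = as.integer(dflt(tr$max_epochs, 30L)),
    patience = as.integer(dflt(tr$patience, 5L)),
    block_channels = as.integer(dflt(tr$block_channels, c(64L, 128L, 256L, 512L))))
  cfg$grid <- lapply(grid_raw, function(g) {
    ag <- dflt(g$augment, list())
    train_config(
      data_origin = cfg$data_origin,
      dropout_rate = dflt(g$dropout_rate, 0),
      weight_decay = dflt(g$weight_decay, 0),
      lr_decay = dflt(g$lr_decay, 0),
      base_lr = cfg$train$base_lr, batch_size = cfg$train$batch_size,
      max_epochs = cfg$train$max_epochs, patience = cfg$train$patience,
      seed = cfg$seed,
      augment = augment_config(
        rotations = dflt(ag$rotations, numeric(0)),
        gaussian_3sigma = dflt(ag$gaussian_3sigma, 0),
        occlusion_fraction = dflt(ag$occlusion_fraction, 0)),
      block_channels = cfg$train$block_channels)
  })
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full classification pipeline from one config
#'
#' Executes simulate -> correct -> ROI selection -> preprocess -> stratified
#' kidney split -> LOOCV over the configuration grid -> final retrain at the
#' median stopping epoch -> held-out test report. All artifacts are written
#' into the config's `out_dir`, which must not already hold a run (outputs
#' are write-once); re-running the same config and seed in a fresh directory
#' reproduces the same numbers.
#'
#' @param config Path to a YAML config or a [read_pipeline_config()] result.
#' @return The [run_experiment()] report, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  out <- cfg$out_dir
  if (file.exists(file.path(out, "metrics.json"))) {
    stop("out_dir already contains a run (outputs are write-once): ", out, call. = FALSE)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    cat(line, "\n", file = log_file, append = TRUE, sep = "")
    message(line)
  }

  cfg_yaml <- file.path(out, "config.yaml")
  yaml::write_yaml(lapply(unclass(cfg)[c("seed", "data_origin", "dataset",
                                         "roi", "preprocess", "train")],
                          unclass), cfg_yaml)
  cfg_hash <- unname(tools::md5sum(cfg_yaml))
  logf("config hash %s, seed %d, R %s", cfg_hash, cfg$seed,
       paste(R.version$major, R.version$minor, sep = "."))

  logf("generating %s kidneys (scene %dx%d px, %d bands, %d time points)",
       paste(cfg$dataset$n_per_class, collapse = "/"),
       cfg$scene$width, cfg$scene$height, length(cfg$scene$wavelengths),
       cfg$scene$time_points)
  template <- class_templates(cfg$scene$wavelengths,
                              separation = cfg$dataset$separation,
                              intra_sd = cfg$dataset$intra_sd,
                              pixel_sd = cfg$dataset$pixel_sd)
  dataset <- withCallingHandlers(
    generate_dataset(cfg$dataset$n_per_class, template, cfg$scene,
                     seed = cfg$seed,
                     data_origin = cfg$data_origin,
                     wl_lo = cfg$roi$wl_lo, wl_hi = cfg$roi$wl_hi,
                     roi_size = cfg$scene$roi_size,
                     n_per_region = cfg$roi$n_per_region,
                     max_overlap = cfg$roi$max_overlap, stride = cfg$roi$stride,
                     isosbestic_nm = cfg$roi$isosbestic_nm,
                     savgol_window = cfg$preprocess$savgol_window,
                     savgol_order = cfg$preprocess$savgol_order),
    warning = function(w) { logf("warning: %s", conditionMessage(w))
                            invokeRestart("muffleWarning") })

  rois <- do.call(rbind, lapply(dataset$kidneys, function(k) {
    do.call(rbind, lapply(k$samples, function(s) data.frame(
      kidney = k$id, timepoint = s$time_point, region = s$region,
      x0 = s$x0, y0 = s$y0, k = s$k, l = s$l, H = s$H,
      stringsAsFactors = FALSE)))
  }))
  utils::write.csv(rois, file.path(out, "rois.csv"), row.names = FALSE)
  logf("extracted %d ROI samples from %d kidneys", nrow(rois), length(dataset$ids))

  dataset <- stratified_split(dataset, cfg$dataset$test_fraction, seed = cfg$seed)
  logf("split: %d trainval / %d test kidneys",
       sum(dataset$split == "trainval"), sum(dataset$split == "test"))

  logf("cross-validating %d configuration(s)", length(cfg$grid))
  report <- run_experiment(dataset, cfg$grid)
  utils::write.csv(report$grid_results, file.path(out, "grid_results.csv"),
                   row.names = FALSE)

  per_kidney <- report$validation$kidneys
  per_kidney$split <- "trainval"
  if (!is.null(report$test)) {
    tk <- report$test$kidneys
    tk$split <- "test"
    per_kidney <- rbind(per_kidney, tk)
  }
  per_kidney <- per_kidney[order(-per_kidney$reliability), ]
  utils::write.csv(per_kidney, file.path(out, "per_kidney.csv"), row.names = FALSE)

  metrics <- list(
    config_hash = cfg_hash,
    seed = cfg$seed,
    best_config = report$best,
    validation = list(
      mean_accuracy = report$validation$mean_val_accuracy,
      median_stopping_epoch = report$validation$median_stopping_epoch,
      roi_confusion = report$validation$roi_metrics$confusion,
      kidney_accuracy = report$validation$kidney_metrics$accuracy),
    test = if (is.null(report$test)) NULL else list(
      roi_accuracy = report$test$roi_metrics$accuracy,
      roi_precision = report$test$roi_metrics$precision,
      roi_recall = report$test$roi_metrics$recall,
      roi_confusion = report$test$roi_metrics$confusion,
      kidney_accuracy = report$test$kidney_metrics$accuracy,
      kidney_confusion = report$test$kidney_metrics$confusion))
  jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  logf("done: metrics.json written")
  invisible(report)
}
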