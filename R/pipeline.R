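#' Configure an end-to-end pipeline run
#'
#' Collects everything one run needs: either a synthetic scene config or
#' paths to an existing image / ROI / SPAD triplet, the degradation
#' factors and approaches for the scale study, the ML methods to
#' benchmark, and the output directory. Validation happens before any
#' compute: referenced paths must exist, and the ML stage requires a SPAD
#' source.
#'
#' @param out_dir Output directory for all artifacts.
#' @param scene A [scene_config()] for synthetic input, or `NULL` when
#'   `image_path` is given.
#' @param image_path,rois_path,spad_path Paths to an existing RGB raster,
#'   ROI file (CSV/GeoJSON) and SPAD CSV; ignored when `scene` is given.
#' @param factors Degradation factors for the scale study.
#' @param approaches Approaches to run (subset of `1:3`).
#' @param ids Index ids (default all 18).
#' @param ml_methods ML methods to cross-validate (subset of
#'   `c("RF", "SVM", "BP")`); empty vector disables the ML stage.
#' @param cv_folds,train_frac Evaluation protocol for the ML stage.
#' @param map_method Method used for the per-pixel chlorophyll map, or
#'   `NULL` to skip the map.
#' @param seed Master seed; stage seeds derive from it.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, scene = scene_config(),
                            image_path = NULL, rois_path = NULL,
                            spad_path = NULL,
                            factors = uav_altitudes()$factor,
                            approaches = 1:3, ids = vi_ids(),
                            ml_methods = c("RF", "SVM", "BP"),
                            cv_folds = 10L, train_frac = 0.7,
                            map_method = "RF", seed = 20190908L) {
  cfg <- list(out_dir = out_dir, scene = scene, image_path = image_path,
              rois_path = rois_path, spad_path = spad_path,
              factors = as.integer(factors),
              approaches = as.integer(approaches), ids = ids,
              ml_methods = ml_methods, cv_folds = as.integer(cv_folds),
              train_frac = train_frac, map_method = map_method,
              seed = as.integer(seed))
  if (is.null(scene)) {
    for (p in c(image_path, rois_path)) {
      if (is.null(p) || !file.exists(p))
        stop("input path missing or nonexistent: ",
             if (is.null(p)) "(NULL)" else p, call. = FALSE)
    }
    if (length(ml_methods) && (is.null(spad_path) || !file.exists(spad_path)))
      stop("ML stage enabled but no SPAD path given", call. = FALSE)
    if (!is.null(spad_path) && !file.exists(spad_path))
      stop("SPAD path does not exist: ", spad_path, call. = FALSE)
  } else if (!inherits(scene, "scene_config")) {
    stop("'scene' must be a scene_config or NULL", call. = FALSE)
  }
  if (!all(cfg$approaches %in% 1:3))
    stop("'approaches' must be a subset of 1:3", call. = FALSE)
  if (length(ml_methods) && !all(ml_methods %in% c("RF", "SVM", "BP")))
    stop("unknown ML method in 'ml_methods'", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains every stage on one scene: (optional) synthetic-scene
#' generation, ExG - ExR masking with accuracy bookkeeping, the
#' multi-factor three-approach scale study, ML benchmarking (70/30 split
#' plus k-fold cross-validation per method), and a per-pixel chlorophyll
#' map. All tables are written as CSV, summaries as JSON, rasters as
#' PNG/TIFF, and a machine-readable run report (config echo, seed,
#' package version, artifact paths, headline numbers) as
#' `report.json`. Reruns with the same config and seed reproduce the
#' same outputs.
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  report <- list(package = "uavchl",
                 version = as.character(packageVersion("uavchl")),
                 seed = config$seed)

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$scene)) {
    scene <- generate_scene(config$scene)
    spad_readings <- sample_spad(scene$truth, seed = config$seed)
    spad <- spad_plot_means(spad_readings)
    artifacts$scene <- as.list(write_scene(scene, file.path(config$out_dir,
                                                            "scene"),
                                           spad = spad_readings))
    image <- scene$image
    rois <- scene$rois
    labels <- scene$truth$labels
  } else {
    image <- read_rgb_image(config$image_path)
    rois <- read_rois(config$rois_path)
    spad <- if (!is.null(config$spad_path)) read_spad(config$spad_path)
            else NULL
    labels <- NULL
  }

  # --- segmentation -------------------------------------------------------
  norm <- normalize_rgb(image)
  mask <- green_mask(norm)
  mask_path <- file.path(config$out_dir, "mask.png")
  write_mask(mask, mask_path)
  artifacts$mask <- mask_path
  report$mask <- list(green_px = sum(mask == 1L),
                      total_px = length(mask))
  if (!is.null(labels))
    report$mask$accuracy <- mask_accuracy(mask, labels)

  # --- scale study --------------------------------------------------------
  if (!is.null(spad) && length(config$factors)) {
    study <- scale_study(image, rois, spad, factors = config$factors,
                         approaches = config$approaches, ids = config$ids)
    artifacts$scale <- as.list(write_scale_study(
      study, file.path(config$out_dir, "scale")))
    summ <- scale_summary(study)
    summ_path <- file.path(config$out_dir, "scale", "summary.json")
    jsonlite::write_json(lapply(unclass(summ), function(s)
      list(peak_factor = as.list(s$peak_factor),
           peak_percent = as.list(s$peak_percent),
           mean_r2 = as.list(s$mean_r2))),
      summ_path, auto_unbox = TRUE, digits = 10)
    artifacts$scale_summary <- summ_path
    report$scale <- lapply(unclass(summ), function(s) s$mean_r2)
  }

  # --- ML stage -----------------------------------------------------------
  if (!is.null(spad) && length(config$ml_methods)) {
    tbl <- run_approach(image, rois, spad, approach = 2L,
                        ids = config$ids)
    tbl_path <- file.path(config$out_dir, "plot_features.csv")
    write.csv(tbl, tbl_path, row.names = FALSE)
    artifacts$features <- tbl_path
    tbl_ok <- tbl[!tbl$flagged, , drop = FALSE]
    split <- split_train_test(tbl_ok, frac = config$train_frac,
                              seed = config$seed)
    ml <- list()
    for (m in config$ml_methods) {
      spec <- ml_spec(m, seed = config$seed)
      fitted <- fit_model(spec, split$train)
      holdout <- evaluate(predict(fitted, split$test), split$test$spad)
      cv <- cross_validate(spec, tbl_ok, k = config$cv_folds,
                           seed = config$seed)
      ml[[m]] <- list(holdout = unclass(holdout)[c("R2", "RMSE", "MAE",
                                                   "within15", "n")],
                      cv = unclass(cv$pooled)[c("R2", "RMSE", "MAE",
                                                "within15", "n")])
    }
    ml_path <- file.path(config$out_dir, "ml_metrics.json")
    jsonlite::write_json(ml, ml_path, auto_unbox = TRUE, digits = 10)
    artifacts$ml_metrics <- ml_path
    report$ml <- lapply(ml, function(x) x$cv$RMSE)

    if (!is.null(config$map_method)) {
      spec <- ml_spec(config$map_method, seed = config$seed)
      full_fit <- fit_model(spec, tbl_ok)
      rasters <- compute_all_indices(norm, config$ids)
      cmap <- predict_map(full_fit, rasters, mask)
      map_path <- file.path(config$out_dir, "chlorophyll_map.tif")
      rng <- range(cmap, na.rm = TRUE)
      scaled <- (cmap - rng[1]) / max(rng[2] - rng[1], 1e-12)
      scaled[is.na(scaled)] <- 0
      tiff::writeTIFF(scaled, map_path, bits.per.sample = 16L)
      jsonlite::write_json(list(value_min = rng[1], value_max = rng[2],
                                method = config$map_method),
                           paste0(map_path, ".aux.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts$map <- map_path
      report$map <- list(method = config$map_method,
                         defined_px = sum(!is.na(cmap)),
                         mean_chl = mean(cmap, na.rm = TRUE))
    }
  }

  cfg_out <- rapply(unclass(config), function(x) x, how = "replace")
  cfg_out$scene <- if (!is.null(config$scene)) unclass(config$scene)
  report$config <- cfg_out
  report$artifacts <- artifacts
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  invisible(report)
}
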