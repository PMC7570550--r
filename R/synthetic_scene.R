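#' Configure a synthetic field scene
#'
#' Describes a gridded trial of rectangular plots on a soil background,
#' where each plot's true chlorophyll (SPAD scale) linearly drives the
#' green chromaticity of its canopy pixels. Vegetation within a plot is
#' placed as a contiguous blob (seeded randomized region growth) so that
#' coarsening the image produces realistic vegetation/soil edge mixing.
#'
#' Chromaticity model: a vegetation pixel in a plot with chlorophyll `chl`
#' has expected normalized green `G = greenness_intercept +
#' greenness_slope * chl`; the residual `1 - G` is split between red and
#' blue by `veg_rb_split` (fraction going to red). Soil chromaticity is
#' drawn around `soil_color_mean` (red-dominant by default). Chromaticities
#' are scaled by a brightness (DN sum) and quantized to 8-bit DN.
#'
#' @param n_plots Number of plots (default 20, a 4 x 5 grid).
#' @param plot_rows,plot_cols Grid layout; `plot_rows * plot_cols` must
#'   equal `n_plots`.
#' @param plot_size_px Side length of each square plot, pixels.
#' @param gap_px Soil gap between and around plots, pixels.
#' @param chlorophyll_range Length-2 numeric, min/max true SPAD-scale
#'   chlorophyll; plots receive evenly spaced values in shuffled order.
#' @param chlorophyll_values Optional explicit per-plot chlorophyll values
#'   (length `n_plots`, assigned to plots in order, no shuffling);
#'   overrides `chlorophyll_range`. Needed when other per-plot settings
#'   (e.g. a `canopy_fraction` vector) must be aligned with chlorophyll,
#'   as in soil-confounded scenes.
#' @param canopy_fraction Fraction of each plot's pixels that are
#'   vegetation, in \[0,1\]; scalar or one value per plot.
#' @param greenness_slope,greenness_intercept Affine map from chlorophyll
#'   to canopy green chromaticity.
#' @param pixel_noise_sd Per-pixel chromatic noise (sd of the noise added
#'   to the green chromaticity and to the red/blue split).
#' @param soil_color_mean Length-3 soil chromaticity mean (sums to 1).
#' @param soil_color_sd Per-channel sd of soil chromatic noise.
#' @param veg_rb_split Fraction of non-green vegetation chromaticity
#'   assigned to red.
#' @param veg_brightness,soil_brightness Expected DN sum (r+g+b) of
#'   vegetation and soil pixels.
#' @param image_height,image_width Optional fixed canvas size in pixels;
#'   if given, the plot layout must fit inside it.
#' @param seed Random seed; every stochastic operation in the package takes
#'   an explicit seed (default 20190908).
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(n_plots = 20L, plot_rows = 4L, plot_cols = 5L,
                         plot_size_px = 48L, gap_px = 12L,
                         chlorophyll_range = c(25, 55),
                         chlorophyll_values = NULL,
                         canopy_fraction = 0.7,
                         greenness_slope = 0.003,
                         greenness_intercept = 0.30,
                         pixel_noise_sd = 0.01,
                         soil_color_mean = c(0.42, 0.33, 0.25),
                         soil_color_sd = 0.015,
                         veg_rb_split = 0.45,
                         veg_brightness = 360,
                         soil_brightness = 450,
                         image_height = NULL, image_width = NULL,
                         seed = 20190908L) {
  cfg <- list(n_plots = as.integer(n_plots), plot_rows = as.integer(plot_rows),
              plot_cols = as.integer(plot_cols),
              plot_size_px = as.integer(plot_size_px),
              gap_px = as.integer(gap_px),
              chlorophyll_range = as.numeric(chlorophyll_range),
              chlorophyll_values = if (!is.null(chlorophyll_values))
                as.numeric(chlorophyll_values),
              canopy_fraction = as.numeric(canopy_fraction),
              greenness_slope = greenness_slope,
              greenness_intercept = greenness_intercept,
              pixel_noise_sd = pixel_noise_sd,
              soil_color_mean = as.numeric(soil_color_mean),
              soil_color_sd = soil_color_sd,
              veg_rb_split = veg_rb_split,
              veg_brightness = veg_brightness,
              soil_brightness = soil_brightness,
              image_height = image_height, image_width = image_width,
              seed = as.integer(seed))
  if (cfg$n_plots != cfg$plot_rows * cfg$plot_cols)
    stop("n_plots must equal plot_rows * plot_cols", call. = FALSE)
  if (!length(cfg$canopy_fraction) %in% c(1L, cfg$n_plots))
    stop("canopy_fraction must be a scalar or one value per plot",
         call. = FALSE)
  if (any(cfg$canopy_fraction < 0 | cfg$canopy_fraction > 1))
    stop("canopy_fraction must lie in [0, 1]", call. = FALSE)
  if (length(cfg$chlorophyll_range) != 2L ||
      diff(cfg$chlorophyll_range) < 0)
    stop("chlorophyll_range must be c(min, max) with min <= max",
         call. = FALSE)
  if (!is.null(cfg$chlorophyll_values) &&
      length(cfg$chlorophyll_values) != cfg$n_plots)
    stop("chlorophyll_values must have one value per plot", call. = FALSE)
  if (length(cfg$soil_color_mean) != 3L ||
      abs(sum(cfg$soil_color_mean) - 1) > 1e-6)
    stop("soil_color_mean must be a chromaticity triple summing to 1",
         call. = FALSE)
  if (cfg$pixel_noise_sd < 0 || cfg$soil_color_sd < 0)
    stop("noise standard deviations must be non-negative", call. = FALSE)
  cfg$layout_height <- cfg$plot_rows * cfg$plot_size_px +
    (cfg$plot_rows + 1L) * cfg$gap_px
  cfg$layout_width <- cfg$plot_cols * cfg$plot_size_px +
    (cfg$plot_cols + 1L) * cfg$gap_px
  if (!is.null(cfg$image_height) &&
      (cfg$image_height < cfg$layout_height ||
       cfg$image_width < cfg$layout_width))
    stop("plot layout exceeds image bounds", call. = FALSE)
  structure(cfg, class = "scene_config")
}

# Contiguous vegetation blob of exactly `target` cells grown from the plot
# centre by randomized region growth. Returns a logical nr x nc matrix.
grow_blob <- function(nr, nc, target) {
  lab <- matrix(FALSE, nr, nc)
  if (target <= 0L) return(lab)
  target <- min(target, nr * nc)
  seen <- matrix(FALSE, nr, nc)
  start <- c((nr + 1L) %/% 2L, (nc + 1L) %/% 2L)
  frontier <- matrix(start, ncol = 2L)
  seen[start[1], start[2]] <- TRUE
  placed <- 0L
  while (placed < target && nrow(frontier) > 0L) {
    pick <- sample.int(nrow(frontier), 1L)
    cell <- frontier[pick, ]
    frontier <- frontier[-pick, , drop = FALSE]
    lab[cell[1], cell[2]] <- TRUE
    placed <- placed + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      nb <- cell + d
      if (nb[1] >= 1L && nb[1] <= nr && nb[2] >= 1L && nb[2] <= nc &&
          !seen[nb[1], nb[2]]) {
        seen[nb[1], nb[2]] <- TRUE
        frontier <- rbind(frontier, nb)
      }
    }
  }
  lab
}

#' Generate a synthetic field mosaic with ground truth
#'
#' Renders the scene described by a [scene_config()]: a soil background with
#' `n_plots` rectangular plots, each containing a contiguous canopy blob
#' whose green chromaticity encodes the plot's true chlorophyll. Output is
#' deterministic given the config (which includes the seed).
#'
#' @param config A [scene_config()].
#' @return A list of class `uav_scene` with elements:
#'   \describe{
#'     \item{image}{the [rgb_image()] mosaic}
#'     \item{rois}{data frame of plot ROIs (`plot_id`, `x0`, `y0`, `x1`,
#'       `y1`; 0-based half-open pixel rectangles, x = column, y = row)}
#'     \item{truth}{ground truth: `$plots` (per-plot `plot_id`,
#'       `true_chlorophyll`) and `$labels` (integer matrix, 1 = vegetation,
#'       0 = soil, covering the whole image)}
#'     \item{config}{the config used}
#'   }
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  cfg <- config
  with_seed(cfg$seed, {
    H <- if (is.null(cfg$image_height)) cfg$layout_height else cfg$image_height
    W <- if (is.null(cfg$image_width)) cfg$layout_width else cfg$image_width
    npx <- H * W

    # soil background everywhere: chromatic noise around the soil mean,
    # renormalized to a valid chromaticity
    sR <- clamp(cfg$soil_color_mean[1] + rnorm(npx, 0, cfg$soil_color_sd),
                0.01, 0.98)
    sG <- clamp(cfg$soil_color_mean[2] + rnorm(npx, 0, cfg$soil_color_sd),
                0.01, 0.98)
    sB <- clamp(cfg$soil_color_mean[3] + rnorm(npx, 0, cfg$soil_color_sd),
                0.01, 0.98)
    ssum <- sR + sG + sB
    chR <- matrix(sR / ssum, H, W)
    chG <- matrix(sG / ssum, H, W)
    chB <- matrix(sB / ssum, H, W)
    bright <- matrix(cfg$soil_brightness, H, W)
    labels <- matrix(0L, H, W)

    chl <- if (!is.null(cfg$chlorophyll_values)) cfg$chlorophyll_values
           else {
      v <- seq(cfg$chlorophyll_range[1], cfg$chlorophyll_range[2],
               length.out = cfg$n_plots)
      v[sample.int(cfg$n_plots)]
    }
    frac <- rep_len(cfg$canopy_fraction, cfg$n_plots)

    ps <- cfg$plot_size_px; gap <- cfg$gap_px
    rois <- data.frame(plot_id = integer(0), x0 = integer(0), y0 = integer(0),
                       x1 = integer(0), y1 = integer(0))
    pid <- 0L
    for (pr in seq_len(cfg$plot_rows)) {
      for (pc in seq_len(cfg$plot_cols)) {
        pid <- pid + 1L
        y0 <- (pr - 1L) * (ps + gap) + gap       # 0-based row offset
        x0 <- (pc - 1L) * (ps + gap) + gap       # 0-based col offset
        rois <- rbind(rois, data.frame(plot_id = pid, x0 = x0, y0 = y0,
                                       x1 = x0 + ps, y1 = y0 + ps))
        target <- as.integer(round(frac[pid] * ps * ps))
        blob <- grow_blob(ps, ps, target)
        nveg <- sum(blob)
        if (nveg > 0L) {
          rows <- (y0 + 1L):(y0 + ps); cols <- (x0 + 1L):(x0 + ps)
          idx <- which(blob)
          G <- cfg$greenness_intercept + cfg$greenness_slope * chl[pid] +
            rnorm(nveg, 0, cfg$pixel_noise_sd)
          G <- clamp(G, 0.05, 0.90)
          split <- clamp(cfg$veg_rb_split + rnorm(nveg, 0, cfg$pixel_noise_sd),
                         0.05, 0.95)
          R <- (1 - G) * split
          B <- 1 - G - R
          sub <- function(m) m[rows, cols]
          put <- function(m, v) { s <- sub(m); s[idx] <- v
                                  m[rows, cols] <- s; m }
          chR <- put(chR, R); chG <- put(chG, G); chB <- put(chB, B)
          bright <- put(bright, rep(cfg$veg_brightness, nveg))
          labels <- put(labels, rep(1L, nveg))
        }
      }
    }

    dn <- function(ch) clamp(round(ch * bright), 0, 255)
    scene <- list(image = rgb_image(dn(chR), dn(chG), dn(chB)),
                  rois = rois,
                  truth = structure(
                    list(plots = data.frame(plot_id = seq_len(cfg$n_plots),
                                            true_chlorophyll = chl),
                         labels = labels),
                    class = "scene_truth"),
                  config = cfg)
    class(scene) <- "uav_scene"
    scene
  })
}

#' @export
print.uav_scene <- function(x, ...) {
  cat(sprintf("<uav_scene> %d x %d px, %d plots, seed %d\n",
              nrow(x$image$r), ncol(x$image$r), nrow(x$rois),
              x$config$seed))
  invisible(x)
}

#' Flight altitude to ground-resolution / degradation-factor table
#'
#' Reference spatial resolutions measured for the study's five flight
#' altitudes, and the integer block-averaging factor used to emulate each
#' altitude from the finest (25 m) imagery: the ratio of each resolution to
#' the finest, rounded to an integer.
#'
#' @return Data frame with columns `altitude_m`, `resolution_m`, `factor`.
#' @export
uav_altitudes <- function() {
  res <- c(0.006, 0.018, 0.021, 0.028, 0.034)
  data.frame(altitude_m = c(25, 50, 75, 100, 125),
             resolution_m = res,
             factor = as.integer(round(res / res[1])))
}

#' Emulate a coarser flight altitude
#'
#' Degrades an image to a coarser ground sampling distance: a Gaussian
#' pre-filter (optical blur) followed by block-averaging over
#' `factor` x `factor` windows (sensor areal integration), producing the
#' mixed vegetation/soil boundary pixels that drive scale effects. If the
#' image dimensions are not divisible by `factor` the bottom/right edge is
#' cropped first (documented pad-or-crop rule: crop). `factor = 1` with
#' `blur_sd = 0` is the identity.
#'
#' @param image An [rgb_image()].
#' @param factor Integer >= 1 downsampling factor.
#' @param blur_sd Gaussian blur sd in pixels; defaults to `factor / 2`.
#' @return An [rgb_image()] of dimension `floor(dim / factor)`; pixel size
#'   in any geotransform is multiplied by `factor`.
#' @export
simulate_altitude <- function(image, factor, blur_sd = factor / 2) {
  stopifnot(inherits(image, "rgb_image"))
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      factor != round(factor))
    stop("'factor' must be a single integer >= 1", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L && blur_sd <= 0) return(image)
  nr <- nrow(image$r) %/% factor * factor
  nc <- ncol(image$r) %/% factor * factor
  if (nr < factor || nc < factor)
    stop("image smaller than one output pixel", call. = FALSE)
  ds_band <- function(m) {
    m <- gaussian_blur(m[seq_len(nr), seq_len(nc), drop = FALSE] * 1.0,
                       blur_sd)
    clamp(round(block_mean(m, factor)), 0, 255)
  }
  nodata <- block_mean(image$nodata[seq_len(nr), seq_len(nc),
                                    drop = FALSE] * 1.0, factor) > 0
  gt <- image$geotransform
  if (!is.null(gt) && "pixel_size" %in% names(gt))
    gt["pixel_size"] <- gt["pixel_size"] * factor
  rgb_image(ds_band(image$r), ds_band(image$g), ds_band(image$b),
            nodata = nodata, geotransform = gt)
}

#' Simulate SPAD meter readings over a scene
#'
#' Emulates the five-point (four corners + centre), three-repetition SPAD
#' sampling protocol: each plot receives `n_points * reps` noisy readings
#' around its true chlorophyll, and the per-plot mean of those readings is
#' the plot's measured chlorophyll.
#'
#' @param truth A `scene_truth` (from [generate_scene()]) or a data frame
#'   with columns `plot_id` and `true_chlorophyll`.
#' @param n_points Sampling points per plot (default 5).
#' @param reps Repetitions per point (default 3).
#' @param noise_sd Reading noise sd, SPAD units (default 1).
#' @param seed Random seed.
#' @return Data frame with one row per reading: `plot_id`, `reading_id`
#'   (1..`n_points*reps` within plot), `value`, and the plot's `plot_mean`
#'   repeated on each row. [spad_plot_means()] reduces it to one row per
#'   plot.
#' @export
sample_spad <- function(truth, n_points = 5L, reps = 3L, noise_sd = 1,
                        seed = 20190908L) {
  plots <- if (inherits(truth, "scene_truth")) truth$plots else truth
  if (!is.data.frame(plots) || nrow(plots) < 1L)
    stop("'truth' must contain at least one plot", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  n_points <- as.integer(n_points); reps <- as.integer(reps)
  stopifnot(n_points >= 1L, reps >= 1L)
  k <- n_points * reps
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
      vals <- plots$true_chlorophyll[i] + rnorm(k, 0, noise_sd)
      data.frame(plot_id = plots$plot_id[i], reading_id = seq_len(k),
                 value = vals, plot_mean = mean(vals))
    }))
    rownames(out) <- NULL
    out
  })
}

#' @rdname sample_spad
#' @param readings Output of [sample_spad()].
#' @return `spad_plot_means` returns a data frame with columns `plot_id`
#'   and `spad` (one row per plot).
#' @export
spad_plot_means <- function(readings) {
  out <- unique(readings[, c("plot_id", "plot_mean")])
  names(out) <- c("plot_id", "spad")
  rownames(out) <- NULL
  out
}

#' Write scene artifacts to disk
#'
#' Writes the mosaic (PNG + TIFF), ROIs (CSV of half-open rectangles and
#' GeoJSON polygons with a `plot_id` property), the SPAD table (CSV), and
#' the ground-truth labels (PNG mask + per-plot CSV) into a directory.
#'
#' @param scene A `uav_scene`.
#' @param dir Output directory (created if needed).
#' @param spad Optional readings from [sample_spad()]; generated with the
#'   scene's seed if omitted.
#' @return Named character vector of file paths, invisibly.
#' @export
write_scene <- function(scene, dir, spad = NULL) {
  stopifnot(inherits(scene, "uav_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(image_png = file.path(dir, "scene.png"),
             image_tif = file.path(dir, "scene.tif"),
             rois_csv = file.path(dir, "rois.csv"),
             rois_geojson = file.path(dir, "rois.geojson"),
             spad_csv = file.path(dir, "spad.csv"),
             labels_png = file.path(dir, "labels.png"),
             plots_csv = file.path(dir, "plots.csv"),
             config_json = file.path(dir, "scene_config.json"))
  write_rgb_image(scene$image, paths[["image_png"]])
  write_rgb_image(scene$image, paths[["image_tif"]])
  write.csv(scene$rois, paths[["rois_csv"]], row.names = FALSE)
  write_rois_geojson(scene$rois, paths[["rois_geojson"]])
  if (is.null(spad))
    spad <- sample_spad(scene$truth, seed = scene$config$seed)
  write.csv(spad, paths[["spad_csv"]], row.names = FALSE)
  png::writePNG(scene$truth$labels * 1.0, paths[["labels_png"]])
  write.csv(scene$truth$plots, paths[["plots_csv"]], row.names = FALSE)
  cfg <- scene$config
  attr(cfg, "class") <- NULL
  jsonlite::write_json(cfg, paths[["config_json"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
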