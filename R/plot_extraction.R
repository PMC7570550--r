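#' Plot regions of interest
#'
#' ROIs are axis-aligned rectangles in 0-based, half-open pixel
#' coordinates: a plot covers columns `x0 <= x < x1` and rows
#' `y0 <= y < y1`. `plot_rois()` validates a data frame of rectangles;
#' `scale_rois()` maps ROIs onto a [simulate_altitude()]-degraded grid
#' (floor on the start edge, ceiling on the end edge, so every partially
#' covered coarse pixel is included).
#'
#' @param rois Data frame with columns `plot_id`, `x0`, `y0`, `x1`, `y1`.
#' @return The validated data frame.
#' @export
plot_rois <- function(rois) {
  need <- c("plot_id", "x0", "y0", "x1", "y1")
  if (!all(need %in% names(rois)))
    stop("ROIs need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(rois$x1 <= rois$x0) || any(rois$y1 <= rois$y0))
    stop("ROIs must have positive area", call. = FALSE)
  if (anyDuplicated(rois$plot_id))
    stop("duplicate plot_id in ROIs", call. = FALSE)
  rois
}

#' @rdname plot_rois
#' @param factor Integer degradation factor.
#' @export
scale_rois <- function(rois, factor) {
  rois <- plot_rois(rois)
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  out <- rois
  out$x0 <- floor(rois$x0 / factor); out$y0 <- floor(rois$y0 / factor)
  out$x1 <- ceiling(rois$x1 / factor); out$y1 <- ceiling(rois$y1 / factor)
  out
}

#' Read and write ROI files
#'
#' CSV stores the rectangle columns directly. GeoJSON stores each ROI as a
#' polygon feature (pixel coordinates, exterior ring closed) with a
#' `plot_id` property; on read, polygon bounding boxes are converted back
#' to rectangles.
#'
#' @param path File path (`.csv` or `.geojson`/`.json`).
#' @return `read_rois` returns a validated ROI data frame.
#' @export
read_rois <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(plot_rois(read.csv(path)))
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    data.frame(plot_id = f$properties$plot_id,
               x0 = min(xs), y0 = min(ys), x1 = max(xs), y1 = max(ys))
  })
  plot_rois(do.call(rbind, rows))
}

#' @rdname read_rois
#' @param rois ROI data frame.
#' @export
write_rois_geojson <- function(rois, path) {
  rois <- plot_rois(rois)
  features <- lapply(seq_len(nrow(rois)), function(i) {
    r <- rois[i, ]
    ring <- list(c(r$x0, r$y0), c(r$x1, r$y0), c(r$x1, r$y1),
                 c(r$x0, r$y1), c(r$x0, r$y0))
    list(type = "Feature",
         properties = list(plot_id = r$plot_id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract the image subset under one ROI
#'
#' Pixel-exact crop of an [rgb_image()] or any matrix-like raster to an
#' ROI rectangle, clipped to the image bounds (an empty intersection is an
#' error). Geotransform origins are shifted accordingly.
#'
#' @param image An `rgb_image` or a matrix (index raster, mask, labels).
#' @param roi One-row ROI data frame (or list) with `x0`, `y0`, `x1`, `y1`.
#' @return The cropped object of the same kind.
#' @export
extract_subsample <- function(image, roi) {
  d <- if (inherits(image, "rgb_image")) dim(image) else dim(image)
  rows <- seq.int(max(roi$y0, 0) + 1L, min(roi$y1, d[1]))
  cols <- seq.int(max(roi$x0, 0) + 1L, min(roi$x1, d[2]))
  if (length(rows) < 1L || length(cols) < 1L || roi$y0 >= d[1] ||
      roi$x0 >= d[2])
    stop("ROI does not intersect the image", call. = FALSE)
  if (inherits(image, "rgb_image")) {
    gt <- image$geotransform
    if (!is.null(gt) && all(c("origin_x", "origin_y", "pixel_size")
                            %in% names(gt))) {
      gt["origin_x"] <- gt["origin_x"] + (cols[1] - 1L) * gt["pixel_size"]
      gt["origin_y"] <- gt["origin_y"] + (rows[1] - 1L) * gt["pixel_size"]
    }
    rgb_image(image$r[rows, cols, drop = FALSE],
              image$g[rows, cols, drop = FALSE],
              image$b[rows, cols, drop = FALSE],
              nodata = image$nodata[rows, cols, drop = FALSE],
              geotransform = gt)
  } else {
    out <- image[rows, cols, drop = FALSE]
    for (a in c("index_id", "index_name", "rule", "margin"))
      attr(out, a) <- attr(image, a)
    class(out) <- class(image)
    out
  }
}

#' Read a SPAD table from CSV
#'
#' Accepts either per-reading rows (`plot_id`, `value`, optionally
#' `reading_id`/`plot_mean`) or already-aggregated rows (`plot_id`,
#' `spad`), and reduces to one mean value per plot.
#'
#' @param path CSV path.
#' @return Data frame with columns `plot_id`, `spad`.
#' @export
read_spad <- function(path) {
  df <- read.csv(path)
  if (all(c("plot_id", "spad") %in% names(df)))
    return(df[, c("plot_id", "spad")])
  if (!all(c("plot_id", "value") %in% names(df)))
    stop("SPAD CSV needs (plot_id, spad) or (plot_id, value) columns",
         call. = FALSE)
  out <- aggregate(value ~ plot_id, df, mean)
  names(out) <- c("plot_id", "spad")
  out
}

#' Aggregate index rasters to a per-plot feature table
#'
#' For each plot ROI, averages every index raster over the pixels that are
#' vegetation (`mask == 1`) and defined, counts green and total pixels,
#' and joins the plot's measured SPAD value. Plots with zero qualifying
#' pixels are kept but flagged (`flagged = TRUE`); downstream regressions
#' drop flagged rows by default. A plot missing from the SPAD table is an
#' error.
#'
#' @param rasters Named list of `index_raster` matrices (shared
#'   dimensions), e.g. from [compute_all_indices()].
#' @param mask A `veg_mask` of the same dimensions (use
#'   [full_mask()] for the all-pixels mode that ignores segmentation).
#' @param rois ROI data frame ([plot_rois()]).
#' @param spad Data frame with `plot_id` and `spad` (see
#'   [spad_plot_means()] / [read_spad()]); or `NULL` to omit the column.
#' @param stat `"mean"` (default) or `"median"` plot statistic.
#' @return Data frame of class `plot_features`: one row per plot with
#'   columns `plot_id`, `green_px`, `total_px`, `flagged`, `spad`, then
#'   one column per index (named by acronym).
#' @export
aggregate_plot_features <- function(rasters, mask, rois, spad = NULL,
                                    stat = c("mean", "median")) {
  stat <- match.arg(stat)
  rois <- plot_rois(rois)
  stopifnot(length(rasters) >= 1L)
  d <- dim(rasters[[1]])
  for (r in rasters) if (!identical(dim(r), d))
    stop("index rasters must share dimensions", call. = FALSE)
  if (!identical(dim(mask), d))
    stop("mask dimensions differ from rasters", call. = FALSE)
  agg <- if (stat == "mean") mean else stats::median
  rows <- lapply(seq_len(nrow(rois)), function(i) {
    roi <- rois[i, ]
    msub <- extract_subsample(mask, roi)
    keep <- msub == 1L
    vals <- lapply(rasters, function(r) {
      v <- extract_subsample(r, roi)[keep]
      v <- v[!is.na(v)]
      if (length(v)) agg(v) else NA_real_
    })
    out <- data.frame(plot_id = roi$plot_id, green_px = sum(keep),
                      total_px = length(msub),
                      flagged = sum(keep) == 0L)
    cbind(out, as.data.frame(vals))
  })
  tbl <- do.call(rbind, rows)
  if (!is.null(spad)) {
    if (!all(tbl$plot_id %in% spad$plot_id))
      stop("SPAD table missing plots: ",
           paste(setdiff(tbl$plot_id, spad$plot_id), collapse = ", "),
           call. = FALSE)
    tbl$spad <- spad$spad[match(tbl$plot_id, spad$plot_id)]
    tbl <- tbl[, c("plot_id", "green_px", "total_px", "flagged", "spad",
                   names(rasters))]
  }
  rownames(tbl) <- NULL
  class(tbl) <- c("plot_features", "data.frame")
  tbl
}

#' All-pixels mask
#'
#' A `veg_mask` of ones, selecting every pixel: the "no segmentation"
#' mode in which plot features are averaged over all defined pixels.
#'
#' @param dims Length-2 integer (rows, cols), or an object with a `dim`.
#' @return A `veg_mask` of ones.
#' @export
full_mask <- function(dims) {
  if (!is.numeric(dims)) dims <- dim(dims)
  structure(matrix(1L, dims[1], dims[2]),
            class = "veg_mask", rule = "all_pixels", margin = -Inf)
}
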