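#' Ordinary least-squares fit of SPAD on a plot-level index
#'
#' Simple linear regression of measured chlorophyll on a vegetation index,
#' reporting the Pearson correlation `r` and its square as the coefficient
#' of determination (`R2 = r^2`, so it is sign-blind and invariant to
#' affine rescaling of either variable). Degenerate inputs (fewer than 3
#' points, or zero variance in x or y) are an error, never a silent 0.
#'
#' @param x Numeric vector of per-plot index means.
#' @param y Numeric vector of per-plot SPAD values, same length.
#' @return List of class `linear_fit`: `slope`, `intercept`, `r`, `R2`,
#'   `n`.
#' @examples
#' fit_linear(1:5, 2 * (1:5) + 1)   # slope 2, intercept 1, R2 1
#' @export
fit_linear <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || length(y) != n)
    stop("linear fit needs >= 3 complete (x, y) pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate fit: zero variance in x or y", call. = FALSE)
  fit <- lm(y ~ x)
  r <- cor(x, y)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = r, R2 = r^2, n = n),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope %.4g, intercept %.4g, R2 %.4f (n = %d)\n",
              x$slope, x$intercept, x$R2, x$n))
  invisible(x)
}

#' Run one feature-extraction approach over a scene
#'
#' The three ways plot features are extracted before regression against
#' SPAD:
#' \describe{
#'   \item{1}{RGB chromaticity indices over *all* plot pixels (background
#'     included);}
#'   \item{2}{RGB chromaticity indices over ExG - ExR green pixels only;}
#'   \item{3}{indices evaluated on HSV channels (positional substitution),
#'     over the same ExG - ExR green pixels.}
#' }
#' The identical ROI set is used for every approach.
#'
#' @param image An [rgb_image()].
#' @param rois ROI data frame.
#' @param spad Per-plot SPAD data frame (`plot_id`, `spad`), or `NULL`.
#' @param approach 1, 2 or 3.
#' @param ids Index ids to compute (default: all 18).
#' @param registry A [vi_registry()].
#' @param margin Segmentation margin for [green_mask()].
#' @param stat Plot aggregation statistic.
#' @return A `plot_features` table (see [aggregate_plot_features()]).
#' @export
run_approach <- function(image, rois, spad = NULL, approach = 2L,
                         ids = vi_ids(registry), registry = vi_registry(),
                         margin = 0, stat = "mean") {
  if (!approach %in% 1:3)
    stop("'approach' must be 1, 2 or 3", call. = FALSE)
  norm <- normalize_rgb(image)
  mask <- if (approach == 1L) full_mask(dim(image))
          else green_mask(norm, margin)
  channels <- if (approach == 3L) rgb_to_hsv_image(image) else norm
  rasters <- compute_all_indices(channels, ids, registry)
  aggregate_plot_features(rasters, mask, rois, spad, stat = stat)
}

#' Index-SPAD regressions across degradation factors and approaches
#'
#' The full scale-effect experiment on one scene: for every degradation
#' factor the image is coarsened with [simulate_altitude()], the ROIs are
#' rescaled, plot features are extracted under each requested approach,
#' and each index is regressed against SPAD. Flagged plots (zero green
#' pixels) are dropped from the fits.
#'
#' @param image An [rgb_image()] at native resolution.
#' @param rois Native-resolution ROI data frame.
#' @param spad Per-plot SPAD data frame.
#' @param factors Integer degradation factors (default: the altitude
#'   table of [uav_altitudes()]).
#' @param approaches Subset of `1:3`.
#' @param ids Index ids.
#' @param registry A [vi_registry()].
#' @param margin Segmentation margin.
#' @return List of class `scale_study`: `r2` is a 3-d array
#'   `[index, factor, approach]` of R-squared values, `n` the matching
#'   array of fit sizes, plus `factors`, `approaches`, `ids`.
#' @export
scale_study <- function(image, rois, spad, factors = uav_altitudes()$factor,
                        approaches = 1:3, ids = vi_ids(registry),
                        registry = vi_registry(), margin = 0) {
  factors <- as.integer(factors)
  acr <- vapply(ids, function(i) vi_entry(registry, i)$name, character(1))
  r2 <- array(NA_real_, c(length(ids), length(factors), length(approaches)),
              dimnames = list(acr, paste0("f", factors),
                              paste0("approach", approaches)))
  nfit <- r2
  for (fi in seq_along(factors)) {
    img_f <- simulate_altitude(image, factors[fi])
    rois_f <- scale_rois(rois, factors[fi])
    for (ai in seq_along(approaches)) {
      tbl <- run_approach(img_f, rois_f, spad, approaches[ai], ids,
                          registry, margin)
      ok <- !tbl$flagged
      for (ii in seq_along(acr)) {
        fit <- tryCatch(fit_linear(tbl[[acr[ii]]][ok], tbl$spad[ok]),
                        error = function(e) NULL)
        if (!is.null(fit)) {
          r2[ii, fi, ai] <- fit$R2
          nfit[ii, fi, ai] <- fit$n
        }
      }
    }
  }
  structure(list(r2 = r2, n = nfit, factors = factors,
                 approaches = approaches, ids = ids),
            class = "scale_study")
}

#' Summarise scale effects
#'
#' For each approach: the altitude/factor at which each index's R-squared
#' peaks (ties resolved to the smallest factor), the percentage of indices
#' peaking at each factor (summing to 100 per approach), and the
#' per-factor mean R-squared across indices. Missing cells are an error
#' listing the gaps.
#'
#' @param fits A `scale_study`, or a single `index x factor` R-squared
#'   matrix (treated as one approach).
#' @return List of class `scale_summary`, one element per approach, each
#'   with `peak_factor` (named by index), `peak_percent` (named by
#'   factor), and `mean_r2` (named by factor).
#' @export
scale_summary <- function(fits) {
  r2 <- if (inherits(fits, "scale_study")) fits$r2
        else array(fits, c(dim(fits), 1L),
                   dimnames = c(dimnames(fits), list("approach1")))
  if (anyNA(r2)) {
    gaps <- which(is.na(r2), arr.ind = TRUE)
    stop("R2 matrix has missing cells: ",
         paste(apply(gaps, 1, paste, collapse = ","), collapse = "; "),
         call. = FALSE)
  }
  out <- lapply(seq_len(dim(r2)[3]), function(ai) {
    m <- r2[, , ai, drop = FALSE][, , 1, drop = FALSE]
    dim(m) <- dim(r2)[1:2]
    dimnames(m) <- dimnames(r2)[1:2]
    peak <- apply(m, 1, which.max)            # ties -> lowest factor
    pct <- vapply(seq_len(ncol(m)), function(j) 100 * mean(peak == j),
                  numeric(1))
    names(pct) <- colnames(m)
    list(peak_factor = structure(colnames(m)[peak], names = rownames(m)),
         peak_percent = pct,
         mean_r2 = colMeans(m))
  })
  names(out) <- dimnames(r2)[[3]]
  structure(out, class = "scale_summary")
}

#' Write a scale-study R-squared matrix as CSV
#'
#' One CSV per approach, rows = factors, columns = indices (the layout of
#' the study's per-date R-squared tables).
#'
#' @param study A `scale_study`.
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_scale_study <- function(study, dir) {
  stopifnot(inherits(study, "scale_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ai in seq_along(study$approaches)) {
    m <- t(study$r2[, , ai])
    df <- data.frame(factor = study$factors, m, check.names = FALSE)
    p <- file.path(dir, sprintf("r2_approach%d.csv", study$approaches[ai]))
    write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
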