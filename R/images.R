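#' Construct an 8-bit RGB image
#'
#' The raw input of the pipeline: three integer digital-number (DN) bands in
#' \[0, 255\] plus an optional nodata mask and an optional geotransform
#' (origin and pixel size in metres) carried through cropping and
#' downsampling.
#'
#' @param r,g,b Numeric matrices of equal dimension with DN values in
#'   \[0, 255\]. Stored as integer.
#' @param nodata Optional logical matrix marking invalid pixels; defaults to
#'   all `FALSE`.
#' @param geotransform Optional named numeric vector
#'   `c(origin_x, origin_y, pixel_size)` in metres.
#' @return An object of class `rgb_image`: a list with elements `r`, `g`,
#'   `b` (integer matrices), `nodata` (logical matrix) and `geotransform`.
#' @examples
#' img <- rgb_image(matrix(10, 2, 2), matrix(200, 2, 2), matrix(30, 2, 2))
#' dim(img)
#' @export
rgb_image <- function(r, g, b, nodata = NULL, geotransform = NULL) {
  r <- as.matrix(r); g <- as.matrix(g); b <- as.matrix(b)
  if (!identical(dim(r), dim(g)) || !identical(dim(r), dim(b)))
    stop("RGB bands must share dimensions", call. = FALSE)
  for (band in list(r, g, b)) {
    if (anyNA(band) || min(band) < 0 || max(band) > 255)
      stop("DN values must lie in [0, 255] with no NA", call. = FALSE)
  }
  if (is.null(nodata)) nodata <- matrix(FALSE, nrow(r), ncol(r))
  nodata <- as.matrix(nodata)
  if (!identical(dim(nodata), dim(r)))
    stop("'nodata' must match band dimensions", call. = FALSE)
  structure(
    list(r = matrix(as.integer(round(r)), nrow(r)),
         g = matrix(as.integer(round(g)), nrow(g)),
         b = matrix(as.integer(round(b)), nrow(b)),
         nodata = matrix(as.logical(nodata), nrow(r)),
         geotransform = geotransform),
    class = "rgb_image")
}

#' @export
dim.rgb_image <- function(x) dim(x$r)

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d px, %d nodata px\n",
              nrow(x$r), ncol(x$r), sum(x$nodata)))
  invisible(x)
}

#' Read / write RGB images as PNG or TIFF
#'
#' 8-bit PNG round-trips DN exactly. TIFF is written as 8-bit 3-band; any
#' geotransform is written to a JSON sidecar (`<path>.aux.json`) and read
#' back from it when present.
#'
#' @param path File path; format chosen by extension (`.png` / `.tif(f)`).
#' @param image An `rgb_image`.
#' @return `read_rgb_image` returns an `rgb_image`; `write_rgb_image`
#'   returns `path` invisibly.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: ", ext, call. = FALSE))
  if (length(dim(a)) != 3L || dim(a)[3] < 3L)
    stop("expected a 3-band raster", call. = FALSE)
  gt <- NULL
  sidecar <- paste0(path, ".aux.json")
  if (file.exists(sidecar)) {
    aux <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(aux$geotransform)) gt <- unlist(aux$geotransform)
  }
  rgb_image(round(a[, , 1] * 255), round(a[, , 2] * 255),
            round(a[, , 3] * 255), geotransform = gt)
}

#' @rdname read_rgb_image
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  a <- array(0, c(dim(image), 3L))
  a[, , 1] <- image$r / 255; a[, , 2] <- image$g / 255; a[, , 3] <- image$b / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(a, path),
    tif = ,
    tiff = tiff::writeTIFF(a, path, bits.per.sample = 8L),
    stop("unsupported raster format: ", ext, call. = FALSE))
  if (!is.null(image$geotransform))
    jsonlite::write_json(list(geotransform = image$geotransform),
                         paste0(path, ".aux.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- low-level raster helpers (shared by simulate_altitude and masks) ------

# Separable Gaussian filter with replicate (edge-extend) padding. Kernel
# radius 3*sd so truncation error is negligible; works on matrices of any
# size including those smaller than the kernel.
gaussian_blur <- function(m, sd) {
  if (sd <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sd)))
  k <- stats::dnorm(seq(-r, r), sd = sd)
  k <- k / sum(k)
  conv_rows <- function(x) {
    n <- nrow(x)
    idx <- c(rep(1L, r), seq_len(n), rep(n, r))
    xp <- x[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k))
      out <- out + k[j] * xp[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

# Mean over non-overlapping f x f blocks; dimensions must be divisible by f.
block_mean <- function(m, f) {
  f <- as.integer(f)
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(nr %% f == 0L, nc %% f == 0L)
  rg <- (seq_len(nr) - 1L) %/% f
  cg <- (seq_len(nc) - 1L) %/% f
  m1 <- rowsum(m, rg, reorder = TRUE)
  t(rowsum(t(m1), cg, reorder = TRUE)) / (f * f)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
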