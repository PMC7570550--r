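#' Segment green vegetation with the ExG - ExR rule
#'
#' Classifies each pixel as green vegetation (1) or background (0) by
#' comparing excess green (`2G - R - B`) against excess red (`1.4R - G`)
#' on normalized chromaticities: a pixel is vegetation iff
#' `ExG - ExR > margin`. Ties and undefined pixels are background
#' (conservative soil exclusion).
#'
#' @param norm A `norm_image` from [normalize_rgb()].
#' @param margin Decision margin added to the ExG > ExR comparison
#'   (default 0, the plain rule).
#' @return Integer 0/1 matrix of class `veg_mask`, with attributes `rule`
#'   and `margin` recording provenance.
#' @examples
#' img <- rgb_image(matrix(40, 1, 1), matrix(160, 1, 1), matrix(60, 1, 1))
#' green_mask(normalize_rgb(img))[1, 1]   # 1
#' @export
green_mask <- function(norm, margin = 0) {
  stopifnot(inherits(norm, "norm_image"))
  diff <- (2 * norm$G - norm$R - norm$B) - (1.4 * norm$R - norm$G)
  m <- diff > margin
  m[is.na(m)] <- FALSE
  structure(matrix(as.integer(m), nrow(norm$G)),
            class = "veg_mask", rule = "exg_minus_exr", margin = margin)
}

#' Restrict an index raster to masked pixels
#'
#' Keeps raster values where the mask is 1 and sets every other pixel
#' undefined (`NA`).
#'
#' @param raster An `index_raster` (or plain numeric matrix).
#' @param mask A `veg_mask` (or 0/1 matrix) of identical dimensions.
#' @return The raster with non-vegetation pixels set to `NA`.
#' @export
apply_mask <- function(raster, mask) {
  if (!identical(dim(raster), dim(mask)))
    stop("raster and mask dimensions differ", call. = FALSE)
  raster[mask != 1L] <- NA_real_
  raster
}

#' Mask accuracy against ground-truth labels
#'
#' Fraction of pixels whose mask value matches the 0/1 ground-truth label.
#'
#' @param mask A `veg_mask`.
#' @param labels Integer 0/1 matrix of identical dimensions.
#' @return Accuracy in \[0, 1\].
#' @export
mask_accuracy <- function(mask, labels) {
  if (!identical(dim(mask), dim(labels)))
    stop("mask and label dimensions differ", call. = FALSE)
  mean(as.integer(mask) == as.integer(labels))
}

#' Downsample ground-truth labels to a coarser grid
#'
#' Majority rule over `factor` x `factor` blocks: a coarse cell is labeled
#' vegetation when more than half of its native pixels are vegetation
#' (exact halves resolve to soil, mirroring the segmenter's tie rule).
#' Dimensions not divisible by `factor` are cropped bottom/right, matching
#' [simulate_altitude()].
#'
#' @param labels Integer 0/1 matrix.
#' @param factor Integer >= 1.
#' @return Integer 0/1 matrix of the downsampled size.
#' @export
downsample_labels <- function(labels, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(labels)
  nr <- nrow(labels) %/% factor * factor
  nc <- ncol(labels) %/% factor * factor
  frac <- block_mean(labels[seq_len(nr), seq_len(nc), drop = FALSE] * 1.0,
                     factor)
  matrix(as.integer(frac > 0.5), nrow(frac))
}

#' Write a vegetation mask to disk
#'
#' Persists the binary crop map as a 1-band image: PNG encodes vegetation
#' as 255 and background as 0; TIFF stores 0/1.
#'
#' @param mask A `veg_mask`.
#' @param path Output path (`.png` or `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  m <- matrix(as.numeric(mask), nrow(mask))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop("unsupported mask format: ", ext, call. = FALSE))
  invisible(path)
}
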