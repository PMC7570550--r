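#' Normalize RGB digital numbers to chromatic coordinates
#'
#' Divides each band by the per-pixel band sum, `R = r/(r+g+b)` (and
#' likewise for G, B), removing overall brightness so that `R + G + B = 1`
#' at every defined pixel. Pixels with `r + g + b = 0`, and input nodata
#' pixels, are marked undefined (`NA`) rather than raising.
#'
#' @param image An [rgb_image()].
#' @return An object of class `norm_image`: list with matrices `R`, `G`,
#'   `B` (NA at undefined pixels) and logical `undefined`.
#' @examples
#' img <- rgb_image(matrix(100, 1, 1), matrix(150, 1, 1), matrix(50, 1, 1))
#' normalize_rgb(img)$G   # 0.5
#' @export
normalize_rgb <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  s <- image$r + image$g + image$b
  und <- image$nodata | s == 0L
  s[und] <- NA_real_
  structure(list(R = image$r / s, G = image$g / s, B = image$b / s,
                 undefined = und),
            class = "norm_image")
}

#' Convert an RGB image to HSV channels
#'
#' Standard hexcone hue-saturation-value transform with all three channels
#' scaled to \[0, 1\]: red at H = 0, green at H = 1/3, blue at H = 2/3;
#' S = 0 on achromatic pixels; V is the maximum of the scaled RGB
#' components. Input nodata pixels are undefined.
#'
#' @param image An [rgb_image()].
#' @return An object of class `hsv_image`: list with matrices `H`, `S`,
#'   `V` and logical `undefined`.
#' @export
rgb_to_hsv_image <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  hsv <- grDevices::rgb2hsv(as.vector(image$r), as.vector(image$g),
                            as.vector(image$b), maxColorValue = 255)
  d <- dim(image$r)
  H <- matrix(hsv["h", ], d[1], d[2])
  S <- matrix(hsv["s", ], d[1], d[2])
  V <- matrix(hsv["v", ], d[1], d[2])
  und <- image$nodata
  H[und] <- NA_real_; S[und] <- NA_real_; V[und] <- NA_real_
  structure(list(H = H, S = S, V = V, undefined = und),
            class = "hsv_image")
}

# Positional channel triple for index evaluation: (first, second, third) =
# (R, G, B) in RGB chromaticity space, (H, S, V) in HSV space.
channel_triple <- function(channels) {
  if (inherits(channels, "norm_image"))
    list(c1 = channels$R, c2 = channels$G, c3 = channels$B,
         undefined = channels$undefined)
  else if (inherits(channels, "hsv_image"))
    list(c1 = channels$H, c2 = channels$S, c3 = channels$V,
         undefined = channels$undefined)
  else stop("'channels' must be a norm_image or hsv_image", call. = FALSE)
}

# Division marking zero denominators undefined (NA), never Inf/NaN.
safe_div <- function(num, den) {
  out <- num / den
  out[which(den == 0)] <- NA_real_
  out
}

#' Registry of the 18 RGB vegetation indices
#'
#' Builds the named registry of vegetation index definitions `E1`..`E18`
#' (ExG, ExR, VDVI, ExGR, NGRDI, NGBDI, CIVE, CRRI, VEG, COM, RGRI, VARI,
#' ExB, MGRVI, WI, IKAW, GBDI, RGBVI), each a formula over the positional
#' channel triple -- normalized (R, G, B) chromaticities, or (H, S, V)
#' substituted positionally when indices are computed in HSV space.
#' Pixels where a formula's denominator vanishes are undefined.
#'
#' Two source formulas are ambiguous and carry switches:
#' \describe{
#'   \item{`exgr`}{`"standard"` (default) reads ExGR as ExG - ExR =
#'     `3G - 2.4R - B`; `"literal"` reads the printed expression
#'     left-to-right as `G - 2.4R - B`.}
#'   \item{`rgri`}{`"printed"` (default) computes `G / B`;
#'     `"ratio_rg"` uses the literature ratio `R / G`.}
#' }
#' VEG (`E9`) is `G / (R^a * B^(1-a))` with `a = 0.667`. CIVE (`E7`) uses
#' the coefficient 0.8818 on G as printed in its source table (the cited
#' literature has 0.811).
#'
#' @param exgr,rgri Formula variant switches, see Details.
#' @return A named list of class `vi_registry`; each element has `id`,
#'   `name`, and `fun(c1, c2, c3)`.
#' @export
vi_registry <- function(exgr = c("standard", "literal"),
                        rgri = c("printed", "ratio_rg")) {
  exgr <- match.arg(exgr)
  rgri <- match.arg(rgri)
  alpha <- 0.667
  exg <- function(R, G, B) 2 * G - R - B
  exr <- function(R, G, B) 1.4 * R - G
  exgr_fun <- if (exgr == "standard")
    function(R, G, B) 3 * G - 2.4 * R - B
  else
    function(R, G, B) G - 2.4 * R - B
  cive <- function(R, G, B) 0.441 * R - 0.8818 * G + 0.385 * B + 18.787
  veg <- function(R, G, B) {
    out <- G / (R^alpha * B^(1 - alpha))
    out[which(R == 0 | B == 0)] <- NA_real_
    out
  }
  defs <- list(
    E1 = list(name = "EXG", fun = exg),
    E2 = list(name = "EXR", fun = exr),
    E3 = list(name = "VDVI",
              fun = function(R, G, B) safe_div(2 * G - R - B,
                                               2 * G + R + B)),
    E4 = list(name = "EXGR", fun = exgr_fun),
    E5 = list(name = "NGRDI", fun = function(R, G, B) safe_div(G - R, G + R)),
    E6 = list(name = "NGBDI", fun = function(R, G, B) safe_div(G - B, G + B)),
    E7 = list(name = "CIVE", fun = cive),
    E8 = list(name = "CRRI", fun = function(R, G, B) safe_div(G, R)),
    E9 = list(name = "VEG", fun = veg),
    E10 = list(name = "COM",
               fun = function(R, G, B)
                 0.25 * exg(R, G, B) + 0.3 * exgr_fun(R, G, B) +
                 0.33 * cive(R, G, B) + 0.12 * veg(R, G, B)),
    E11 = list(name = "RGRI",
               fun = if (rgri == "printed")
                 function(R, G, B) safe_div(G, B)
               else function(R, G, B) safe_div(R, G)),
    E12 = list(name = "VARI",
               fun = function(R, G, B) safe_div(G - R, G + R - B)),
    E13 = list(name = "EXB", fun = function(R, G, B) 1.4 * B - G),
    E14 = list(name = "MGRVI",
               fun = function(R, G, B) safe_div(G * G - R * R,
                                                G * G + R * R)),
    E15 = list(name = "WI", fun = function(R, G, B) safe_div(G - B, R - G)),
    E16 = list(name = "IKAW",
               fun = function(R, G, B) safe_div(R - B, R + B)),
    E17 = list(name = "GBDI", fun = function(R, G, B) G - B),
    E18 = list(name = "RGBVI",
               fun = function(R, G, B) safe_div(G * G - B * R,
                                                G * G + B * R))
  )
  for (id in names(defs)) defs[[id]]$id <- id
  structure(defs, class = "vi_registry")
}

#' @rdname vi_registry
#' @param registry A `vi_registry`.
#' @return `vi_ids` returns the character vector of index ids;
#'   `vi_names` the named vector mapping id to acronym.
#' @export
vi_ids <- function(registry = vi_registry()) names(registry)

#' @rdname vi_registry
#' @export
vi_names <- function(registry = vi_registry())
  vapply(registry, `[[`, character(1), "name")

# Resolve an index id or acronym to the registry entry.
vi_entry <- function(registry, id) {
  if (id %in% names(registry)) return(registry[[id]])
  hit <- which(vi_names(registry) == id)
  if (length(hit) == 1L) return(registry[[hit]])
  stop("unknown vegetation index: '", id, "'", call. = FALSE)
}

#' Compute a vegetation index raster
#'
#' Evaluates one registry formula per pixel over a channel triple --
#' normalized RGB chromaticities or, positionally substituted, HSV
#' channels. Undefined input pixels and zero-denominator pixels yield `NA`.
#'
#' @param channels A `norm_image` or `hsv_image`.
#' @param index_id Registry id (`"E1"`..`"E18"`) or acronym (`"NGRDI"`, ...).
#' @param registry A [vi_registry()].
#' @return A numeric matrix of class `index_raster` with attributes
#'   `index_id` and `index_name`; `NA` marks undefined pixels.
#' @export
compute_index <- function(channels, index_id, registry = vi_registry()) {
  ch <- channel_triple(channels)
  entry <- vi_entry(registry, index_id)
  val <- entry$fun(ch$c1, ch$c2, ch$c3)
  val[ch$undefined] <- NA_real_
  structure(val, class = c("index_raster", class(val)),
            index_id = entry$id, index_name = entry$name)
}

#' @rdname compute_index
#' @param ids Character vector of ids/acronyms (default: all 18, in
#'   registry order). Duplicates are an error.
#' @return `compute_all_indices` returns a named list of `index_raster`
#'   matrices in the requested order, named by acronym.
#' @export
compute_all_indices <- function(channels, ids = vi_ids(registry),
                                registry = vi_registry()) {
  if (anyDuplicated(ids))
    stop("duplicate index ids requested: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  out <- lapply(ids, function(id) compute_index(channels, id, registry))
  names(out) <- vapply(out, attr, character(1), "index_name")
  out
}
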