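# Independent scalar oracle for the 18 vegetation indices: straight
# transcription of each printed formula, one pixel at a time, with NA on
# zero denominators. Kept deliberately separate from the package's
# vectorized registry.
scalar_vi <- function(id, R, G, B, exgr = "standard", rgri = "printed") {
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  a <- 0.667
  exg <- 2 * G - R - B
  exr <- 1.4 * R - G
  # standard ExGR = ExG - ExR, written in the same simplified closed form
  # the registry documents so the loop-vs-vector comparison can be exact
  exgr_v <- if (exgr == "standard") 3 * G - 2.4 * R - B else G - 2.4 * R - B
  cive <- 0.441 * R - 0.8818 * G + 0.385 * B + 18.787
  veg <- if (R == 0 || B == 0) NA_real_ else G / (R^a * B^(1 - a))
  switch(id,
    E1 = exg,
    E2 = exr,
    E3 = sdiv(2 * G - R - B, 2 * G + R + B),
    E4 = exgr_v,
    E5 = sdiv(G - R, G + R),
    E6 = sdiv(G - B, G + B),
    E7 = cive,
    E8 = sdiv(G, R),
    E9 = veg,
    E10 = 0.25 * exg + 0.3 * exgr_v + 0.33 * cive + 0.12 * veg,
    E11 = if (rgri == "printed") sdiv(G, B) else sdiv(R, G),
    E12 = sdiv(G - R, G + R - B),
    E13 = 1.4 * B - G,
    E14 = sdiv(G * G - R * R, G * G + R * R),
    E15 = sdiv(G - B, R - G),
    E16 = sdiv(R - B, R + B),
    E17 = G - B,
    E18 = sdiv(G * G - B * R, G * G + B * R),
    stop("bad id"))
}

# One-pixel (or small) rgb_image from DN vectors/matrices.
dn_image <- function(r, g, b) {
  if (is.null(dim(r))) {
    r <- matrix(r, 1); g <- matrix(g, 1); b <- matrix(b, 1)
  }
  rgb_image(r, g, b)
}

# A norm_image built directly from chromaticity matrices (R+G+B must be 1).
chrom_image <- function(R, G, B) {
  structure(list(R = R, G = G, B = B,
                 undefined = matrix(FALSE, nrow(R), ncol(R))),
            class = "norm_image")
}

# Small fast scene for structural tests: 4 plots of 12 px.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_plots = 4L, plot_rows = 2L, plot_cols = 2L,
         plot_size_px = 12L, gap_px = 4L),
    list(...))
  do.call(scene_config, args)
}

# The frozen n = 200 parameter-recovery benchmark.
bench_config <- function(...) {
  args <- utils::modifyList(
    list(n_plots = 200L, plot_rows = 10L, plot_cols = 20L,
         plot_size_px = 24L, gap_px = 6L, pixel_noise_sd = 0.015),
    list(...))
  do.call(scene_config, args)
}

# Random chromaticity matrices (rows x cols), valid triples summing to 1.
random_chrom <- function(nr, nc) {
  u <- matrix(runif(nr * nc), nr); v <- matrix(runif(nr * nc), nr)
  w <- matrix(runif(nr * nc), nr)
  s <- u + v + w
  list(R = u / s, G = v / s, B = w / s)
}
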