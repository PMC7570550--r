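test_that("scene generation is deterministic and respects the plot layout", {
  cfg <- scene_config()
  scn <- generate_scene(cfg)
  expect_equal(nrow(scn$rois), 20L)
  expect_equal(nrow(scn$truth$plots), 20L)
  expect_identical(dim(scn$image), dim(scn$truth$labels))

  again <- generate_scene(cfg)
  expect_identical(scn$image$r, again$image$r)
  expect_identical(scn$image$g, again$image$g)
  expect_identical(scn$image$b, again$image$b)
  expect_identical(scn$truth$labels, again$truth$labels)

  other <- generate_scene(scene_config(seed = 4L))
  expect_false(identical(scn$image$g, other$image$g))

  expect_error(scene_config(n_plots = 20, plot_rows = 3, plot_cols = 5),
               "rows")
  expect_error(scene_config(canopy_fraction = 1.2), "canopy_fraction")
  expect_error(scene_config(image_height = 10, image_width = 10),
               "exceeds")
})

test_that("canopy placement matches the requested fraction exactly", {
  cfg <- tiny_config(canopy_fraction = 0)
  scn <- generate_scene(cfg)
  expect_equal(sum(scn$truth$labels), 0L)

  cfg <- tiny_config(canopy_fraction = 0.6)
  scn <- generate_scene(cfg)
  npx <- cfg$plot_size_px^2
  for (i in seq_len(nrow(scn$rois))) {
    lab <- extract_subsample(scn$truth$labels, scn$rois[i, ])
    expect_equal(sum(lab), round(0.6 * npx))
  }
  # vegetation is one contiguous blob per plot (region growth)
  lab <- extract_subsample(scn$truth$labels, scn$rois[1, ])
  expect_true(sum(lab) > 0)
})

test_that("noiseless scenes inject the chlorophyll-greenness signal exactly", {
  cfg <- tiny_config(pixel_noise_sd = 0)
  scn <- generate_scene(cfg)
  norm <- normalize_rgb(scn$image)
  for (i in seq_len(nrow(scn$rois))) {
    g <- extract_subsample(norm$G, scn$rois[i, ])
    lab <- extract_subsample(scn$truth$labels, scn$rois[i, ])
    chl <- scn$truth$plots$true_chlorophyll[
      scn$truth$plots$plot_id == scn$rois$plot_id[i]]
    expected <- cfg$greenness_intercept + cfg$greenness_slope * chl
    # DN quantization at brightness 360 perturbs chromaticity < 0.005
    expect_lt(abs(mean(g[lab == 1L]) - expected), 0.005)
  }
  # soil is red-dominant on average
  soil <- scn$truth$labels == 0L
  expect_gt(mean(norm$R[soil]), mean(norm$G[soil]))
})

test_that("altitude simulation block-averages after an optional blur", {
  const <- rgb_image(matrix(37, 8, 8), matrix(120, 8, 8), matrix(55, 8, 8))
  for (f in c(1, 2, 4)) {
    out <- simulate_altitude(const, f)
    expect_true(all(out$r == 37) && all(out$g == 120) && all(out$b == 55))
  }

  m <- matrix(c(0, 40, 80, 120,
                8, 48, 88, 128,
                16, 56, 96, 136,
                24, 64, 104, 144), 4, 4, byrow = TRUE)
  img <- rgb_image(m, m, m)
  out <- simulate_altitude(img, 2, blur_sd = 0)
  expect_identical(dim(out), c(2L, 2L))
  expect_equal(out$g[1, 1], round(mean(m[1:2, 1:2])))
  expect_equal(out$g[2, 2], round(mean(m[3:4, 3:4])))

  # checkerboard of two colors averages to the uniform mixture
  chk <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  img <- rgb_image(chk * 200, chk * 100 + (1 - chk) * 60, (1 - chk) * 240)
  out <- simulate_altitude(img, 2, blur_sd = 0)
  expect_true(all(out$r == 100) && all(out$g == 80) && all(out$b == 120))

  expect_error(simulate_altitude(img, 0), "factor")
  ident <- simulate_altitude(img, 1, blur_sd = 0)
  expect_identical(ident$r, img$r)

  # non-divisible dimensions are cropped bottom/right
  img5 <- rgb_image(matrix(10, 5, 7), matrix(20, 5, 7), matrix(30, 5, 7))
  expect_identical(dim(simulate_altitude(img5, 2, blur_sd = 0)), c(2L, 3L))
})

test_that("the altitude table maps resolutions to integer factors", {
  alt <- uav_altitudes()
  expect_equal(alt$altitude_m, c(25, 50, 75, 100, 125))
  expect_equal(alt$resolution_m, c(0.006, 0.018, 0.021, 0.028, 0.034))
  expect_equal(alt$factor, c(1L, 3L, 4L, 5L, 6L))
})

test_that("SPAD sampling follows the 5-point x 3-rep protocol", {
  scn <- generate_scene(scene_config())
  spad <- sample_spad(scn$truth)
  expect_equal(nrow(spad), 20L * 15L)
  expect_true(all(table(spad$plot_id) == 15L))
  means <- spad_plot_means(spad)
  expect_equal(nrow(means), 20L)

  exact <- sample_spad(scn$truth, noise_sd = 0)
  expect_equal(exact$value,
               scn$truth$plots$true_chlorophyll[
                 match(exact$plot_id, scn$truth$plots$plot_id)])
  expect_error(sample_spad(scn$truth, noise_sd = -1), "non-negative")
  expect_equal(nrow(sample_spad(scn$truth, n_points = 3, reps = 2)),
               20L * 6L)
})

test_that("soil mixing error in all-pixel NGRDI grows with the degradation factor", {
  scn <- generate_scene(scene_config())
  norm0 <- normalize_rgb(scn$image)
  ref <- aggregate_plot_features(
    list(NGRDI = compute_index(norm0, "E5")), green_mask(norm0),
    scn$rois)$NGRDI
  dev <- vapply(c(1L, 2L, 3L, 4L, 6L), function(f) {
    img <- simulate_altitude(scn$image, f)
    tbl <- aggregate_plot_features(
      list(NGRDI = compute_index(normalize_rgb(img), "E5")),
      full_mask(dim(img)), scale_rois(scn$rois, f))
    mean(abs(tbl$NGRDI - ref))
  }, numeric(1))
  expect_true(all(diff(dev) >= 0))
})

test_that("scene artifacts round-trip through disk formats", {
  dir <- withr::local_tempdir()
  scn <- generate_scene(tiny_config())
  paths <- write_scene(scn, dir)
  expect_true(all(file.exists(paths)))

  back <- read_rgb_image(paths[["image_png"]])
  expect_identical(back$r, scn$image$r)
  expect_identical(back$g, scn$image$g)
  expect_identical(back$b, scn$image$b)

  rois <- read_rois(paths[["rois_csv"]])
  expect_equal(rois, scn$rois)
  gj <- read_rois(paths[["rois_geojson"]])
  expect_equal(gj[order(gj$plot_id), ], scn$rois, ignore_attr = TRUE)

  spad <- read_spad(paths[["spad_csv"]])
  expect_equal(nrow(spad), 4L)
})
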