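test_that("band normalization yields chromatic coordinates summing to one", {
  img <- dn_image(100, 150, 50)
  norm <- normalize_rgb(img)
  expect_equal(norm$R[1, 1], 1 / 3)
  expect_equal(norm$G[1, 1], 1 / 2)
  expect_equal(norm$B[1, 1], 1 / 6)

  pure <- normalize_rgb(dn_image(255, 0, 0))
  expect_equal(c(pure$R, pure$G, pure$B), c(1, 0, 0))

  zero <- normalize_rgb(dn_image(0, 0, 0))
  expect_true(zero$undefined[1, 1])
  expect_true(is.na(zero$R[1, 1]))

  set.seed(11)
  for (i in 1:20) {
    img <- rgb_image(matrix(sample(0:255, 64, TRUE), 8),
                     matrix(sample(0:255, 64, TRUE), 8),
                     matrix(sample(0:255, 64, TRUE), 8))
    n <- normalize_rgb(img)
    ok <- !n$undefined
    expect_true(all(abs((n$R + n$G + n$B)[ok] - 1) < 1e-9))
    expect_true(all(is.na(n$R[!ok])))
  }
})

test_that("HSV conversion honors the hexcone anchors and inverts within 1 DN", {
  expect_equal(unname(vapply(rgb_to_hsv_image(dn_image(255, 0, 0)),
                             function(m) m[1, 1], numeric(1))[1:3]),
               c(0, 1, 1))
  expect_equal(rgb_to_hsv_image(dn_image(0, 255, 0))$H[1, 1], 1 / 3)
  expect_equal(rgb_to_hsv_image(dn_image(0, 0, 255))$H[1, 1], 2 / 3)
  expect_equal(rgb_to_hsv_image(dn_image(128, 128, 128))$S[1, 1], 0)

  set.seed(7)
  img <- rgb_image(matrix(sample(0:255, 64, TRUE), 8),
                   matrix(sample(0:255, 64, TRUE), 8),
                   matrix(sample(0:255, 64, TRUE), 8))
  h <- rgb_to_hsv_image(img)
  back <- t(grDevices::col2rgb(grDevices::hsv(as.vector(h$H),
                                              as.vector(h$S),
                                              as.vector(h$V))))
  expect_true(max(abs(back[, 1] - as.vector(img$r))) <= 1)
  expect_true(max(abs(back[, 2] - as.vector(img$g))) <= 1)
  expect_true(max(abs(back[, 3] - as.vector(img$b))) <= 1)
})

test_that("the index registry holds exactly 18 distinct indices", {
  reg <- vi_registry()
  expect_length(reg, 18L)
  expect_equal(vi_ids(reg), paste0("E", 1:18))
  expect_false(anyDuplicated(vi_names(reg)) > 0)
  expect_error(compute_index(chrom_image(matrix(0.3), matrix(0.4),
                                         matrix(0.3)), "E19"),
               "unknown")
  ch <- chrom_image(matrix(0.3), matrix(0.4), matrix(0.3))
  expect_error(compute_all_indices(ch, c("E1", "E1")), "duplicate")
  expect_length(compute_all_indices(ch, character(0)), 0L)
  expect_length(compute_all_indices(ch), 18L)
})

test_that("index formulas reproduce hand-computed pixel values", {
  gray <- normalize_rgb(dn_image(85, 85, 85))
  expect_equal(compute_index(gray, "E1")[1, 1], 0)
  expect_equal(compute_index(gray, "E2")[1, 1], 0.4 / 3)
  expect_equal(compute_index(gray, "E5")[1, 1], 0)
  expect_equal(compute_index(gray, "E9")[1, 1], 1)

  green <- normalize_rgb(dn_image(0, 255, 0))
  expect_equal(compute_index(green, "E1")[1, 1], 2)
  expect_equal(compute_index(green, "E2")[1, 1], -1)
  expect_equal(compute_index(green, "E13")[1, 1], -1)

  px <- normalize_rgb(dn_image(20, 50, 30))   # chromaticity (0.2, 0.5, 0.3)
  expect_equal(compute_index(px, "E1")[1, 1], 0.5)
  expect_equal(compute_index(px, "E5")[1, 1], 0.3 / 0.7)
  expect_equal(compute_index(px, "E6")[1, 1], 0.25)
  expect_equal(compute_index(px, "E14")[1, 1], 0.21 / 0.29)

  # WI denominator vanishes when R = G
  eq <- normalize_rgb(dn_image(90, 90, 60))
  expect_true(is.na(compute_index(eq, "E15")[1, 1]))

  # formula-variant switches
  expect_equal(compute_index(px, "E4")[1, 1], 3 * 0.5 - 2.4 * 0.2 - 0.3)
  expect_equal(compute_index(px, "E4",
                             vi_registry(exgr = "literal"))[1, 1],
               0.5 - 2.4 * 0.2 - 0.3)
  expect_equal(compute_index(px, "E11")[1, 1], 0.5 / 0.3)
  expect_equal(compute_index(px, "E11",
                             vi_registry(rgri = "ratio_rg"))[1, 1],
               0.2 / 0.5)
})

test_that("vectorized index evaluation equals the per-pixel scalar oracle", {
  reg <- vi_registry()
  set.seed(42)
  for (rep in 1:100) {
    ch <- random_chrom(8, 8)
    img <- chrom_image(ch$R, ch$G, ch$B)
    for (id in vi_ids(reg)) {
      got <- compute_index(img, id, reg)
      want <- matrix(NA_real_, 8, 8)
      for (i in 1:8) for (j in 1:8)
        want[i, j] <- scalar_vi(id, ch$R[i, j], ch$G[i, j], ch$B[i, j])
      expect_equal(unclass(got), want, tolerance = 0,
                   ignore_attr = TRUE)
    }
  }
})

test_that("normalized-difference indices stay within [-1, 1] and NGRDI rises with G", {
  set.seed(99)
  for (rep in 1:25) {
    ch <- random_chrom(8, 8)
    img <- chrom_image(ch$R, ch$G, ch$B)
    for (id in c("E3", "E5", "E6", "E14", "E16", "E18")) {
      v <- compute_index(img, id)
      expect_true(all(abs(v[!is.na(v)]) <= 1 + 1e-12), label = id)
    }
    v12 <- compute_index(img, "E12")
    dom <- ch$B <= pmin(ch$R, 2 * ch$G) & !is.na(v12)
    expect_true(all(abs(v12[dom]) <= 1 + 1e-12))
  }

  R <- 0.31
  g_grid <- seq(0.05, 0.65, by = 0.05)
  ngrdi <- (g_grid - R) / (g_grid + R)
  expect_true(all(diff(ngrdi) > 0))
  got <- compute_index(chrom_image(matrix(R, 1, length(g_grid)),
                                   matrix(g_grid, 1),
                                   matrix(1 - R - g_grid, 1)), "E5")
  expect_true(all(diff(as.vector(got)) > 0))
})

test_that("undefined pixels propagate through indices and composites", {
  img <- rgb_image(matrix(c(0, 120), 1), matrix(c(0, 200), 1),
                   matrix(c(0, 40), 1))
  norm <- normalize_rgb(img)
  for (id in c("E1", "E9", "E10")) {
    v <- compute_index(norm, id)
    expect_true(is.na(v[1, 1]))
    expect_false(is.na(v[1, 2]))
  }
})
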