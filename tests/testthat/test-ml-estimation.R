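make_table <- function(n, p = 5, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(runif(n * p), n)
    colnames(x) <- paste0("V", seq_len(p))
    beta <- seq_len(p)
    data.frame(x, spad = drop(x %*% beta) + rnorm(n, 0, noise))
  })
}

test_that("train/test splitting is a deterministic exhaustive partition", {
  tbl <- make_table(20)
  sp <- split_train_test(tbl, 0.7, seed = 3)
  expect_equal(nrow(sp$train), 14L)
  expect_equal(nrow(sp$test), 6L)
  ids <- c(rownames(sp$train), rownames(sp$test))
  expect_setequal(ids, rownames(tbl))
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0L)

  again <- split_train_test(tbl, 0.7, seed = 3)
  expect_identical(sp$train, again$train)
  expect_error(split_train_test(tbl, 1.2), "frac")
  expect_error(split_train_test(tbl[1:3, ], 0.7), "4")
})

test_that("evaluation metrics match closed forms and expose the error band", {
  m <- evaluate(c(10, 20, 30), c(10, 20, 30))
  expect_equal(m$RMSE, 0)
  expect_equal(m$MAE, 0)
  expect_equal(m$R2, 1)
  expect_equal(m$within15, 1)

  off <- evaluate(c(12, 22, 32), c(10, 20, 30))
  expect_equal(off$RMSE, 2)
  expect_equal(off$MAE, 2)
  expect_equal(off$R2, 1)       # correlation-based R2 is bias-blind
  expect_lt(off$R2_ss, 1)

  g <- evaluate(c(1, 2, 3), c(3, 2, 1))
  expect_equal(g$RMSE, sqrt(8 / 3))
  expect_equal(g$MAE, 4 / 3)

  flat <- evaluate(c(1, 2, 3), c(2, 2, 2))
  expect_true(is.na(flat$R2))
  expect_equal(flat$RMSE, sqrt(2 / 3))
  expect_error(evaluate(1:3, 1:4), "length")
})

test_that("RMSE dominates MAE on arbitrary error vectors", {
  set.seed(13)
  for (rep in 1:1000) {
    n <- sample(2:30, 1)
    p <- rnorm(n); a <- rnorm(n)
    m <- evaluate(p, a)
    expect_gte(m$RMSE, m$MAE)
  }
  # equality iff all absolute errors are equal
  eq <- evaluate(c(5, 1), c(3, 3))
  expect_equal(eq$RMSE, eq$MAE)
})

test_that("all three regressors collapse to the constant on flat targets", {
  tbl <- make_table(30)
  tbl$spad <- 42
  for (m in c("RF", "SVM", "BP")) {
    fit <- fit_model(ml_spec(m), tbl)
    pred <- predict(fit, make_table(10, seed = 99))
    expect_true(all(abs(pred - 42) < 1e-6), label = m)
  }
})

test_that("fits are seed-deterministic, persistable and reject bad input", {
  tbl <- make_table(60, noise = 0.2)
  newx <- make_table(15, seed = 7)
  for (m in c("RF", "SVM", "BP")) {
    spec <- ml_spec(m, seed = 77L)
    p1 <- predict(fit_model(spec, tbl), newx)
    p2 <- predict(fit_model(spec, tbl), newx)
    expect_identical(p1, p2, label = m)

    path <- withr::local_tempfile(fileext = ".rds")
    save_model(fit_model(spec, tbl), path)
    expect_identical(predict(load_model(path), newx), p1, label = m)
  }
  bad <- tbl
  bad$V1[c(2, 5)] <- Inf
  expect_error(fit_model(ml_spec("RF"), bad), "rows: 2, 5")
})

test_that("random forests reach the noise floor on clean linear data", {
  tbl <- make_table(200, noise = 0)
  sp <- split_train_test(tbl, 0.7, seed = 2)
  fit <- fit_model(ml_spec("RF"), sp$train)
  m <- evaluate(predict(fit, sp$test), sp$test$spad)
  expect_lt(m$RMSE, sd(tbl$spad))
})

test_that("cross-validation folds partition the table evenly", {
  tbl <- make_table(20, noise = 0.5)
  cv <- cross_validate(ml_spec("RF"), tbl, k = 10, seed = 5)
  expect_equal(sort(cv$folds$n), rep(2L, 10))
  expect_equal(cv$pooled$n, 20L)
  expect_setequal(cv$predictions$row, 1:20)
  expect_true(all(table(cv$predictions$row) == 1L))

  n23 <- cross_validate(ml_spec("SVM"), make_table(23, noise = 0.5), k = 10)
  expect_lte(diff(range(n23$folds$n)), 1L)
  expect_error(cross_validate(ml_spec("RF"), tbl, k = 21), "k")
})

test_that("per-pixel maps agree with tabular predictions", {
  scn <- generate_scene(tiny_config(n_plots = 9L, plot_rows = 3L,
                                    plot_cols = 3L))
  spad <- spad_plot_means(sample_spad(scn$truth))
  tbl <- run_approach(scn$image, scn$rois, spad, approach = 2)
  fit <- fit_model(ml_spec("RF"), tbl)
  norm <- normalize_rgb(scn$image)
  rasters <- compute_all_indices(norm)
  mask <- green_mask(norm)

  empty <- predict_map(fit, rasters, full_mask(dim(scn$image)) * 0L)
  expect_true(all(is.na(empty)))

  cmap <- predict_map(fit, rasters, mask)
  expect_identical(dim(cmap), dim(scn$image))
  expect_equal(is.na(cmap)[mask == 1L],
               !stats::complete.cases(
                 vapply(rasters, function(r) as.vector(r),
                        numeric(length(mask)))[as.vector(mask == 1L), ]))

  # pointwise cross-check at 10 random green pixels
  ok <- which(mask == 1L & !is.na(cmap))
  set.seed(8)
  for (px in sample(ok, 10)) {
    feats <- as.data.frame(lapply(rasters, function(r) r[px]))
    expect_equal(cmap[px], predict(fit, feats))
  }

  expect_error(predict_map(fit, rasters[1:3], mask), "missing feature")

  # uniform image: constant prediction equal to the tabular one
  const <- rgb_image(matrix(60, 6, 6), matrix(140, 6, 6), matrix(70, 6, 6))
  cn <- normalize_rgb(const)
  cr <- compute_all_indices(cn)
  cm <- predict_map(fit, cr, green_mask(cn))
  expect_equal(length(unique(as.vector(cm))), 1L)
  expect_equal(cm[1, 1],
               predict(fit, as.data.frame(lapply(cr, function(r) r[1, 1]))))
})

test_that("grid aggregation averages the per-pixel map over blocks", {
  scn <- generate_scene(tiny_config(n_plots = 9L, plot_rows = 3L,
                                    plot_cols = 3L))
  spad <- spad_plot_means(sample_spad(scn$truth))
  tbl <- run_approach(scn$image, scn$rois, spad, approach = 2)
  fit <- fit_model(ml_spec("RF"), tbl)
  norm <- normalize_rgb(scn$image)
  rasters <- compute_all_indices(norm)
  mask <- green_mask(norm)
  fine <- predict_map(fit, rasters, mask)
  coarse <- predict_map(fit, rasters, mask, grid = 4L)
  expect_identical(dim(coarse), dim(fine) %/% 4L)
  blk <- fine[1:4, 1:4]
  expect_equal(coarse[1, 1],
               if (all(is.na(blk))) NA_real_ else mean(blk, na.rm = TRUE))
})
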