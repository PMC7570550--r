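#' Specify a chlorophyll regression model
#'
#' Declares one of the three regressors used to map 18-index feature
#' vectors to SPAD-scale chlorophyll, with its hyperparameters and seed.
#' Defaults (the study protocol leaves them open, so they are package
#' choices, all exposed here):
#' \describe{
#'   \item{BP}{single-hidden-layer backpropagation network, 10 hidden
#'     units, linear output, standardized inputs and target, weight decay
#'     `1e-4`, at most 2000 iterations;}
#'   \item{SVM}{radial-basis-kernel epsilon-regression, `cost = 10`,
#'     `epsilon = 0.1`, internally standardized inputs;}
#'   \item{RF}{random forest of 500 trees, default `mtry`.}
#' }
#'
#' @param method `"RF"`, `"SVM"` or `"BP"`.
#' @param seed Seed fixed into every fit for reproducibility.
#' @param features Character vector of feature column names, or `NULL` to
#'   use every index column present at fit time (order is then frozen
#'   into the fitted model).
#' @param hyper Named list overriding method hyperparameters (`size`,
#'   `maxit`, `decay` for BP; `cost`, `epsilon`, `gamma` for SVM;
#'   `ntree`, `mtry` for RF).
#' @return List of class `ml_spec`.
#' @export
ml_spec <- function(method = c("RF", "SVM", "BP"), seed = 20190908L,
                    features = NULL, hyper = list()) {
  method <- match.arg(method)
  defaults <- switch(method,
    BP = list(size = 10L, maxit = 2000L, decay = 1e-4),
    SVM = list(cost = 10, epsilon = 0.1, gamma = NULL),
    RF = list(ntree = 500L, mtry = NULL))
  defaults[names(hyper)] <- hyper
  structure(list(method = method, seed = as.integer(seed),
                 features = features, hyper = defaults),
            class = "ml_spec")
}

# Feature matrix in the spec's (or table's) frozen column order.
feature_matrix <- function(table, features) {
  missing <- setdiff(features, names(table))
  if (length(missing))
    stop("feature columns missing from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  as.matrix(table[, features, drop = FALSE])
}

default_features <- function(table) {
  drop <- c("plot_id", "green_px", "total_px", "flagged", "spad")
  setdiff(names(table), drop)
}

#' Split a feature table into training and test sets
#'
#' Random disjoint, exhaustive split with `round(frac * n)` training
#' rows; deterministic for a given seed.
#'
#' @param table A `plot_features` data frame (or any data frame).
#' @param frac Training fraction in (0, 1) (default 0.7).
#' @param seed Random seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(table, frac = 0.7, seed = 20190908L) {
  n <- nrow(table)
  if (n < 4L) stop("need at least 4 rows to split", call. = FALSE)
  if (!is.numeric(frac) || frac <= 0 || frac >= 1)
    stop("'frac' must lie strictly between 0 and 1", call. = FALSE)
  n_train <- as.integer(round(frac * n))
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Fit a chlorophyll regressor
#'
#' Fits the regressor described by an [ml_spec()] on a training feature
#' table (target column `spad`). Inputs are standardized with parameters
#' learned on the training data (BP explicitly; SVM internally; RF is
#' scale-equivariant). A zero-variance target degenerates every method to
#' the constant predictor, reported as such. Non-finite feature values
#' are an error naming the offending rows.
#'
#' @param spec An [ml_spec()].
#' @param train Training `plot_features` table with a `spad` column.
#' @return Object of class `chl_model` whose [predict()] method maps a
#'   feature table (or matrix) to SPAD predictions. Persist with
#'   [save_model()] / [load_model()].
#' @export
fit_model <- function(spec, train) {
  stopifnot(inherits(spec, "ml_spec"))
  features <- spec$features
  if (is.null(features)) features <- default_features(train)
  x <- feature_matrix(train, features)
  y <- train$spad
  if (is.null(y)) stop("training table lacks a 'spad' column", call. = FALSE)
  bad <- which(!stats::complete.cases(cbind(x, y)) |
                 apply(!is.finite(cbind(x, y)), 1, any))
  if (length(bad))
    stop("non-finite features/target in rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  model <- list(spec = spec, features = features, method = spec$method)
  if (sd(y) < 1e-12) {
    model$constant <- mean(y)
    class(model) <- "chl_model"
    return(model)
  }
  h <- spec$hyper
  fit <- with_seed(spec$seed, switch(spec$method,
    BP = {
      xc <- colMeans(x); xs <- apply(x, 2, sd); xs[xs == 0] <- 1
      yc <- mean(y); ys <- sd(y)
      model$x_center <- xc; model$x_scale <- xs
      model$y_center <- yc; model$y_scale <- ys
      xstd <- scale(x, xc, xs)
      nnet::nnet(xstd, (y - yc) / ys, size = h$size, linout = TRUE,
                 decay = h$decay, maxit = h$maxit, trace = FALSE)
    },
    SVM = {
      args <- list(x = x, y = y, type = "eps-regression",
                   kernel = "radial", cost = h$cost, epsilon = h$epsilon,
                   scale = TRUE)
      if (!is.null(h$gamma)) args$gamma <- h$gamma
      do.call(e1071::svm, args)
    },
    RF = {
      args <- list(x = x, y = y, ntree = h$ntree)
      if (!is.null(h$mtry)) args$mtry <- h$mtry
      do.call(randomForest::randomForest, args)
    }))
  model$fit <- fit
  class(model) <- "chl_model"
  model
}

#' @rdname fit_model
#' @param object A fitted `chl_model`.
#' @param newdata Feature table or matrix containing the model's feature
#'   columns.
#' @param ... Unused.
#' @export
predict.chl_model <- function(object, newdata, ...) {
  x <- feature_matrix(as.data.frame(newdata), object$features)
  if (!is.null(object$constant)) return(rep(object$constant, nrow(x)))
  switch(object$method,
    BP = {
      xstd <- scale(x, object$x_center, object$x_scale)
      as.vector(predict(object$fit, xstd)) * object$y_scale +
        object$y_center
    },
    SVM = as.vector(predict(object$fit, x)),
    RF = as.vector(predict(object$fit, x)))
}

#' @rdname fit_model
#' @param path File path for the persisted model.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "chl_model"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname fit_model
#' @export
load_model <- function(path) {
  object <- readRDS(path)
  stopifnot(inherits(object, "chl_model"))
  object
}

#' Evaluate predictions against measurements
#'
#' The study's three accuracy statistics plus the tolerance band:
#' `R2` is the squared Pearson correlation between predicted and measured
#' values (sign- and bias-blind; `NA` when either side has zero
#' variance), `RMSE` the root-mean-square error and `MAE` the mean
#' absolute error (both in SPAD units), `within15` the fraction of
#' predictions with `|P - M| <= 0.15 * M`. The conventional
#' `1 - SSres/SStot` is also reported as `R2_ss`.
#'
#' @param predicted,actual Equal-length numeric vectors, `n >= 2`.
#' @return List of class `eval_metrics`: `R2`, `r`, `R2_ss`, `RMSE`,
#'   `MAE`, `within15`, `n`.
#' @examples
#' evaluate(c(1, 2, 3), c(3, 2, 1))   # RMSE sqrt(8/3), MAE 4/3
#' @export
evaluate <- function(predicted, actual) {
  n <- length(actual)
  if (length(predicted) != n || n < 2L)
    stop("'predicted' and 'actual' must share length >= 2", call. = FALSE)
  err <- predicted - actual
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  if (sd(actual) == 0 || sd(predicted) == 0) {
    r <- NA_real_; r2 <- NA_real_
  } else {
    r <- cor(predicted, actual); r2 <- r^2
  }
  r2ss <- if (sd(actual) == 0) NA_real_ else
    1 - sum(err^2) / sum((actual - mean(actual))^2)
  structure(list(R2 = r2, r = r, R2_ss = r2ss, RMSE = rmse, MAE = mae,
                 within15 = mean(abs(err) <= 0.15 * actual), n = n),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "<eval_metrics> R2 %.4f, RMSE %.4f, MAE %.4f, within15 %.2f (n = %d)\n",
    x$R2, x$RMSE, x$MAE, x$within15, x$n))
  invisible(x)
}

#' K-fold cross-validation of a chlorophyll regressor
#'
#' Partitions the table into `k` folds of sizes differing by at most one,
#' fits on the out-of-fold rows and predicts each fold exactly once, then
#' pools all out-of-fold predictions into one set of metrics (per-fold
#' metrics are also returned; folds too small or degenerate for a
#' correlation report `NA` there).
#'
#' @param spec An [ml_spec()].
#' @param table Feature table with `spad` column, `nrow >= k`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List of class `cv_result`: `pooled` ([evaluate()] metrics over
#'   concatenated out-of-fold predictions), `folds` (data frame of
#'   per-fold RMSE/MAE/R2/n), `predictions` (data frame `row`, `fold`,
#'   `predicted`, `actual`).
#' @export
cross_validate <- function(spec, table, k = 10L, seed = 20190908L) {
  n <- nrow(table)
  k <- as.integer(k)
  if (k < 2L || k > n)
    stop("'k' must lie in [2, nrow(table)]", call. = FALSE)
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    hold <- fold == f
    fitted <- fit_model(spec, table[!hold, , drop = FALSE])
    pred[hold] <- predict(fitted, table[hold, , drop = FALSE])
  }
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    hold <- fold == f
    if (sum(hold) >= 2L) {
      m <- evaluate(pred[hold], table$spad[hold])
      data.frame(fold = f, n = m$n, RMSE = m$RMSE, MAE = m$MAE, R2 = m$R2)
    } else {
      data.frame(fold = f, n = sum(hold), RMSE = NA_real_, MAE = NA_real_,
                 R2 = NA_real_)
    }
  }))
  structure(list(pooled = evaluate(pred, table$spad),
                 folds = per_fold,
                 predictions = data.frame(row = seq_len(n), fold = fold,
                                          predicted = pred,
                                          actual = table$spad)),
            class = "cv_result")
}

#' Predict a per-pixel chlorophyll map
#'
#' Applies a fitted model to every green, feature-complete pixel of a
#' stack of index rasters, producing a chlorophyll surface; all other
#' pixels are undefined (`NA`). Predictions agree exactly with tabular
#' [predict()] on the same feature vectors. An optional `grid` block size
#' aggregates the map to coarser cells (block mean over defined pixels).
#'
#' @param model A fitted `chl_model`.
#' @param rasters Named list of index rasters covering every model
#'   feature (names are index acronyms, as from [compute_all_indices()]).
#' @param mask A `veg_mask`.
#' @param grid Optional integer block size for grid-aggregated output.
#' @return Numeric matrix of class `chl_map` with attribute `method`.
#' @export
predict_map <- function(model, rasters, mask, grid = NULL) {
  stopifnot(inherits(model, "chl_model"))
  missing <- setdiff(model$features, names(rasters))
  if (length(missing))
    stop("missing feature rasters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  d <- dim(rasters[[1]])
  if (!identical(dim(mask), d))
    stop("mask dimensions differ from rasters", call. = FALSE)
  feat <- vapply(model$features, function(f) as.vector(rasters[[f]]),
                 numeric(prod(d)))
  ok <- as.vector(mask == 1L) & stats::complete.cases(feat)
  out <- matrix(NA_real_, d[1], d[2])
  if (any(ok)) {
    df <- as.data.frame(feat[ok, , drop = FALSE])
    names(df) <- model$features
    out[ok] <- predict(model, df)
  }
  if (!is.null(grid)) {
    grid <- as.integer(grid)
    stopifnot(grid >= 1L)
    nr <- d[1] %/% grid * grid; nc <- d[2] %/% grid * grid
    sub <- out[seq_len(nr), seq_len(nc), drop = FALSE]
    cnt <- block_mean((!is.na(sub)) * 1.0, grid)
    sub[is.na(sub)] <- 0
    avg <- block_mean(sub, grid) / cnt
    avg[cnt == 0] <- NA_real_
    out <- avg
  }
  structure(out, class = c("chl_map", class(out)), method = model$method)
}
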