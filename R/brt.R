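#' Response transforms for reef indicators
#'
#' Benthic percent cover is modeled on the square-root scale and fish biomass
#' on the fourth-root scale; predictions are back-transformed and clipped to
#' the indicator's valid range.
#'
#' @param values numeric (>= 0).
#' @param kind `"sqrt"` or `"fourth_root"`.
#' @return transformed values.
#' @export
transform_response <- function(values, kind = c("sqrt", "fourth_root")) {
  kind <- match.arg(kind)
  if (any(values < 0, na.rm = TRUE)) stop("responses must be >= 0")
  if (kind == "sqrt") sqrt(values) else values^0.25
}

#' @rdname transform_response
#' @param upper clip ceiling on the original scale (100 for percent cover,
#'   `Inf` for biomass).
#' @export
inverse_transform <- function(values, kind = c("sqrt", "fourth_root"),
                              upper = Inf) {
  kind <- match.arg(kind)
  v <- pmax(values, 0)
  out <- if (kind == "sqrt") v^2 else v^4
  pmin(out, upper)
}

#' Sample a driver stack at survey points by bilinear interpolation
#'
#' Each layer is interpolated from the four nearest cell centers; weights of
#' nodata neighbors are renormalized over the valid ones. Points outside the
#' stack extent are an error, as are points whose four neighbors are all
#' nodata.
#'
#' @param stack a `driver_stack` (named list of co-registered rasters).
#' @param points data.frame or matrix with `x`, `y` columns.
#' @return data.frame of predictor values, one row per point.
#' @export
sample_at_points <- function(stack, points) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  g <- stack[[1]]
  ext <- c(g$origin[1], g$origin[1] + ncol(g$values) * g$cell_size,
           g$origin[2], g$origin[2] + nrow(g$values) * g$cell_size)
  if (any(pts[, 1] < ext[1] | pts[, 1] > ext[2] |
          pts[, 2] < ext[3] | pts[, 2] > ext[4]))
    stop("point outside stack extent")
  out <- lapply(stack, function(layer) {
    vapply(seq_len(nrow(pts)), function(r)
      bilinear_at(layer$values, layer, pts[r, ]), 0)
  })
  df <- as.data.frame(out)
  if (any(!is.finite(as.matrix(df))))
    stop("point with all-nodata bilinear neighborhood")
  df
}

#' BRT configuration
#'
#' Hyperparameter grid and fitting controls for [fit_brt()]: learning rate
#' (shrinkage), tree complexity (interaction depth), bag fraction (per-tree
#' subsample), and the tree-count ceiling; the tree count itself is selected
#' by k-fold cross-validated deviance.
#'
#' @param lr learning rates to search.
#' @param tc tree complexities (maximum tree depth) to search.
#' @param bag bag fractions to search.
#' @param n_trees_max ceiling on the number of trees.
#' @param folds number of CV folds.
#' @param early_stop CV rounds without improvement before stopping.
#' @return a list of class `brt_config`.
#' @export
brt_config <- function(lr = c(0.05, 0.01), tc = c(2, 3), bag = c(0.5, 0.75),
                       n_trees_max = 1500, folds = 10, early_stop = 50) {
  structure(list(lr = lr, tc = tc, bag = bag, n_trees_max = n_trees_max,
                 folds = folds, early_stop = early_stop),
            class = "brt_config")
}

#' Fit a boosted regression tree model
#'
#' Stagewise least-squares boosting (Gaussian deviance) with shrinkage and
#' bagging. For every (lr, tc, bag) combination the tree count is chosen at
#' the k-fold cross-validated deviance minimum (folds assigned from the
#' seed); the winning combination maximizes the cross-validated percent
#' deviance explained (CV PDE). PDE and CV PDE are reported on the
#' transformed scale the model is fit on: `PDE = 1 - SSE / SST`.
#'
#' @param X predictor data.frame (numeric columns).
#' @param y transformed response vector.
#' @param config a [brt_config()].
#' @param seed integer seed governing fold assignment and bagging.
#' @param response name of the response (for printing).
#' @param transform transform `y` is on (`"sqrt"`/`"fourth_root"`), recorded
#'   for back-mapping predictions.
#' @param upper back-transform ceiling (100 for cover).
#' @return an object of class `reef_brt` with elements `booster`,
#'   `hyperparameters` (lr, tc, bag, n_trees), `PDE`, `CV_PDE`,
#'   `relative_influence`, `fitted`, plus the training data.
#' @export
fit_brt <- function(X, y, config = brt_config(), seed = 1,
                    response = "response", transform = "sqrt", upper = Inf) {
  X <- as.data.frame(X)
  n <- nrow(X)
  if (n < 30) stop("need n >= 30 observations")
  if (ncol(X) < 2) stop("need >= 2 predictors")
  if (n < config$folds) stop("fewer observations than CV folds")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant response (SST = 0)")
  Xm <- as.matrix(X)
  storage.mode(Xm) <- "double"
  dtrain <- xgboost::xgb.DMatrix(Xm, label = y)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(config$folds), length.out = n))
  folds <- split(seq_len(n), fold_id)
  grid <- expand.grid(lr = config$lr, tc = config$tc, bag = config$bag)
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    params <- list(objective = "reg:squarederror", eta = grid$lr[g],
                   max_depth = grid$tc[g], subsample = grid$bag[g],
                   nthread = 1, seed = seed, lambda = 0, min_child_weight = 1)
    cv <- xgboost::xgb.cv(params, dtrain, nrounds = config$n_trees_max,
                          folds = folds, verbose = 0,
                          early_stopping_rounds = config$early_stop)
    log <- cv$evaluation_log
    n_trees <- which.min(log$test_rmse_mean)
    # exact held-out SSE at the chosen tree count
    cv_sse <- 0
    for (f in folds) {
      df <- xgboost::xgb.DMatrix(Xm[-f, , drop = FALSE], label = y[-f])
      bst <- xgboost::xgb.train(params, df, nrounds = n_trees)
      pr <- predict(bst, xgboost::xgb.DMatrix(Xm[f, , drop = FALSE]))
      cv_sse <- cv_sse + sum((y[f] - pr)^2)
    }
    cv_pde <- 1 - cv_sse / sst
    if (is.null(best) || cv_pde > best$cv_pde)
      best <- list(params = params, n_trees = n_trees, cv_pde = cv_pde,
                   lr = grid$lr[g], tc = grid$tc[g], bag = grid$bag[g])
  }
  booster <- xgboost::xgb.train(best$params, dtrain, nrounds = best$n_trees)
  fitted <- predict(booster, dtrain)
  pde <- 1 - sum((y - fitted)^2) / sst
  structure(list(
    response = response, transform = transform, upper = upper,
    booster = booster,
    hyperparameters = list(lr = best$lr, tc = best$tc, bag = best$bag,
                           n_trees = best$n_trees),
    PDE = pde, CV_PDE = best$cv_pde,
    relative_influence = influence_from_booster(booster, colnames(Xm)),
    fitted = fitted, X = X, y = y, seed = seed),
    class = "reef_brt")
}

influence_from_booster <- function(booster, feature_names) {
  imp <- xgboost::xgb.importance(model = booster)
  ri <- stats::setNames(rep(0, length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp)) ri[imp$Feature] <- imp$Gain
  100 * ri / sum(ri)
}

#' @export
print.reef_brt <- function(x, ...) {
  h <- x$hyperparameters
  cat(sprintf("<reef_brt> %s (%s scale): %d trees, lr=%g, tc=%d, bag=%g\n",
              x$response, x$transform, h$n_trees, h$lr, h$tc, h$bag))
  cat(sprintf("  PDE = %.1f%%, CV PDE = %.1f%%\n", 100 * x$PDE, 100 * x$CV_PDE))
  top <- sort(x$relative_influence, decreasing = TRUE)[1:min(3, length(x$relative_influence))]
  cat("  top drivers:", paste(sprintf("%s (%.1f%%)", names(top), top),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.reef_brt <- function(object, ...) {
  print(object)
  cat("  relative influence (%):\n")
  ri <- sort(object$relative_influence, decreasing = TRUE)
  for (nm in names(ri)) cat(sprintf("    %-12s %6.2f\n", nm, ri[nm]))
  invisible(object)
}

#' @export
predict.reef_brt <- function(object, newdata, back_transform = FALSE, ...) {
  Xm <- as.matrix(as.data.frame(newdata)[, names(object$X), drop = FALSE])
  storage.mode(Xm) <- "double"
  pr <- predict(object$booster, xgboost::xgb.DMatrix(Xm))
  if (back_transform) inverse_transform(pr, object$transform, object$upper) else pr
}

#' Relative influence of each driver
#'
#' Per-driver share of the total squared-error reduction over all tree splits
#' in the ensemble, normalized to sum to 100. Never-split drivers score 0.
#'
#' @param model a fitted `reef_brt`.
#' @return named numeric vector of percentages.
#' @export
relative_influence <- function(model) {
  if (!inherits(model, "reef_brt")) stop("not a reef_brt model")
  model$relative_influence
}

#' Partial dependence of the model on one driver
#'
#' Marginalizes the model over the training rows: for each grid value the
#' driver column is set to that value in every training row and predictions
#' averaged.
#'
#' @param model a fitted `reef_brt`.
#' @param driver driver name.
#' @param values evaluation values; default 25 quantile-spanning points.
#' @return data.frame `value`, `yhat` (transformed scale).
#' @export
partial_dependence <- function(model, driver, values = NULL) {
  if (!driver %in% names(model$X)) stop("unknown driver: ", driver)
  if (is.null(values))
    values <- seq(min(model$X[[driver]]), max(model$X[[driver]]), length.out = 25)
  yhat <- vapply(values, function(v) {
    Xv <- model$X
    Xv[[driver]] <- v
    mean(predict(model, Xv))
  }, 0)
  data.frame(value = values, yhat = yhat)
}

#' Predict a reef indicator map
#'
#' Applies a fitted model cell-by-cell over the driver stack, back-transforms
#' to the indicator scale, clips to the valid range, and propagates nodata
#' from any driver layer. Fish models require the predicted benthic layers to
#' be present in the stack under their indicator names.
#'
#' @param model a fitted `reef_brt`.
#' @param stack a `driver_stack` holding every driver the model uses.
#' @return prediction [raster_grid()].
#' @export
predict_map <- function(model, stack) {
  need <- names(model$X)
  miss <- setdiff(need, names(stack))
  if (length(miss)) stop("missing driver layer(s): ", paste(miss, collapse = ", "))
  dims <- dim(stack[[need[1]]]$values)
  cols <- lapply(need, function(nm) as.vector(stack[[nm]]$values))
  Xm <- do.call(cbind, cols)
  colnames(Xm) <- need
  ok <- rowSums(is.na(Xm)) == 0
  out <- rep(NA_real_, nrow(Xm))
  if (any(ok)) {
    pr <- predict(model$booster, xgboost::xgb.DMatrix(Xm[ok, , drop = FALSE]))
    out[ok] <- inverse_transform(pr, model$transform, model$upper)
  }
  grid_with(stack[[need[1]]], matrix(out, dims[1], dims[2]),
            units = if (is.finite(model$upper)) "%" else "g.m-2")
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' Row-standardized distance-band weights (neighbors within `band` meters);
#' the p-value is two-sided from `nperm` seeded permutations of the values
#' over the locations, comparing |I - E\[I\]| with the permutation
#' distribution. E\[I\] = -1/(n-1) under the null.
#'
#' @param values numeric vector (non-constant, n >= 10).
#' @param coords n x 2 matrix of locations (m).
#' @param band neighbor distance band (m); the default is 3x the median
#'   nearest-neighbor distance, widened to the maximum nearest-neighbor
#'   distance when points would otherwise be neighborless.
#' @param nperm permutations (default 999).
#' @param seed permutation seed.
#' @return list: `I`, `expected`, `p`, `band`.
#' @export
morans_i <- function(values, coords, band = NULL, nperm = 999, seed = 1) {
  n <- length(values)
  if (n < 10) stop("need n >= 10")
  if (stats::sd(values) == 0) stop("constant values")
  coords <- as.matrix(coords)
  D <- as.matrix(stats::dist(coords))
  if (is.null(band)) {
    diag(D) <- Inf
    nn <- apply(D, 1, min)
    band <- max(3 * stats::median(nn), max(nn) * (1 + 1e-9))
    diag(D) <- 0
  }
  W <- (D > 0 & D <= band) * 1
  if (any(rowSums(W) == 0)) stop("empty neighbor set at band ", format(band))
  W <- W / rowSums(W)
  s0 <- sum(W)
  I_of <- function(z) {
    zc <- z - mean(z)
    n / s0 * sum(W * outer(zc, zc)) / sum(zc^2)
  }
  I <- I_of(values)
  e <- -1 / (n - 1)
  set.seed(seed)
  perm <- replicate(nperm, I_of(sample(values)))
  p <- (1 + sum(abs(perm - e) >= abs(I - e))) / (nperm + 1)
  list(I = I, expected = e, p = p, band = band)
}

#' Observed-versus-predicted linear regression
#'
#' Ordinary least squares of the observed indicator on its prediction,
#' reporting the coefficient of determination, the slope, and the two-sided
#' p-value for the slope.
#'
#' @param observed,predicted paired numeric vectors (n >= 3).
#' @return list: `r2`, `slope`, `intercept`, `p`.
#' @export
obs_vs_pred <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3)
    stop("need >= 3 paired values")
  if (stats::sd(predicted) == 0) stop("zero-variance predictions")
  fit <- stats::lm(observed ~ predicted)
  sm <- summary(fit)
  list(r2 = sm$r.squared, slope = stats::coef(fit)[[2]],
       intercept = stats::coef(fit)[[1]], p = sm$coefficients[2, 4])
}
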