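fast_cfg <- function(...) brt_config(lr = 0.1, tc = 2, bag = 0.75,
                                     n_trees_max = 150, folds = 5, ...)

test_that("response transforms and their inverses round-trip with clipping", {
  expect_equal(transform_response(16, "fourth_root"), 2)
  expect_equal(transform_response(0, "sqrt"), 0)
  expect_equal(inverse_transform(0, "sqrt"), 0)
  expect_equal(inverse_transform(transform_response(49, "sqrt"), "sqrt"), 49)
  expect_equal(inverse_transform(transform_response(81, "fourth_root"), "fourth_root"), 81)
  expect_equal(inverse_transform(11, "sqrt", upper = 100), 100)  # clipped
  expect_equal(inverse_transform(-2, "sqrt"), 0)                 # floored
  expect_error(transform_response(-1, "sqrt"), ">= 0")
})

test_that("bilinear sampling matches cell centers, midpoints and the direct formula", {
  g <- raster_grid(matrix(c(0, 10, 20, 30), 2, 2), 10)
  st <- structure(list(v = g), class = "driver_stack")
  expect_equal(sample_at_points(st, data.frame(x = 5, y = 5))$v, g$values[1, 1])
  expect_equal(sample_at_points(st, data.frame(x = 10, y = 5))$v, 10)  # midway 0|20
  set.seed(8)
  big <- raster_grid(matrix(rnorm(400), 20, 20), 10)
  stb <- structure(list(v = big), class = "driver_stack")
  pts <- data.frame(x = runif(40, 5, 195), y = runif(40, 5, 195))
  got <- sample_at_points(stb, pts)$v
  oracle <- apply(pts, 1, function(p) brute_bilinear(big$values, big, p))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(sample_at_points(stb, data.frame(x = -50, y = 5)), "outside")
  # a nodata neighbor renormalizes instead of poisoning the estimate
  gn <- big; gn$values[1, 1] <- NA
  stn <- structure(list(v = gn), class = "driver_stack")
  v <- sample_at_points(stn, data.frame(x = 7, y = 7))$v
  expect_true(is.finite(v))
})

test_that("a noiseless signal is fit nearly perfectly and refits are identical", {
  set.seed(10)
  X <- data.frame(a = runif(120), b = runif(120), c = runif(120))
  y <- 3 * X$a
  m1 <- fit_brt(X, y, fast_cfg(), seed = 7)
  expect_gt(m1$PDE, 0.99)
  m2 <- fit_brt(X, y, fast_cfg(), seed = 7)
  expect_identical(m1$hyperparameters, m2$hyperparameters)
  expect_identical(m1$fitted, m2$fitted)
  expect_identical(m1$relative_influence, m2$relative_influence)
  expect_gt(m1$relative_influence["a"], 95)
  expect_error(fit_brt(X[1:10, ], y[1:10], fast_cfg()), "n >= 30")
  expect_error(fit_brt(X, rep(2, 120), fast_cfg()), "constant response")
})

test_that("pure-noise responses cross-validate to roughly zero deviance explained", {
  cvs <- vapply(1:8, function(s) {
    set.seed(100 + s)
    X <- data.frame(a = runif(80), b = runif(80))
    y <- rnorm(80)
    fit_brt(X, y, fast_cfg(), seed = s)$CV_PDE
  }, 0)
  expect_lt(abs(mean(cvs)), 0.1)
  expect_true(all(cvs < 0.25))
})

test_that("relative influence finds the informative predictor among noise", {
  hits <- vapply(1:5, function(s) {
    set.seed(200 + s)
    X <- as.data.frame(matrix(runif(300 * 6), 300))
    names(X) <- c("signal", paste0("noise", 1:5))
    y <- sin(2 * pi * X$signal) + rnorm(300, 0, 0.2)
    ri <- fit_brt(X, y, fast_cfg(), seed = s)$relative_influence
    expect_equal(sum(ri), 100, tolerance = 1e-6)
    names(which.max(ri)) == "signal"
  }, TRUE)
  expect_true(all(hits))
})

test_that("partial dependence recovers a linear truth and flattens on noise drivers", {
  set.seed(30)
  X <- data.frame(x = runif(200, 0, 1), junk = runif(200))
  y <- 2 * X$x
  m <- fit_brt(X, y, fast_cfg(), seed = 3)
  pd <- partial_dependence(m, "x")
  inner <- pd$value > 0.15 & pd$value < 0.85
  slope <- coef(lm(yhat ~ value, pd[inner, ]))[2]
  expect_equal(unname(slope), 2, tolerance = 0.25)
  pdj <- partial_dependence(m, "junk")
  expect_lt(diff(range(pdj$yhat)), 0.1 * diff(range(pd$yhat)))
  # definition check: curve point equals the brute-force row average
  v0 <- pd$value[10]
  Xv <- m$X; Xv$x <- v0
  expect_equal(pd$yhat[10], mean(predict(m, Xv)), tolerance = 1e-12)
  expect_error(partial_dependence(m, "absent"), "unknown driver")
})

test_that("prediction maps honor constants, clip covers and agree with fitted values", {
  set.seed(40)
  st <- toy_stack(8, 8)
  st$c <- NULL
  pts <- data.frame(x = runif(60, 40, 440), y = runif(60, 40, 440))
  X <- sample_at_points(st, pts)
  y <- pmin(10, 6 + 3 * X$a - 2 * X$b + rnorm(60, 0, 0.1))
  m <- fit_brt(X, y, fast_cfg(), seed = 4, transform = "sqrt", upper = 100)
  pm <- predict_map(m, st)
  expect_true(all(pm$values <= 100, na.rm = TRUE))
  # constant stack -> constant map at the point prediction
  cst <- structure(list(a = grid_with(st$a, matrix(0.5, 8, 8)),
                        b = grid_with(st$b, matrix(0.5, 8, 8))),
                   class = "driver_stack")
  pc <- predict_map(m, cst)
  expect_true(all(abs(pc$values - pc$values[1, 1]) < 1e-12))
  point_pred <- inverse_transform(predict(m, data.frame(a = 0.5, b = 0.5)),
                                  "sqrt", 100)
  expect_equal(pc$values[1, 1], point_pred)
  # sampling the map back at cell centers reproduces back-transformed fits
  centers <- data.frame(x = 90, y = 150)
  Xc <- sample_at_points(st, centers)
  expect_equal(sample_at_points(structure(list(p = pm), class = "driver_stack"),
                                centers)$p,
               inverse_transform(predict(m, Xc), "sqrt", 100), tolerance = 1e-9)
  expect_error(predict_map(m, structure(list(a = st$a), class = "driver_stack")),
               "missing driver")
})

test_that("Moran's I sits at its null expectation for iid data and detects structure", {
  set.seed(50)
  coords <- expand.grid(x = 1:7, y = 1:7) * 10
  iid <- rnorm(49)
  mi <- morans_i(iid, coords, nperm = 499, seed = 1)
  expect_equal(mi$expected, -1 / 48)
  expect_gt(mi$p, 0.05)
  # cross-check the statistic itself against an independent implementation
  skip_if_not_installed("ape")
  D <- as.matrix(dist(coords))
  W <- (D > 0 & D <= mi$band) * 1
  ape_i <- ape::Moran.I(iid, W / rowSums(W))
  expect_equal(mi$I, ape_i$observed, tolerance = 1e-12)
  # smooth gradient: strongly positive; checkerboard on rook band: negative
  grad <- coords$x + coords$y + rnorm(49, 0, 1)
  mg <- morans_i(grad, coords, nperm = 499, seed = 2)
  expect_gt(mg$I, 0.3); expect_lt(mg$p, 0.01)
  chk <- (-1)^(coords$x / 10 + coords$y / 10)
  mc <- morans_i(chk, coords, band = 10, nperm = 199, seed = 3)
  expect_lt(mc$I, -0.5)
  expect_error(morans_i(rep(1, 49), coords), "constant")
})

test_that("observed-versus-predicted regression matches a hand-computed example", {
  ob <- c(2, 4, 5, 4, 5); pr <- c(1, 2, 3, 4, 5)
  fit <- obs_vs_pred(ob, pr)
  # textbook OLS by hand: slope = Sxy/Sxx = 6/10, R2 = Sxy^2/(Sxx*Syy)
  expect_equal(fit$slope, 0.6)
  expect_equal(fit$intercept, 4 - 0.6 * 3)
  expect_equal(fit$r2, 36 / (10 * 6))
  perfect <- suppressWarnings(obs_vs_pred(1:10, 1:10))
  expect_equal(perfect$r2, 1)
  set.seed(60)
  null <- obs_vs_pred(rnorm(100), rnorm(100))
  expect_lt(null$r2, 0.1)
  expect_error(obs_vs_pred(1:5, rep(2, 5)), "zero-variance")
})
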