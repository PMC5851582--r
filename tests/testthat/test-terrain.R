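plane_grid <- function(px, py, nr = 12, nc = 12, a = 10, z0 = -5) {
  xs <- (seq_len(nc) - 0.5) * a; ys <- (seq_len(nr) - 0.5) * a
  raster_grid(outer(ys, xs, function(y, x) z0 + px * x + py * y), a)
}
interior <- function(g, k = 2) {
  nr <- nrow(g); nc <- ncol(g)
  g[(1 + k):(nr - k), (1 + k):(nc - k)]
}

test_that("slope and aspect match analytic planes; flat surfaces have no aspect", {
  flat <- plane_grid(0, 0)
  sa <- slope_aspect(flat)
  expect_true(all(sa$slope$values < 1e-12))
  expect_true(all(is.na(sa$aspect$values)))
  # z = -0.1 x: slope atan(0.1) ~ 5.71 deg, downslope faces east (90 deg)
  east <- slope_aspect(plane_grid(-0.1, 0))
  expect_true(all(abs(interior(east$slope$values) - atan(0.1) * 180 / pi) < 1e-9))
  expect_true(all(abs(interior(east$aspect$values) - 90) < 1e-9))
  # z = -0.2 y: downslope faces north (0 deg)
  north <- slope_aspect(plane_grid(0, -0.2))
  expect_true(all(abs(interior(north$aspect$values) %% 360) < 1e-9))
  # symmetric bump: slope ~ 0 at the apex
  a <- 10; xs <- (1:15 - 0.5) * a
  bump <- raster_grid(outer(xs, xs, function(y, x)
    -10 + 3 * exp(-((x - 75)^2 + (y - 75)^2) / 1000)), a)
  sab <- slope_aspect(bump)
  apex <- which(bump$values == max(bump$values), arr.ind = TRUE)
  expect_lt(sab$slope$values[apex], 0.05)
})

test_that("BPI vanishes on planes and detects pinnacles and their moat", {
  pl <- plane_grid(0.05, -0.02)
  b <- bpi(pl, radius = 30)
  expect_true(all(abs(interior(b$values, 3)) < 1e-9))   # symmetric cancellation
  flat <- matrix(-10, 11, 11)
  flat[6, 6] <- 0                                        # +10 m pinnacle
  pin <- raster_grid(flat, 10)
  bp <- bpi(pin, radius = 15)
  expect_gt(bp$values[6, 6], 5)
  expect_lt(bp$values[6, 5], 0)
  # brute-force neighborhood mean at the pinnacle: 8 neighbors of -10
  expect_equal(bp$values[6, 6], 0 - mean(rep(-10, 8)))
  expect_error(bpi(pin, radius = 5), "radius")
})

test_that("curvatures separate along- and across-gradient bending", {
  pl <- curvatures(plane_grid(0.1, -0.3))
  expect_true(all(abs(interior(pl$planar$values, 1)) < 1e-9))
  expect_true(all(abs(interior(pl$profile$values, 1)) < 1e-9))
  # tilted parabolic channel z = 0.1 x - 0.02 y^2 (axis along x at y = 0):
  # on the axis the gradient is along x -> profile 0, planar = -2*0.02
  a <- 5; xs <- (1:21 - 0.5) * a
  ys <- xs - mean(xs)
  chan <- raster_grid(outer(ys, xs, function(y, x) 0.1 * x - 0.02 * y^2), a,
                      origin = c(0, -mean(xs)))
  cv <- curvatures(chan)
  axis_row <- which.min(abs(ys))
  expect_equal(cv$profile$values[axis_row, 5], 0, tolerance = 1e-6)
  expect_equal(cv$planar$values[axis_row, 5], -0.04, tolerance = 1e-6)
  # spherical cap: both curvatures equal -1/R on the flank
  R <- 500
  cap <- raster_grid(outer(ys, ys, function(y, x)
    sqrt(R^2 - x^2 - y^2) - R), a, origin = c(-mean(xs), -mean(xs)))
  cc <- curvatures(cap)
  flank <- cbind(axis_row, 16)
  expect_equal(cc$profile$values[flank], cc$planar$values[flank], tolerance = 0.01)
  expect_equal(cc$planar$values[flank], -1 / R, tolerance = 2e-3)
  # degenerate zero-gradient window reports zero curvature
  expect_true(all(curvatures(plane_grid(0, 0))$profile$values == 0))
})

test_that("rugosity is exactly 1 when flat, 1/cos(slope) when tilted, larger when rough", {
  expect_true(all(abs(rugosity(plane_grid(0, 0))$values - 1) < 1e-12))
  for (px in c(0.1, 0.3)) {
    r <- rugosity(plane_grid(px, 0))
    expect_equal(interior(r$values),
                 matrix(1 / cos(atan(px)), nrow(interior(r$values)),
                        ncol(interior(r$values))), tolerance = 0.01)
  }
  set.seed(9)
  rough <- plane_grid(0, 0)
  rough$values <- rough$values + matrix(rnorm(144, 0, 2), 12, 12)
  expect_gt(mean(rugosity(rough)$values), mean(rugosity(plane_grid(0.1, 0))$values))
})

test_that("aspect circular statistics respect wraparound and dispersion limits", {
  g <- function(v) raster_grid(matrix(v, 5, 5), 10)
  cs <- circular_stats(g(0), radius = 15)
  expect_equal(cs$northness$values[3, 3], 1)
  expect_equal(cs$eastness$values[3, 3], 0)
  expect_equal(cs$aspect_sd$values[3, 3], 0)
  # aspects straddling north ({350, 10}) average to 0 degrees, never 180:
  # northness stays ~ +1 (it would be -1 for a naive arithmetic mean of 180)
  two <- g(350); two$values[, c(2, 4)] <- 10
  cs2 <- circular_stats(two, radius = 15)
  expect_gt(cs2$northness$values[3, 3], 0.95)
  expect_lt(abs(cs2$eastness$values[3, 3]), 0.2)
  # near-uniform aspects: resultant collapses, sd blows past the von-Mises scale
  set.seed(2)
  unif <- raster_grid(matrix(runif(900, 0, 360), 30, 30), 10)
  cs3 <- circular_stats(unif, radius = 120)
  mid <- cs3$aspect_sd$values[15, 15]
  expect_gt(mid, 1.5)   # sqrt(-2 log Rbar) is large as Rbar -> 0
})

test_that("distance to shore matches brute-force nearest-point search", {
  shore <- cbind(seq(0, 100, 10), 0)
  g <- raster_grid(matrix(0, 5, 10), 10)
  d <- distance_to_shore(shore, g)
  expect_equal(d$values[1, ], rep(5, 10))    # first row of centers at y = 5
  expect_equal(d$values[3, 2], 25)
  # concave bay: compare to a densified-vertex brute force
  t <- seq(0, pi, length.out = 200)
  bay <- cbind(50 + 40 * cos(t), 40 * sin(t))
  db <- distance_to_shore(bay, g)
  xy <- grid_xy(g)
  brute <- apply(xy, 1, function(p) sqrt(min((bay[, 1] - p[1])^2 + (bay[, 2] - p[2])^2)))
  expect_equal(as.vector(db$values), brute, tolerance = 0.01)
  expect_error(distance_to_shore(matrix(numeric(0), 0, 2), g), ">= 2")
})

test_that("terrain metrics ignore a constant depth shift and aggregation means blocks", {
  set.seed(4)
  z <- matrix(rnorm(144, -10, 2), 12, 12)
  g1 <- raster_grid(z, 10); g2 <- raster_grid(z + 100, 10)
  expect_equal(slope_aspect(g1)$slope$values, slope_aspect(g2)$slope$values)
  expect_equal(bpi(g1, 20)$values, bpi(g2, 20)$values, tolerance = 1e-9)
  expect_equal(rugosity(g1)$values, rugosity(g2)$values)
  ag <- aggregate_grid(g1, 3)
  expect_identical(dim(ag$values), c(4L, 4L))
  expect_equal(ag$values[1, 1], mean(z[1:3, 1:3]))
  expect_equal(ag$cell_size, 30)
})
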