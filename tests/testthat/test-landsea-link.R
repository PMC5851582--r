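straight_shore <- function(L = 1000, y = 0) cbind(seq(0, L, by = 50), y)

test_that("pour points fall at arc-length intervals with the half-offset start", {
  pp <- place_pour_points(straight_shore(1000), 200)
  expect_identical(nrow(pp), 5L)
  expect_equal(pp$x, c(100, 300, 500, 700, 900))
  expect_true(all(pp$y == 0))
  expect_error(place_pour_points(straight_shore(100), 200), "shorter")
  expect_error(place_pour_points(matrix(c(0, 0), 1, 2), 10), "degenerate")
})

test_that("closed-loop shorelines wrap without a duplicate at the seam", {
  th <- seq(0, 2 * pi, length.out = 721)
  r <- 500
  ring <- cbind(r * cos(th), r * sin(th))
  L <- sum(sqrt(diff(ring[, 1])^2 + diff(ring[, 2])^2))
  pp <- place_pour_points(ring, 200)
  expect_identical(nrow(pp), as.integer(floor(L / 200)))
  # brute-force arc-length walk: all pairwise gaps >= spacing/2 (no seam twin)
  d <- as.matrix(dist(pp[, c("x", "y")]))
  diag(d) <- Inf
  expect_gt(min(d), 100)
})

test_that("reverse tracking follows the negated field and flags stagnation", {
  # uniform southward flow (toward a coast at y = 0): reverse paths head north
  g <- raster_grid(matrix(1, 20, 10), 10)
  ff <- structure(list(qx = matrix(0, 20, 9), qy = matrix(-5, 19, 10),
                       grid = g, fixed = matrix(FALSE, 20, 10)),
                  class = "flow_field")
  seeds <- data.frame(x = c(25, 75), y = c(5, 5))
  paths <- trace_flowpaths(ff, seeds)
  for (k in 1:2) {
    v <- paths[[k]]$vertices
    expect_true(all(abs(v[, 1] - seeds$x[k]) < 1e-9))   # straight inland line
    expect_true(all(diff(v[, 2]) > 0))
    expect_identical(paths[[k]]$status, "exited")
  }
  # zero-velocity field: path is the seed alone, flagged stagnant
  ff0 <- structure(list(qx = matrix(0, 20, 9), qy = matrix(0, 19, 10),
                        grid = g, fixed = matrix(FALSE, 20, 10)),
                   class = "flow_field")
  p0 <- trace_flowpaths(ff0, data.frame(x = 50, y = 50))[[1]]
  expect_identical(nrow(p0$vertices), 1L)
  expect_identical(p0$status, "stagnant")
})

test_that("radially convergent flow makes adjacent reverse paths diverge inland", {
  # analytic sink at the bay mouth (50, 0): q = -r_hat / |r|
  n <- 30; a <- 10
  g <- raster_grid(matrix(1, n, n), a)
  cx <- 150; cy <- 0
  vx_at <- function(x, y) -(x - cx) / pmax(sqrt((x - cx)^2 + (y - cy)^2), 1)
  vy_at <- function(x, y) -(y - cy) / pmax(sqrt((x - cx)^2 + (y - cy)^2), 1)
  xs <- (seq_len(n) - 0.5) * a
  qx <- matrix(0, n, n - 1); qy <- matrix(0, n - 1, n)
  for (i in seq_len(n)) for (j in seq_len(n - 1))
    qx[i, j] <- vx_at(j * a, xs[i]) * a * 2      # face flux ~ v * a (x2: cell-avg)
  for (i in seq_len(n - 1)) for (j in seq_len(n))
    qy[i, j] <- vy_at(xs[j], i * a) * a * 2
  ff <- structure(list(qx = qx, qy = qy, grid = g, fixed = matrix(FALSE, n, n)),
                  class = "flow_field")
  seeds <- data.frame(x = c(130, 170), y = c(15, 15))
  paths <- trace_flowpaths(ff, seeds, max_steps = 500)
  d_start <- abs(diff(seeds$x))
  ends <- vapply(paths, function(p) p$vertices[nrow(p$vertices), ], numeric(2))
  d_end <- sqrt(sum((ends[, 1] - ends[, 2])^2))
  expect_gt(d_end, 2 * d_start)
})

test_that("straight parallel paths partition the strip into equal tubes", {
  nr <- 20; nc <- 20; a <- 10
  g <- raster_grid(matrix(1, nr, nc), a)
  shore <- straight_shore(200, 0)
  mk_path <- function(x) list(vertices = cbind(x, seq(0, 200, by = 5)),
                              status = "exited")
  paths <- lapply(c(20, 60, 100, 140, 180), mk_path)
  tubes <- delineate_flow_tubes(paths, shore, g, inland_extent = 150)
  asg <- tubes$assignment
  strip <- tubes$strip
  expect_true(all(!is.na(asg[strip])))                 # partition property
  expect_true(all(is.na(asg[!strip])))
  counts <- table(asg[strip])
  expect_identical(length(counts), 4L)                 # 5 paths -> 4-6 tubes
  # brute-force band assignment oracle for interior columns
  cells <- which(strip, arr.ind = TRUE)
  xs <- (cells[, 2] - 0.5) * a
  inner <- xs > 20 & xs < 180
  oracle <- findInterval(xs[inner], c(20, 60, 100, 140, 180))
  expect_identical(as.integer(asg[cells[inner, , drop = FALSE]]), as.integer(oracle))
  expect_error(delineate_flow_tubes(paths[1], shore, g, 100), ">= 2")
  crossing <- list(mk_path(20),
                   list(vertices = cbind(c(60, -25), c(0, 200)), status = "exited"))
  expect_error(delineate_flow_tubes(crossing, shore, g, 150), "cross")
})

test_that("zone budgets conserve the strip totals and split symmetric inputs", {
  nr <- 10; nc <- 12; a <- 10
  g <- raster_grid(matrix(1, nr, nc), a)
  shore <- straight_shore(120, 0)
  mk_path <- function(x) list(vertices = cbind(x, seq(0, 100, by = 5)),
                              status = "exited")
  set.seed(11)
  rand_grid <- function() raster_grid(matrix(runif(nr * nc), nr, nc), a)
  # seven tubes from eight paths over seeded random rasters
  paths <- lapply(seq(7.5, 112.5, by = 15), mk_path)
  tubes <- delineate_flow_tubes(paths, shore, g, inland_extent = 95)
  rs <- replicate(5, rand_grid(), simplify = FALSE)
  tb <- zone_budget(tubes, rs[[1]], rs[[2]], rs[[3]], rs[[4]], rs[[5]])
  expect_identical(nrow(tb), 7L)
  strip_total <- function(r) sum(r$values[tubes$strip])
  expect_rel_equal(sum(tb$water_flux), strip_total(rs[[1]]), 1e-9)
  expect_rel_equal(sum(tb$n_flux_background), strip_total(rs[[2]]), 1e-9)
  expect_rel_equal(sum(tb$p_flux_anthropogenic), strip_total(rs[[5]]), 1e-9)
  expect_equal(tb$n_flux, tb$n_flux_background + tb$n_flux_anthropogenic)

  # upslope inflow is allocated and conserved
  tb2 <- zone_budget(tubes, rs[[1]], rs[[2]], rs[[3]], rs[[4]], rs[[5]],
                     upslope = list(water = 100, n_bg = 10))
  expect_rel_equal(sum(tb2$water_flux), strip_total(rs[[1]]) + 100, 1e-9)
  expect_rel_equal(sum(tb2$n_flux_background), strip_total(rs[[2]]) + 10, 1e-9)

  # two equal tubes over uniform rasters split 50/50; one tube takes all
  paths2 <- lapply(c(10, 60, 110), mk_path)
  tubes2 <- delineate_flow_tubes(paths2, shore, g, inland_extent = 95)
  ug <- raster_grid(matrix(2, nr, nc), a)
  tb3 <- zone_budget(tubes2, ug, ug, ug, ug, ug)
  expect_equal(tb3$water_flux[1], tb3$water_flux[2], tolerance = 0.1)
  paths1 <- lapply(c(2, 118), mk_path)
  tubes1 <- delineate_flow_tubes(paths1, shore, g, inland_extent = 95)
  tb4 <- zone_budget(tubes1, ug, ug, ug, ug, ug)
  expect_identical(nrow(tb4), 1L)
  expect_rel_equal(tb4$water_flux, sum(ug$values[tubes1$strip]), 1e-9)
})
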