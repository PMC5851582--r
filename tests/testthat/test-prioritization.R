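toy_site <- function() {
  g <- function(v) raster_grid(matrix(v, 3, 3, byrow = TRUE), 60)
  stack <- structure(list(
    depth = g(c(-2, -2, -8,
                -3, -4, -9,
                -2, -6, -3)),
    wave_power = g(c(5, 30, 5,
                     5, 5, 30,
                     30, 5, 5)),
    n_flux = g(c(10, 10, 10,
                 50, 50, 1,
                 50, 50, 50)),
    p_flux = g(c(9, 1, 9,
                 9, 9, 9,
                 1, 9, 9))), class = "driver_stack")
  predictions <- list(
    coral = g(c(20, 20, 20, 20, 5, 20, 20, 20, 20)),
    macroalgae = g(c(12, 12, 2, 12, 12, 12, 12, 12, 12)),
    cca = g(c(6, 6, 6, 6, 6, 2, 6, 6, 6)),
    turf = g(c(60, 60, 60, 60, 60, 60, 2, 60, 60)))
  list(stack = stack, predictions = predictions)
}

test_that("tercile and mean thresholds follow order statistics and overrides", {
  s <- toy_site()
  # linear-interpolation terciles of 1..9: upper 19/3, lower 11/3
  s$stack$n_flux <- raster_grid(matrix(1:9, 3, 3), 60)
  s$stack$wave_power <- raster_grid(matrix(1:9, 3, 3), 60)
  cc <- derive_thresholds(s$stack, s$predictions, site = "dry")
  expect_equal(unname(cc$nutrient["n_flux"]), 1 + 8 * 2 / 3)
  cw <- derive_thresholds(s$stack, s$predictions, site = "wet")
  expect_equal(unname(cw$wave), 1 + 8 / 3)
  # benthic thresholds default to prediction-map site means
  expect_equal(unname(cw$benthic["coral"]),
               mean(s$predictions$coral$values))
  # printed site-specific values pass straight through as overrides
  ov <- derive_thresholds(s$stack, s$predictions, site = "wet",
                          overrides = list(coral = 11.4, macroalgae = 9.4,
                                           turf = 50.0, n_flux = 1322.7,
                                           wave_power = 19860))
  expect_equal(unname(ov$benthic), c(11.4, 9.4, 50.0))
  expect_equal(unname(ov$nutrient["n_flux"]), 1322.7)
  expect_equal(ov$wave, 19860)
  expect_identical(names(derive_thresholds(s$stack, s$predictions, "dry")$nutrient),
                   c("n_flux", "p_flux"))
})

test_that("vulnerability flags equal the brute-force cell-by-cell evaluation", {
  s <- toy_site()
  crit <- structure(list(site = "wet", depth_max = 5,
                         benthic = c(coral = 11.4, macroalgae = 9.4, turf = 50),
                         nutrient = c(n_flux = 20), wave = 20),
                    class = "criteria_config")
  vm <- classify_vulnerable(s$stack, s$predictions, crit)
  # exhaustive per-cell oracle
  for (i in 1:3) for (j in 1:3) {
    want <- s$stack$depth$values[i, j] >= -5 &&
      s$predictions$coral$values[i, j] > 11.4 &&
      s$predictions$macroalgae$values[i, j] > 9.4 &&
      s$predictions$turf$values[i, j] > 50 &&
      s$stack$n_flux$values[i, j] > 20 &&
      s$stack$wave_power$values[i, j] < 20
    expect_identical(vm$flags$values[i, j] == 1, want,
                     info = sprintf("cell (%d,%d)", i, j))
  }
  # flag set is the intersection of the per-criterion masks
  expect_identical(vm$flags$values == 1, Reduce(`&`, vm$masks))
  expect_identical(vm$n_flagged, sum(Reduce(`&`, vm$masks)))
})

test_that("degenerate criteria flag everything or nothing", {
  s <- toy_site()
  none <- structure(list(site = "wet", depth_max = 5,
                         benthic = c(coral = Inf), nutrient = c(n_flux = Inf),
                         wave = -Inf), class = "criteria_config")
  expect_identical(classify_vulnerable(s$stack, s$predictions, none)$n_flagged, 0L)
  all_of <- structure(list(site = "wet", depth_max = Inf,
                           benthic = c(coral = -Inf), nutrient = c(n_flux = -Inf),
                           wave = Inf), class = "criteria_config")
  expect_identical(classify_vulnerable(s$stack, s$predictions, all_of)$n_flagged, 9L)
  deep <- s; deep$stack$depth <- raster_grid(matrix(-50, 3, 3), 60)
  crit <- structure(list(site = "wet", depth_max = 5, benthic = c(coral = -Inf),
                         nutrient = c(n_flux = -Inf), wave = Inf),
                    class = "criteria_config")
  expect_identical(classify_vulnerable(deep$stack, deep$predictions, crit)$n_flagged, 0L)
  bad <- structure(list(site = "wet", depth_max = 5, benthic = c(sand = 1),
                        nutrient = c(n_flux = 1), wave = NA_real_),
                   class = "criteria_config")
  expect_error(classify_vulnerable(s$stack, s$predictions, bad), "missing")
})

test_that("flagged cells are attributed to the dominant plume and ranked stably", {
  g <- function(v) raster_grid(matrix(v, 2, 3, byrow = TRUE), 60)
  flags <- g(c(1, 1, 0, 0, 1, 1))
  vuln <- structure(list(flags = flags), class = "vulnerability_map")
  budget <- data.frame(id = 1:2, n_flux_anthropogenic = c(5, 50),
                       p_flux_anthropogenic = c(1, 2))
  plumes <- list(g(c(9, 1, 0, 0, 1, 1)),   # tube 1 dominates cell (1,1)
                 g(c(1, 8, 0, 0, 7, 7)))   # tube 2 dominates the rest
  rk <- match_priority_tubes(vuln, budget, plumes)
  # per-cell argmax oracle: 4 flagged cells, tube1 wins 1, tube2 wins 3
  expect_identical(rk$flagged_cells[rk$id == 1], 1L)
  expect_identical(rk$flagged_cells[rk$id == 2], 3L)
  expect_identical(rk$id[1], 2L)          # higher anthropogenic flux first
  # single tube receives every flag
  rk1 <- match_priority_tubes(vuln, budget[1, ], plumes[1])
  expect_identical(rk1$flagged_cells, 4L)
  # tied fluxes fall back to flag count, then id: deterministic order
  budget_t <- data.frame(id = 1:2, n_flux_anthropogenic = c(5, 5),
                         p_flux_anthropogenic = c(1, 1))
  rk_t <- match_priority_tubes(vuln, budget_t, plumes)
  expect_identical(rk_t$id, c(2L, 1L))    # more flags wins the tie
  expect_identical(rk_t$rank, 1:2)
  # no flags: zero counts, logged
  vuln0 <- structure(list(flags = g(rep(0, 6))), class = "vulnerability_map")
  expect_message(rk0 <- match_priority_tubes(vuln0, budget, plumes), "no flagged")
  expect_true(all(rk0$flagged_cells == 0L))
})
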