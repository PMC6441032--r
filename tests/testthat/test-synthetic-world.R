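test_that("grid construction validates inputs and indexes cells row-major", {
  g <- make_grid(4, 5)
  expect_equal(n_cells(g), 20)
  cc <- cell_coords(g)
  expect_equal(cc$cell, 1:20)
  expect_equal(cc$row[6], 2L) # cell 6 starts row 2 on a 5-column grid
  expect_equal(cc$x_km[1], 50)
  expect_error(make_grid(0, 5), class = "bioscen_invalid_input")
  expect_error(make_grid(3, 3, cell_size_km = 0), class = "bioscen_invalid_input")
})

test_that("current climate is deterministic given the seed", {
  g <- make_grid(10, 10)
  a <- simulate_current_climate(g, corr_length = 0, seed = 1)
  b <- simulate_current_climate(g, corr_length = 0, seed = 1)
  expect_identical(a, b)
  c <- simulate_current_climate(g, corr_length = 0, seed = 2)
  expect_false(identical(a$mean_temp, c$mean_temp))
})

test_that("zero-noise climate is an exact planar gradient", {
  g <- make_grid(12, 9)
  cl <- simulate_current_climate(
    g, corr_length = 0, seed = 1,
    noise_sd = c(mean_temp = 0, temp_range = 0, precip_sum = 0, precip_cv = 0)
  )
  # a plane has zero residual against row + col
  fit <- lm(mean_temp ~ row + col, data = cl)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_true(all(cl$precip_sum >= 0))
  expect_true(all(cl$precip_cv >= 0))
})

test_that("spatial autocorrelation decays with lag for correlated noise", {
  cl <- simulate_current_climate(make_grid(30, 30), corr_length = 5, seed = 7)
  resid <- residuals(lm(mean_temp ~ row + col, data = cl))
  m <- matrix(resid[order(cl$cell)], nrow = 30, byrow = TRUE)
  lag_cor <- function(k) {
    cor(as.vector(m[seq_len(30 - k), ]), as.vector(m[seq_len(30 - k) + k, ]))
  }
  expect_gt(lag_cor(1), lag_cor(10))
  expect_gt(lag_cor(1), 0.3)
})

test_that("scenario cube covers every combo x period exactly once and is seeded", {
  cur <- toy_climate(8)
  des <- default_scenario_design()
  cube <- simulate_scenario_climate(cur, des, scenario_effects(), seed = 3)
  keys <- dplyr::distinct(cube$future, gcm, rcp, period)
  expect_equal(nrow(keys), 14 * 2)
  expect_equal(nrow(cube$future), 14 * 2 * n_cells(make_grid(8, 8)))
  cube2 <- simulate_scenario_climate(cur, des, scenario_effects(), seed = 3)
  expect_identical(cube$future, cube2$future)
})

test_that("with no GCM spread or noise, warming is strictly increasing in RCP rank", {
  cur <- toy_climate(8)
  eff <- scenario_effects(
    gcm_sd = c(mean_temp = 0, temp_range = 0, precip_sum = 0, precip_cv = 0)
  )
  cube <- simulate_scenario_climate(cur, default_scenario_design(), eff, seed = 1)
  warming <- cube$future |>
    dplyr::group_by(rcp, period) |>
    dplyr::summarise(t = mean(mean_temp), .groups = "drop") |>
    dplyr::arrange(period, rcp)
  for (p in unique(warming$period)) {
    expect_true(all(diff(warming$t[warming$period == p]) > 0))
  }
})

test_that("zero-effect scenarios reproduce the current climate exactly", {
  cur <- toy_climate(6)
  eff <- scenario_effects(
    rcp_severity_step = c(mean_temp = 0, temp_range = 0, precip_sum = 0, precip_cv = 0),
    gcm_sd = c(mean_temp = 0, temp_range = 0, precip_sum = 0, precip_cv = 0)
  )
  cube <- simulate_scenario_climate(cur, default_scenario_design(), eff, seed = 1)
  one <- cube$future[cube$future$gcm == "GCM-A" & cube$future$rcp == "RCP8.5" &
                       cube$future$period == "2041-2060", ]
  expect_equal(one$mean_temp, cur$mean_temp)
  expect_equal(one$precip_sum, cur$precip_sum)
})

test_that("between-GCM variance of spatial-mean warming matches gcm_sd^2", {
  cur <- toy_climate(6)
  gsd <- 0.5
  eff <- scenario_effects(
    rcp_severity_step = c(mean_temp = 0, temp_range = 0, precip_sum = 0, precip_cv = 0),
    gcm_sd = c(mean_temp = gsd, temp_range = 0, precip_sum = 0, precip_cv = 0)
  )
  des <- scenario_design(sprintf("G%d", 1:5), "RCP8.5", periods = "2041-2060")
  vars <- vapply(1:60, function(s) {
    cube <- simulate_scenario_climate(cur, des, eff, seed = s)
    means <- cube$future |>
      dplyr::group_by(gcm) |>
      dplyr::summarise(t = mean(mean_temp), .groups = "drop")
    var(means$t)
  }, numeric(1))
  expect_equal(mean(vars), gsd^2, tolerance = 0.15)
})

test_that("the same GCM deviation field is reused across RCPs", {
  cur <- toy_climate(6)
  eff <- scenario_effects(
    rcp_severity_step = c(mean_temp = 0, temp_range = 0, precip_sum = 0, precip_cv = 0)
  )
  des <- scenario_design("G1", c("RCP2.6", "RCP8.5"), periods = "2041-2060")
  cube <- simulate_scenario_climate(cur, des, eff, seed = 4)
  low <- cube$future$mean_temp[cube$future$rcp == "RCP2.6"]
  high <- cube$future$mean_temp[cube$future$rcp == "RCP8.5"]
  expect_equal(low, high) # only the (zeroed) RCP term differs
})

test_that("virtual species honour prevalence targets and the 20-cell filter", {
  cl <- toy_climate(40)
  sp <- simulate_species(cl, 1, prevalence_range = c(0.5, 0.5), seed = 5)
  expect_equal(sp$range_size, 800, tolerance = 0.02)
  many <- simulate_species(toy_climate(30), 15, seed = 6)
  expect_true(all(many$range_size >= 20))
  realized <- many$range_size / 900
  expect_true(all(abs(realized - many$prevalence_target) <= 0.02))
})

test_that("species generation is seed-deterministic and errors on impossible grids", {
  cl <- toy_climate(20)
  a <- simulate_species(cl, 4, seed = 9)
  b <- simulate_species(cl, 4, seed = 9)
  expect_identical(a, b)
  tiny <- simulate_current_climate(make_grid(2, 2), corr_length = 0, seed = 1)
  expect_error(
    simulate_species(tiny, 1, prevalence_range = c(0.05, 0.05), seed = 1),
    "unattainable", class = "bioscen_invalid_input"
  )
})

test_that("a narrow-niche species concentrates around its optimum cell", {
  # smooth noise-free gradients so climate similarity implies proximity
  cl <- simulate_current_climate(
    make_grid(20, 20), corr_length = 0, seed = 1,
    noise_sd = c(mean_temp = 0, temp_range = 0, precip_sum = 0, precip_cv = 0)
  )
  anchor <- 190
  opt <- vapply(c("mean_temp", "temp_range", "precip_sum", "precip_cv"),
                function(v) cl[[v]][anchor], numeric(1))
  suit <- niche_suitability(
    cl, opt,
    breadth = c(mean_temp = 0.5, temp_range = 0.5, precip_sum = 10, precip_cv = 0.5)
  )
  expect_equal(which.max(suit), anchor)
  top <- order(suit, decreasing = TRUE)[1:5]
  cc <- cell_coords(make_grid(20, 20))
  d <- sqrt((cc$x_km[top] - cc$x_km[anchor])^2 + (cc$y_km[top] - cc$y_km[anchor])^2)
  expect_true(all(d <= 500))
})

test_that("regions tile the grid into contiguous near-equal blocks", {
  g <- make_grid(10, 10)
  r1 <- assign_regions(g, 1)
  expect_equal(unique(r1$region_id), "R01")
  r4 <- assign_regions(g, 4)
  expect_equal(unname(table(r4$region_id)), rep(25L, 4), ignore_attr = TRUE)
  # blocks are contiguous: each region spans a rectangular row/col window
  for (rid in unique(r4$region_id)) {
    sub <- r4[r4$region_id == rid, ]
    expect_equal(nrow(sub), length(unique(sub$row)) * length(unique(sub$col)))
  }
  r7 <- assign_regions(g, 7)
  expect_equal(sum(table(r7$region_id)), 100)
  expect_error(assign_regions(g, 101), class = "bioscen_invalid_input")
})
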