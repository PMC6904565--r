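# rasterization, mask-aware smoothing and the residual objective

test_that("downsampling bins vessel top flows into the right pixels", {
  net <- parallel_vessel_network(r1 = 10, r2 = 20)  # vessels at x = 0, 100
  sol <- solve_flow(net, boundary_conditions(-1))
  grid <- list(pixel_size_um = 50, x0 = -25, y0 = 25, nx = 4, ny = 1)
  fm <- downsample_to_pixels(sol, net, grid)
  f <- sol$vessels$top_flow_ug_s
  expect_equal(fm$values[1, 1], f[1])
  expect_equal(fm$values[1, 3], f[2])
  expect_equal(fm$values[1, c(2, 4)], c(0, 0))
  # two vessels in the same pixel add
  grid2 <- list(pixel_size_um = 200, x0 = -50, y0 = 25, nx = 1, ny = 1)
  fm2 <- downsample_to_pixels(sol, net, grid2)
  expect_equal(fm2$values[1, 1], sum(f))
})

test_that("raster total equals the network total and strays are dropped", {
  gen <- generate_network(small_spec(), 3)
  sol <- solve_flow(gen$network, boundary_conditions(-0.1))
  grid <- default_grid(gen$network, 78)
  fm <- downsample_to_pixels(sol, gen$network, grid)
  expect_equal(sum(fm$values), total_top_flow(sol), tolerance = 1e-12)
  # a huge offset pushes every vessel off the grid
  expect_warning(
    fm2 <- downsample_to_pixels(sol, gen$network, grid, offset_um = c(1e6, 0)),
    "outside the grid")
  expect_equal(sum(fm2$values), 0)
})

test_that("masked box smoothing matches the naive double-loop oracle", {
  set.seed(42)
  for (k in c(1, 3, 5)) {
    v <- matrix(rnorm(30 * 20), 30, 20)
    inc <- matrix(runif(30 * 20) > 0.25, 30, 20)
    got <- box_smooth(v, inc, k = k)
    oracle <- box_smooth_oracle(v, inc, k)
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("the windowed objective is zero iff model equals observation", {
  set.seed(7)
  o <- flow_map(matrix(abs(rnorm(100)), 10), 78)
  ro <- residual_objective(o, o)
  expect_equal(ro$objective, 0)
  # a single interior residual rho contributes rho^2 / 25
  m <- o
  m$values[5, 5] <- m$values[5, 5] + 3
  ro2 <- residual_objective(m, o)
  expect_equal(ro2$objective, 9 / 25, tolerance = 1e-12)
  expect_gt(ro2$objective, 0)
  # shape mismatch errors
  expect_error(residual_objective(flow_map(matrix(0, 2, 2), 78), o),
               "shape")
})

test_that("objective matches a from-scratch loop computation on random rasters", {
  set.seed(11)
  m <- flow_map(matrix(rnorm(200), 20), 78)
  o <- flow_map(matrix(rnorm(200), 20), 78)
  inc <- matrix(runif(200) > 0.2, 20)
  ro <- residual_objective(m, o, include = inc)
  sm <- box_smooth_oracle(`[<-`(m$values - o$values, !inc, 0), inc, 5)
  expect_equal(ro$objective, sum(sm[inc]^2), tolerance = 1e-12)
})

test_that("pixel pressure map is the flow-weighted mean of member drops", {
  # one vessel per pixel: the pixel carries that vessel's drop
  net <- parallel_vessel_network(r1 = 10, r2 = 20)
  sol <- solve_flow(net, boundary_conditions(-0.3))
  grid <- list(pixel_size_um = 50, x0 = -25, y0 = 25, nx = 4, ny = 1)
  pm <- pixel_pressure_map(sol, net, grid)
  expect_equal(pm$values[1, 1], 0.3)
  expect_equal(pm$values[1, 3], 0.3)
  expect_true(is.na(pm$values[1, 2]))  # empty pixel
})

test_that("shared-pixel pressure averages use flows as weights", {
  # hand-built solution: drops 1 and 3 kPa with equal/unequal flows
  fake_net <- parallel_vessel_network()
  fake_sol <- solve_flow(fake_net, boundary_conditions(-1))
  fake_sol$vessels$pressure_drop_kPa <- c(1, 3)
  fake_sol$vessels$top_flow_ug_s <- c(1, 1)
  grid <- list(pixel_size_um = 200, x0 = -50, y0 = 25, nx = 1, ny = 1)
  pm <- pixel_pressure_map(fake_sol, fake_net, grid)
  expect_equal(pm$values[1, 1], 2)
  fake_sol$vessels$top_flow_ug_s <- c(3, 1)
  pm2 <- pixel_pressure_map(fake_sol, fake_net, grid)
  expect_equal(pm2$values[1, 1], 1.5)
})

test_that("mask labels select included pixels", {
  mk <- matrix(c("inner.lateral", "outer.lateral", "excluded",
                 "inner.dorsal_ventral"), 2, 2)
  fm <- flow_map(matrix(1, 2, 2), 78, mask = mk)
  inc <- include_from_mask(fm)
  expect_equal(sum(inc), 3)
  inc2 <- include_from_mask(fm, c("excluded", "outer"))
  expect_equal(inc2, matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
})
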