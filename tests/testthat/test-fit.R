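# inverse boundary-pressure estimation

make_truth <- function(seed, noise = 0, model = "per_group_uniform", ...) {
  generate_synthetic_truth(small_spec(noise_sd_ug_s = noise,
                                      pressure_model = model, ...), seed)
}

test_that("uniform fit recovers a noiseless uniform drop exactly", {
  truth <- make_truth(5, model = "uniform")
  fit <- fit_uniform_pressure(truth$network, truth$noiseless)
  expect_equal(fit$drops_kPa, truth$spec$uniform_drop_kPa, tolerance = 1e-9)
  expect_gte(fit$nse, 0.999999)
  # scaling the observation scales the fitted drop
  obs2 <- truth$noiseless
  obs2$values <- obs2$values * 2
  fit2 <- fit_uniform_pressure(truth$network, obs2)
  expect_equal(fit2$drops_kPa, 2 * fit$drops_kPa, tolerance = 1e-9)
  expect_error(
    fit_uniform_pressure(truth$network,
                         flow_map(matrix(0, nrow(obs2$values),
                                         ncol(obs2$values)),
                                  obs2$pixel_size_um, obs2$x0, obs2$y0)),
    "all zero")
})

test_that("uniform fit agrees with a 1-D search of the objective", {
  truth <- make_truth(8, noise = 2, model = "uniform")
  fit <- fit_uniform_pressure(truth$network, truth$noisy)
  objective_of <- function(drop) {
    sol <- solve_flow(truth$network, boundary_conditions(-drop))
    model <- suppressWarnings(downsample_to_pixels(
      sol, truth$network, truth$grid, mask = truth$noisy$mask))
    residual_objective(model, truth$noisy)$objective
  }
  opt <- stats::optimize(objective_of, c(0, 5 * fit$drops_kPa), tol = 1e-10)
  expect_equal(fit$drops_kPa, opt$minimum, tolerance = 1e-5)
  expect_lte(fit$objective, objective_of(fit$drops_kPa) + 1e-9)
})

test_that("total-flow fit is exact and linear in the target", {
  truth <- make_truth(3, model = "uniform")
  unit <- solve_flow(truth$network, boundary_conditions(-1))
  K <- total_top_flow(unit)
  fit <- fit_total_flow(truth$network, K)
  expect_equal(fit$drops_kPa, 1, tolerance = 1e-12)
  fit2 <- fit_total_flow(truth$network, 2 * K)
  expect_equal(fit2$drops_kPa, 2, tolerance = 1e-12)
  # reproduces a forward total exactly
  fit3 <- fit_total_flow(truth$network, sum(truth$noiseless$values),
                         observed = truth$noiseless)
  expect_equal(total_top_flow(fit3$solution), sum(truth$noiseless$values),
               tolerance = 1e-12)
  expect_error(fit_total_flow(truth$network, -1), "positive")
})

test_that("per-group fit recovers noiseless per-group drops", {
  truth <- make_truth(5)
  fit <- fit_group_pressures(truth$network, truth$noiseless)
  obs <- observable_groups(truth)
  expect_gt(length(obs), 0)
  err <- abs(fit$drops_kPa[obs] - truth$true_drops_kPa[obs])
  expect_lt(stats::median(err), 1e-6)
  expect_lt(max(err), 1e-6)
  expect_gte(fit$nse, 0.999)
})

test_that("an all-zero observation with zero lower bound gives zero drops", {
  truth <- make_truth(4)
  zero_obs <- truth$noiseless
  zero_obs$values[] <- 0
  fit <- fit_group_pressures(truth$network, zero_obs, init = 0)
  expect_equal(max(abs(fit$drops_kPa)), 0)
})

test_that("bounded least squares matches an exhaustive QP oracle", {
  set.seed(21)
  for (rep in 1:3) {
    m <- 7
    B <- matrix(rnorm(40 * m), 40, m)
    d_true <- c(runif(m - 2), -0.5, -0.2)  # some bound-active coordinates
    y <- B %*% d_true + rnorm(40, 0, 0.1)
    got <- xylemflow:::.nnls_design(B, as.numeric(y))
    obj <- function(d) sum((B %*% d - y)^2)
    # oracle: enumerate all active sets, solve free coordinates, keep the
    # best feasible KKT point
    best <- Inf
    for (mask in 0:(2^m - 1)) {
      active <- as.logical(bitwAnd(mask, 2^(0:(m - 1))))
      d <- numeric(m)
      if (any(!active)) {
        Bf <- B[, !active, drop = FALSE]
        d[!active] <- qr.solve(crossprod(Bf), crossprod(Bf, y))
      }
      if (all(d >= -1e-12)) best <- min(best, obj(pmax(d, 0)))
    }
    expect_equal(obj(got), best, tolerance = 1e-8)
  }
})

test_that("richer pressure parameterizations never fit worse", {
  for (seed in c(2, 6)) {
    truth <- make_truth(seed, noise = 1)
    obs <- truth$noisy
    inc <- include_from_mask(obs)
    fit_u <- fit_uniform_pressure(truth$network, obs)
    fit_g <- fit_group_pressures(truth$network, obs)
    obj_zero <- residual_objective(
      flow_map(matrix(0, nrow(obs$values), ncol(obs$values)),
               obs$pixel_size_um, obs$x0, obs$y0, obs$mask), obs)$objective
    expect_lte(fit_g$objective, fit_u$objective + 1e-9)
    expect_lte(fit_u$objective, obj_zero + 1e-9)
  }
})

test_that("smoothing makes the fit robust to registration jitter", {
  spec <- small_spec(pressure_model = "uniform")
  truth <- generate_synthetic_truth(spec, 9)
  jit <- c(78, 0)  # one pixel
  nse_of <- function(smooth, offset) {
    obs <- suppressWarnings(downsample_to_pixels(
      truth$solution, truth$network, truth$grid, offset,
      mask = truth$noiseless$mask))
    fit <- fit_uniform_pressure(truth$network, obs, smooth = smooth)
    k <- if (smooth) 5 else 1
    inc <- include_from_mask(obs)
    s_m <- box_smooth(`[<-`(fit$model_map$values, !inc, 0), inc, k)[inc]
    s_o <- box_smooth(`[<-`(obs$values, !inc, 0), inc, k)[inc]
    nse(s_o, s_m)
  }
  drop_smooth <- nse_of(TRUE, c(0, 0)) - nse_of(TRUE, jit)
  drop_raw <- nse_of(FALSE, c(0, 0)) - nse_of(FALSE, jit)
  expect_lt(drop_smooth, drop_raw)
})
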