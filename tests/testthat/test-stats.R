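# flow-weighted statistics, NSE, gradients, deviation tests, ANOVA

test_that("NSE is 1 for a perfect model and 0 for the mean model", {
  set.seed(3)
  o <- rnorm(50, 10, 2)
  expect_equal(nse(o, o), 1)
  expect_equal(nse(o, rep(mean(o), 50)), 0)
  m <- o + rnorm(50)
  expect_equal(nse(o, m), 1 - sum((o - m)^2) / sum((o - mean(o))^2))
  # invariant to a common affine unit change of both series
  expect_equal(nse(2 * o + 5, 2 * m + 5), nse(o, m))
  expect_error(nse(rep(1, 5), rnorm(5)), "constant")
})

test_that("flow-weighted summary reduces to ordinary moments and is scale-free", {
  set.seed(4)
  x <- rnorm(30, 5)
  s <- flow_weighted_summary(x, rep(2, 30))
  expect_equal(s$mean, mean(x))
  expect_equal(s$sd, sd(x))
  w <- runif(30)
  s1 <- flow_weighted_summary(x, w)
  s2 <- flow_weighted_summary(x, 7 * w)
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$sd, s2$sd)
  # direct formula oracle
  W <- sum(w); mu <- sum(w * x) / W
  expect_equal(s1$mean, mu)
  expect_equal(s1$sd, sqrt(sum(w * (x - mu)^2) / (W - sum(w^2) / W)))
  # a single nonzero weight pins the mean, SD degenerates with a warning
  expect_warning(s3 <- flow_weighted_summary(x, c(1, rep(0, 29))), "single")
  expect_equal(s3$mean, x[1])
  expect_equal(s3$sd, 0)
  expect_error(flow_weighted_summary(x, rep(0, 30)), "zero")
})

test_that("transverse gradients enumerate 4-neighbour pairs once", {
  # uniform map: every gradient zero
  pm <- flow_map(matrix(0.5, 4, 4), 78)
  tg <- transverse_gradients(pm)
  expect_equal(tg$n, 2 * 4 * 3)
  expect_equal(max(tg$gradients_MPa_m), 0)
  # two adjacent pixels differing by 0.078 kPa at 78 um -> 1 MPa/m
  v <- matrix(NA_real_, 2, 2)
  v[1, 1] <- 0.1; v[1, 2] <- 0.1 + 0.078
  tg2 <- transverse_gradients(flow_map(v, 78))
  expect_equal(tg2$n, 1)
  expect_equal(tg2$gradients_MPa_m, 1)
  # random map against brute-force neighbour enumeration
  set.seed(8)
  v3 <- matrix(rnorm(48), 6, 8)
  v3[sample(48, 12)] <- NA
  tg3 <- transverse_gradients(flow_map(v3, 78))
  brute <- c()
  for (i in 1:6) for (j in 1:8) {
    if (i < 6 && is.finite(v3[i, j]) && is.finite(v3[i + 1, j]))
      brute <- c(brute, abs(v3[i, j] - v3[i + 1, j]))
    if (j < 8 && is.finite(v3[i, j]) && is.finite(v3[i, j + 1]))
      brute <- c(brute, abs(v3[i, j] - v3[i, j + 1]))
  }
  expect_equal(tg3$n, length(brute))
  expect_equal(sort(tg3$gradients_MPa_m), sort(brute / 78 * 1e3))
})

test_that("flows on the idealized curve give t = 0 and p = 1 everywhere", {
  r <- seq(12, 50, by = 2)
  f <- hp_theoretical_curve(r, 0.07)
  d <- suppressWarnings(hp_deviation_test(r, f, 0.07))
  expect_true(all(d$t == 0))
  expect_true(all(d$p == 1))
  expect_equal(d$df, d$n - 1)
})

test_that("a constant residual shift reproduces the textbook t statistic", {
  set.seed(12)
  r <- rep(30, 10)  # one window of exactly 10 vessels
  noise <- rnorm(10)
  noise <- noise - mean(noise)  # center so the shift is the exact mean
  shift <- 0.8
  f <- hp_theoretical_curve(r, 0.05) + shift + noise
  d <- suppressWarnings(hp_deviation_test(r, f, 0.05))
  s <- sd(shift + noise)
  expect_equal(d$t[d$center_radius_um == 30], shift / (s / sqrt(10)),
               tolerance = 1e-12)
})

test_that("the deviation test detects flow suppression above a radius threshold", {
  set.seed(33)
  r <- runif(400, 10, 60)
  f <- hp_theoretical_curve(r, 0.07) * ifelse(r > 35, 0.4, 1) +
    rnorm(400, 0, 0.05)
  d <- suppressWarnings(hp_deviation_test(r, f, 0.07))
  below <- d$p[d$center_radius_um <= 30]
  above <- d$p[d$center_radius_um >= 40]
  expect_gt(min(below), 0.05)   # no deviation below the threshold
  expect_lt(max(above), 0.05)   # strong deviation above it
  # robustness utility covers wider windows
  prof <- suppressWarnings(hp_deviation_profile(r, f, 0.07,
                                                widths_um = c(6, 12)))
  expect_setequal(unique(prof$window_um), c(6, 12))
})

test_that("two-way ANOVA matches the closed-form balanced oracle", {
  set.seed(5)
  a <- rep(c("inner", "outer"), each = 20)
  b <- rep(rep(c("dorsal_ventral", "lateral"), each = 10), 2)
  # identical means: F should be ~0 against pure noise effects
  y0 <- rnorm(40)
  res0 <- two_way_anova(y0, a, b)
  expect_true(all(res0$p[1:2] > 1e-6))
  # injected factor-A effect recovered; balanced Type II equals aov
  y <- y0 + ifelse(a == "inner", 1.5, 0)
  res <- two_way_anova(y, a, b)
  oracle <- summary(stats::aov(y ~ factor(a) * factor(b)))[[1]]
  expect_equal(res$F[1], oracle[["F value"]][1], tolerance = 1e-9)
  expect_equal(res$p[1], oracle[["Pr(>F)"]][1], tolerance = 1e-9)
  expect_lt(res$p[1], 0.05)
  # degenerate layouts error
  expect_error(two_way_anova(y, rep("inner", 40), b), "two levels")
  expect_error(two_way_anova(y[1:20], a[1:20], b[1:20]))
  expect_error(two_way_anova(y[c(1:10, 21:40)], a[c(1:10, 21:40)],
                             b[c(1:10, 21:40)]), "empty cell")
})

test_that("flow shares partition and conductivities scale", {
  net <- parallel_vessel_network(10, 10)
  sol <- solve_flow(net, boundary_conditions(-1))
  rep1 <- flow_share_report(sol, c("all", "all"),
                            domain_areas_mm2 = c(all = 1))
  expect_equal(rep1$flow_fraction, 1)
  rep2 <- flow_share_report(sol, c("left", "right"),
                            domain_areas_mm2 = c(left = 1, right = 1))
  expect_equal(rep2$flow_fraction, c(0.5, 0.5))
  expect_equal(sum(rep2$flow_fraction), 1)
  expect_equal(rep2$conductivity[1], rep2$conductivity[2])
})

test_that("flow redirection ledgers per-vessel gains and losses", {
  truth <- generate_synthetic_truth(small_spec(noise_sd_ug_s = 0), 13)
  fit_u <- fit_uniform_pressure(truth$network, truth$noiseless)
  fit_g <- fit_group_pressures(truth$network, truth$noiseless)
  r <- truth$vessels$radius_um
  # identical fits: nothing redirected
  rd0 <- flow_redirection(fit_u, fit_u, r)
  expect_equal(rd0$redirected_share, 0)
  rd <- flow_redirection(fit_u, fit_g, r)
  # ledger oracle: recompute from the per-vessel table
  pv <- rd$per_vessel
  expect_equal(rd$redirected_share,
               sum(pv$delta[pv$delta > 0]) / sum(pv$flow_b))
  expect_equal(rd$wide_loss_fraction,
               -sum(pv$delta[pv$wide & pv$delta < 0]) /
                 sum(pv$flow_a[pv$wide]))
  # a pure two-vessel swap redirects exactly q / total
  fa <- fit_u; fb <- fit_u
  fa$vessels <- fa$vessels[1:2, ]
  fb$vessels <- fb$vessels[1:2, ]
  fa$vessels$top_flow_ug_s <- c(3, 1)
  fb$vessels$top_flow_ug_s <- c(2, 2)
  rd2 <- flow_redirection(fa, fb, c(50, 10), mean_radius_um = 30)
  expect_equal(rd2$redirected_share, 1 / 4)
  expect_equal(rd2$wide_loss_fraction, 1 / 3)
})
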