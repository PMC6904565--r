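# the synthetic network and flow-map generator

test_that("generation is a pure function of spec and seed", {
  spec <- small_spec()
  g1 <- generate_network(spec, 17)
  g2 <- generate_network(spec, 17)
  f1 <- tempfile(); f2 <- tempfile()
  write_network(g1$network, f1)
  write_network(g2$network, f2)
  expect_identical(readLines(f1), readLines(f2))
  g3 <- generate_network(spec, 18)
  expect_false(identical(g1$vessels$x, g3$vessels$x))
  t1 <- generate_synthetic_truth(spec, 17)
  t2 <- generate_synthetic_truth(spec, 17)
  expect_identical(t1$noisy$values, t2$noisy$values)
})

test_that("zero connection probability leaves every vessel solitary", {
  spec <- small_spec(p_connect = 0, p_relay = 0)
  g <- generate_network(spec, 2)
  expect_equal(nrow(g$network$connections), 0)
  gr <- vessel_groups(g$network)
  expect_equal(max(gr$group), spec$n_vessels)
})

test_that("realized diameters track the per-domain targets over seeds", {
  spec <- small_spec()
  d_dv <- c(); d_lat <- c()
  for (s in 1:20) {
    v <- generate_network(spec, s)$vessels
    d_dv <- c(d_dv, v$diam_um[v$tangential == "dorsal_ventral"])
    d_lat <- c(d_lat, v$diam_um[v$tangential == "lateral"])
  }
  # within 3 standard errors of the spec's lognormal targets
  expect_lt(abs(mean(d_dv) - spec$diam_dv_mean_um),
            3 * spec$diam_dv_sd_um / sqrt(length(d_dv)))
  expect_lt(abs(mean(d_lat) - spec$diam_lat_mean_um),
            3 * spec$diam_lat_sd_um / sqrt(length(d_lat)))
})

test_that("noiseless maps equal the forward solve and noise has the right scale", {
  spec <- small_spec(noise_sd_ug_s = 0)
  truth <- generate_synthetic_truth(spec, 5)
  expect_identical(truth$noiseless$values, truth$noisy$values)
  expect_equal(sum(truth$noiseless$values),
               total_top_flow(truth$solution), tolerance = 1e-9)
  # Gaussian perturbation: mean |dx| ~ sd * sqrt(2/pi) over many pixels
  sdv <- 2
  truth2 <- generate_synthetic_truth(small_spec(noise_sd_ug_s = sdv), 5)
  nz <- truth2$noiseless$values != 0
  pert <- abs(truth2$noisy$values - truth2$noiseless$values)[nz]
  expect_gt(length(pert), 30)
  expect_equal(mean(pert), sdv * sqrt(2 / pi),
               tolerance = 4 / sqrt(length(pert)))
})

test_that("domain masks tile the annulus and track the geometry", {
  spec <- small_spec()
  grid <- list(pixel_size_um = 78, x0 = -1050, y0 = 1050, nx = 27, ny = 27)
  mk <- domain_mask(grid, spec)
  expect_true(all(mk %in% c("excluded",
                            paste(rep(c("inner", "outer"), each = 2),
                                  c("dorsal_ventral", "lateral"),
                                  sep = "."))))
  # the pith centre pixel is excluded, a pixel on +y inside the annulus is
  # dorsal/ventral
  centre <- mk[14, 14]
  expect_equal(centre, "excluded")
  iy <- floor((1050 - 900) / 78) + 1
  expect_match(mk[iy, 14], "dorsal_ventral")
})

test_that("recovery error grows with observation noise", {
  noise_grid <- c(0, 1, 4, 16)
  med <- vapply(noise_grid, function(sdv) {
    runs <- recovery_experiment(small_spec(noise_sd_ug_s = sdv), seeds = 1:6)
    stats::median(runs$median_abs_error_kPa)
  }, numeric(1))
  expect_equal(med[1], 0, tolerance = 1e-8)
  expect_gt(stats::cor(noise_grid, med, method = "spearman"), 0)
  expect_lt(med[1], med[4])
})

test_that("serial narrow feeders depress wide-vessel flow share", {
  spec <- small_spec(pressure_model = "serial_feeder", noise_sd_ug_s = 0)
  truth <- generate_synthetic_truth(spec, 11)
  fit_g <- fit_group_pressures(truth$network, truth$noiseless)
  fit_u <- fit_uniform_pressure(truth$network, truth$noiseless)
  r <- truth$vessels$radius_um
  wide <- r > mean(r)
  share <- function(fit)
    sum(fit$vessels$top_flow_ug_s[wide]) / sum(fit$vessels$top_flow_ug_s)
  # the per-group fit reproduces the reduced wide-vessel share relative to
  # the homogeneous-gradient (uniform) prediction
  expect_lt(share(fit_g), share(fit_u))
  # and the wide-vessel gradients it infers are reduced
  gw <- fit_g$vessels$gradient_MPa_m
  expect_lt(stats::median(gw[wide]), stats::median(gw[!wide]))
})
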