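# vessel networks: construction, groups, flow solves

test_that("parallel lumina with radii r and 2r carry flows 1:16", {
  net <- parallel_vessel_network(r1 = 10, r2 = 20)
  sol <- solve_flow(net, boundary_conditions(-1))
  f <- sol$vessels$top_flow_ug_s
  expect_equal(f[2] / f[1], 16, tolerance = 1e-12)
  # positive upward flow for a pressure drop from bottom to top
  expect_true(all(f > 0))
  # both gradients equal the imposed drop over the length
  expect_equal(sol$vessels$gradient_MPa_m,
               rep(1 / 1000 * 1e3, 2))
})

test_that("solitary vessels conserve their axial flow top to bottom", {
  net <- parallel_vessel_network()
  sol <- solve_flow(net, boundary_conditions(-0.5))
  expect_equal(vessel_axial_flow(sol, 1, "top"),
               vessel_axial_flow(sol, 1, "bottom"))
  expect_error(vessel_axial_flow(sol, 99), "unknown vessel")
  # zero drop -> zero flow
  sol0 <- solve_flow(net, boundary_conditions(0))
  expect_equal(vessel_axial_flow(sol0, 1, "top"), 0)
})

test_that("vessel groups partition vessels and match a union-find oracle", {
  net <- parallel_vessel_network()
  g <- vessel_groups(net)
  expect_equal(g$group, c(1, 2))  # no connections: all solitary
  net2 <- pitted_pair_network()
  g2 <- vessel_groups(net2)
  expect_equal(g2$group, c(1, 1))  # one pit field joins the pair
  for (seed in c(2, 9)) {
    gen <- generate_network(small_spec(), seed)
    got <- vessel_groups(gen$network)$group
    oracle <- union_find_groups(gen$network)
    # same partition up to labels
    expect_equal(length(unique(got)), length(unique(oracle)))
    expect_true(all(tapply(oracle, got, function(x) length(unique(x))) == 1))
  }
})

test_that("group partition is invariant under connection reordering", {
  gen <- generate_network(small_spec(), 4)
  net <- gen$network
  g1 <- vessel_groups(net)
  net$connections <- net$connections[rev(seq_len(nrow(net$connections))), ]
  g2 <- vessel_groups(net)
  expect_equal(g1, g2)
})

test_that("per-group boundary pressures broadcast to the right vessels", {
  net <- pitted_pair_network()
  # both vessels share one group: per-group vector of length 1
  sol <- solve_flow(net, boundary_conditions(c("1" = -0.2)))
  expect_equal(sol$vessels$pressure_drop_kPa, c(0.2, 0.2))
  expect_error(solve_flow(net, boundary_conditions(c(-0.1, -0.2))),
               "one top pressure per vessel group")
})

test_that("total top inflow equals total bottom outflow", {
  gen <- generate_network(small_spec(), 6)
  groups <- vessel_groups(gen$network)
  drops <- stats::setNames(seq_len(max(groups$group)) * 1e-3,
                           seq_len(max(groups$group)))
  sol <- solve_flow(gen$network, boundary_conditions(-drops))
  expect_equal(sum(sol$vessels$top_flow_ug_s),
               sum(sol$vessels$bottom_flow_ug_s), tolerance = 1e-9)
  # interior conservation
  res <- xylemflow:::.conservation_residual(
    sol$edges, list(flows = sol$edges$flow_ug_s), sol$fixed_nodes)
  expect_lt(res, 1e-9)
})

test_that("network validation rejects malformed inputs", {
  nodes <- data.frame(id = c("a", "b"), x = 0, y = 0, z = c(0, 100),
                      tag = c("bottom", "top"))
  lum <- data.frame(vessel_id = 1, node_a = "a", node_b = "b",
                    radius_um = -5)
  expect_error(vessel_network(nodes, lum, NULL, 100, 1), "positive")
  nodes2 <- nodes
  nodes2$tag <- c("bottom", "sideways")
  lum$radius_um <- 5
  expect_error(vessel_network(nodes2, lum, NULL, 100, 1), "tag")
  # duplicated ids
  nodes3 <- nodes
  nodes3$id <- c("a", "a")
  expect_error(vessel_network(nodes3, lum, NULL, 100, 1), "unique")
})
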