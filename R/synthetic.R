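# Synthetic vessel networks and observed flow maps with the statistical
# structure of first-year grapevine stem xylem: ~500 vessels in an annular
# cross-section, per-domain lognormal diameter distributions, pit-field
# and relay connections, and forward-simulated noisy flow rasters with
# known boundary pressures for recovery experiments.

#' Specification of a synthetic xylem network
#'
#' Defaults emulate the anatomical census of a 3.3 mm first-year grapevine
#' internode:
#' 491 vessels over a 10.4 mm2 annular xylem cross-section, dorsal/ventral
#' vessel diameters 44 +/- 34 um versus lateral 30 +/- 20 um (lognormal,
#' moment-matched), pit membrane areas 0.015 +/- 0.012 mm2, vessel relays
#' with diameters 10 +/- 11 um, and per-group pressure drops drawn
#' uniformly over 0 to 0.78 kPa, the range such stems exhibit in vivo.
#'
#' @param n_vessels Number of vessels.
#' @param stem_radius_um,pith_radius_um Annulus radii in um (defaults give
#'   a 10.4 mm2 xylem area).
#' @param inner_fraction Radial position of the inner/outer domain split as
#'   a fraction of the annulus width.
#' @param diam_dv_mean_um,diam_dv_sd_um Diameter moments in the
#'   dorsal/ventral wedges.
#' @param diam_lat_mean_um,diam_lat_sd_um Diameter moments in the lateral
#'   wedges.
#' @param min_diam_um Lower truncation of diameters.
#' @param wall_gap_um Minimum clearance between vessel perimeters enforced
#'   by the Poisson-disc placement.
#' @param contact_gap_um Decay length (um) of the pit-field connection
#'   kernel: a pair with perimeter gap g is pitted with probability
#'   `p_connect * exp(-g / contact_gap_um)`.
#' @param p_connect Amplitude of the pit-field connection kernel.
#' @param pit_multiplicity Pitted pairs carry `1 + Poisson(pit_multiplicity)`
#'   pit fields at independent heights.
#' @param relay_range_um Decay length of the vessel-relay kernel.
#' @param p_relay Amplitude of the vessel-relay kernel.
#' @param pit_area_mean_mm2,pit_area_sd_mm2 Pit membrane area moments
#'   (lognormal).
#' @param relay_diam_mean_um,relay_diam_sd_um Relay diameter moments
#'   (lognormal), truncated below at `min_relay_diam_um`.
#' @param min_relay_diam_um Lower truncation of relay diameters.
#' @param sample_length_um Axial sample length.
#' @param pressure_model "per_group_uniform" (independent drops uniform in
#'   `drop_range_kPa`), "uniform" (single drop `uniform_drop_kPa`),
#'   "serial_feeder" (each group's drop is the share of `system_drop_kPa`
#'   falling across the sampled segment when the group drains through a
#'   narrow feeder conduit of radius `feeder_radius_um`; wide, conductive
#'   groups then see systematically smaller drops), or "table" (drops
#'   supplied to the generator).
#' @param drop_range_kPa Range of per-group drops.
#' @param uniform_drop_kPa Drop for the "uniform" model.
#' @param system_drop_kPa,feeder_radius_um Parameters of "serial_feeder".
#' @param noise_sd_ug_s Observation noise SD added per nonzero pixel.
#' @param pixel_size_um Flow-map pixel size.
#' @param jitter_um length-2 registration jitter applied to the noisy map.
#' @param fluid A [fluid_constants()] object.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_vessels = 491,
                           stem_radius_um = 2000,
                           pith_radius_um = 830,
                           inner_fraction = 0.5,
                           diam_dv_mean_um = 44, diam_dv_sd_um = 34,
                           diam_lat_mean_um = 30, diam_lat_sd_um = 20,
                           min_diam_um = 5,
                           wall_gap_um = 5,
                           contact_gap_um = 30,
                           p_connect = 0.95,
                           pit_multiplicity = 2.1,
                           relay_range_um = 90,
                           p_relay = 0.13,
                           pit_area_mean_mm2 = 0.015, pit_area_sd_mm2 = 0.012,
                           relay_diam_mean_um = 10, relay_diam_sd_um = 11,
                           min_relay_diam_um = 2,
                           sample_length_um = 3300,
                           pressure_model = c("per_group_uniform", "uniform",
                                              "serial_feeder", "table"),
                           drop_range_kPa = c(0, 0.78),
                           uniform_drop_kPa = 0.055,
                           system_drop_kPa = 0.78,
                           feeder_radius_um = 15,
                           noise_sd_ug_s = 0.5,
                           pixel_size_um = 78,
                           jitter_um = c(0, 0),
                           fluid = fluid_constants()) {
  pressure_model <- match.arg(pressure_model)
  spec <- as.list(environment())
  stopifnot(spec$n_vessels > 0, spec$stem_radius_um > spec$pith_radius_um,
            spec$p_connect >= 0, spec$p_connect <= 1,
            spec$p_relay >= 0, spec$p_relay <= 1,
            all(spec$drop_range_kPa >= 0))
  structure(spec, class = "synthetic_spec")
}

# lognormal parameters matching a target mean and sd
.lognormal_params <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

.rlnorm_trunc <- function(n, mean, sd, lower) {
  p <- .lognormal_params(mean, sd)
  x <- stats::rlnorm(n, p$meanlog, p$sdlog)
  while (any(bad <- x < lower))
    x[bad] <- stats::rlnorm(sum(bad), p$meanlog, p$sdlog)
  x
}

# tangential wedge of an angle (radians): dorsal and ventral wedges are
# centered on +y and -y, lateral wedges on +x and -x, each 90 degrees
.tangential_domain <- function(theta) {
  a <- (theta * 180 / pi) %% 360
  ifelse((a >= 45 & a < 135) | (a >= 225 & a < 315),
         "dorsal_ventral", "lateral")
}

.radial_domain <- function(r, spec) {
  split <- spec$pith_radius_um +
    spec$inner_fraction * (spec$stem_radius_um - spec$pith_radius_um)
  ifelse(r < split, "inner", "outer")
}

#' Generate a synthetic vessel network
#'
#' Vessels are placed by Poisson-disc (dart-throwing) sampling in the
#' annular cross-section, with diameters drawn from the wedge's lognormal
#' distribution. Vessels run the full sample length. Pairs whose perimeter
#' gap is within contact range become pit fields with probability
#' `p_connect`; pairs in the relay range are bridged by a vessel relay
#' (two relay pit fields in series with a narrow relay lumen) with
#' probability `p_relay`. Connections sit at a uniform random height.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; the output is a pure function of (spec, seed).
#' @return list(network, vessels) where `vessels` is a data.frame
#'   (vessel_id, x, y, radius_um, diam_um, radial, tangential).
#' @export
generate_network <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- spec$n_vessels
  # wedge and diameter are drawn first and kept; only the position is
  # rejection-sampled, so packing does not bias the diameter distribution
  wedge <- ifelse(stats::runif(n) < 0.5, "dorsal_ventral", "lateral")
  diam <- numeric(n)
  dv <- wedge == "dorsal_ventral"
  diam[dv] <- .rlnorm_trunc(sum(dv), spec$diam_dv_mean_um,
                            spec$diam_dv_sd_um, spec$min_diam_um)
  diam[!dv] <- .rlnorm_trunc(sum(!dv), spec$diam_lat_mean_um,
                             spec$diam_lat_sd_um, spec$min_diam_um)
  ord <- order(diam, decreasing = TRUE)  # place large vessels first
  xs <- ys <- rad <- numeric(n)
  dom_t <- character(n)
  placed <- 0
  for (kk in ord) {
    r <- diam[kk] / 2
    wd <- wedge[kk]
    tries <- 0
    repeat {
      tries <- tries + 1
      if (tries > 20000)
        stop(sprintf(
          "generate_network: packing infeasible (placed %d of %d, stuck on diameter %.1f um)",
          placed, n, diam[kk]))
      rr <- sqrt(stats::runif(1, spec$pith_radius_um^2, spec$stem_radius_um^2))
      th <- stats::runif(1, 0, 2 * pi)
      if (.tangential_domain(th) != wd) next
      if (rr - r < spec$pith_radius_um || rr + r > spec$stem_radius_um) next
      x <- rr * cos(th)
      y <- rr * sin(th)
      if (placed > 0) {
        dd <- sqrt((xs[1:placed] - x)^2 + (ys[1:placed] - y)^2)
        if (any(dd < rad[1:placed] + r + spec$wall_gap_um)) next
      }
      break
    }
    placed <- placed + 1
    xs[placed] <- x; ys[placed] <- y; rad[placed] <- r; dom_t[placed] <- wd
  }
  vessels <- data.frame(
    vessel_id = seq_len(n), x = xs, y = ys, radius_um = rad,
    diam_um = 2 * rad,
    radial = .radial_domain(sqrt(xs^2 + ys^2), spec),
    tangential = dom_t, stringsAsFactors = FALSE)

  # candidate pairs by perimeter gap; connection probability decays
  # exponentially with the gap, separately for direct pit fields (short
  # range) and vessel relays (longer range)
  dmat <- as.matrix(stats::dist(cbind(xs, ys)))
  gap <- pmax(dmat - outer(rad, rad, "+"), 0)
  iu <- which(upper.tri(gap), arr.ind = TRUE)
  gaps <- gap[iu]
  p_pit <- spec$p_connect * exp(-gaps / spec$contact_gap_um)
  u <- stats::runif(length(gaps))
  is_pit <- u < p_pit
  p_rel <- spec$p_relay * exp(-gaps / spec$relay_range_um)
  is_relay <- !is_pit & stats::runif(length(gaps)) < p_rel
  pit_pairs <- iu[is_pit, , drop = FALSE]
  relay_pairs <- iu[is_relay, , drop = FALSE]
  # pitted pairs often share several pit fields at different heights
  if (nrow(pit_pairs) > 0 && spec$pit_multiplicity > 0) {
    reps <- 1 + stats::rpois(nrow(pit_pairs), spec$pit_multiplicity)
    pit_pairs <- pit_pairs[rep(seq_len(nrow(pit_pairs)), reps), ,
                           drop = FALSE]
  }

  L <- spec$sample_length_um
  nodes <- data.frame(id = character(), x = numeric(), y = numeric(),
                      z = numeric(), tag = character(),
                      stringsAsFactors = FALSE)
  add_node <- function(id, x, y, z, tag)
    rbind(nodes, data.frame(id = id, x = x, y = y, z = z, tag = tag,
                            stringsAsFactors = FALSE))
  for (v in seq_len(n)) {
    nodes <- add_node(sprintf("v%d_b", v), xs[v], ys[v], 0, "bottom")
    nodes <- add_node(sprintf("v%d_t", v), xs[v], ys[v], L, "top")
  }
  conn <- data.frame(kind = character(), node_a = character(),
                     node_b = character(), area_mm2 = numeric(),
                     diam_um = numeric(), stringsAsFactors = FALSE)
  vessel_node <- function(v, z, k) {
    id <- sprintf("v%d_c%d", v, k)
    nodes <<- add_node(id, xs[v], ys[v], z, "interior")
    id
  }
  cid <- 0
  if (nrow(pit_pairs)) {
    areas <- .rlnorm_trunc(nrow(pit_pairs), spec$pit_area_mean_mm2,
                           spec$pit_area_sd_mm2, 1e-5)
    zs <- stats::runif(nrow(pit_pairs), 0.05 * L, 0.95 * L)
    for (k in seq_len(nrow(pit_pairs))) {
      cid <- cid + 1
      na <- vessel_node(pit_pairs[k, 1], zs[k], cid)
      nb <- vessel_node(pit_pairs[k, 2], zs[k], cid)
      conn <- rbind(conn, data.frame(kind = "pit_field", node_a = na,
                                     node_b = nb, area_mm2 = areas[k],
                                     diam_um = NA_real_))
    }
  }
  if (nrow(relay_pairs)) {
    r_area <- .rlnorm_trunc(2 * nrow(relay_pairs), spec$pit_area_mean_mm2,
                            spec$pit_area_sd_mm2, 1e-5)
    r_diam <- .rlnorm_trunc(nrow(relay_pairs), spec$relay_diam_mean_um,
                            spec$relay_diam_sd_um, spec$min_relay_diam_um)
    zs <- stats::runif(nrow(relay_pairs), 0.05 * L, 0.95 * L)
    for (k in seq_len(nrow(relay_pairs))) {
      cid <- cid + 1
      v1 <- relay_pairs[k, 1]; v2 <- relay_pairs[k, 2]
      na <- vessel_node(v1, zs[k], cid)
      nb <- vessel_node(v2, zs[k], cid)
      r1 <- sprintf("r%d_1", cid); r2 <- sprintf("r%d_2", cid)
      nodes <- add_node(r1, xs[v1] + (xs[v2] - xs[v1]) / 3,
                        ys[v1] + (ys[v2] - ys[v1]) / 3, zs[k], "interior")
      nodes <- add_node(r2, xs[v1] + 2 * (xs[v2] - xs[v1]) / 3,
                        ys[v1] + 2 * (ys[v2] - ys[v1]) / 3, zs[k], "interior")
      conn <- rbind(conn,
        data.frame(kind = c("relay_pit", "relay_lumen", "relay_pit"),
                   node_a = c(na, r1, r2), node_b = c(r1, r2, nb),
                   area_mm2 = c(r_area[2 * k - 1], NA, r_area[2 * k]),
                   diam_um = c(NA, r_diam[k], NA)))
    }
  }

  lum <- do.call(rbind, lapply(seq_len(n), function(v) {
    ids <- nodes$id[nodes$id %in%
                      c(sprintf("v%d_b", v), sprintf("v%d_t", v)) |
                    grepl(sprintf("^v%d_c", v), nodes$id)]
    zz <- nodes$z[match(ids, nodes$id)]
    ord <- order(zz)
    ids <- ids[ord]
    data.frame(vessel_id = v, node_a = ids[-length(ids)], node_b = ids[-1],
               radius_um = rad[v], stringsAsFactors = FALSE)
  }))

  area_mm2 <- pi * (spec$stem_radius_um^2 - spec$pith_radius_um^2) * 1e-6
  net <- vessel_network(nodes, lum, conn, sample_length_um = L,
                        xylem_area_mm2 = area_mm2, fluid = spec$fluid)
  list(network = net, vessels = vessels)
}

#' Domain mask for a pixel grid
#'
#' Labels each pixel centre by its radial and tangential domain
#' ("inner.dorsal_ventral", "outer.lateral", ...) or "excluded" outside
#' the xylem annulus.
#'
#' @param grid A grid (see [default_grid()]).
#' @param spec The [synthetic_spec()] describing the geometry.
#' @return Character matrix of labels.
#' @export
domain_mask <- function(grid, spec) {
  xc <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$pixel_size_um
  yc <- grid$y0 - (seq_len(grid$ny) - 0.5) * grid$pixel_size_um
  xm <- matrix(xc, grid$ny, grid$nx, byrow = TRUE)
  ym <- matrix(yc, grid$ny, grid$nx)
  r <- sqrt(xm^2 + ym^2)
  th <- atan2(ym, xm)
  lab <- paste(.radial_domain(r, spec), .tangential_domain(th), sep = ".")
  lab[r < spec$pith_radius_um | r > spec$stem_radius_um] <- "excluded"
  matrix(lab, grid$ny, grid$nx)
}

# per-group pressure drops for the spec's generator model
.true_drops <- function(spec, network, groups, drops_table = NULL) {
  m <- max(groups$group)
  switch(spec$pressure_model,
    uniform = rep(spec$uniform_drop_kPa, m),
    per_group_uniform = stats::runif(m, spec$drop_range_kPa[1],
                                     spec$drop_range_kPa[2]),
    serial_feeder = {
      sens <- .group_sensitivity(network, groups)
      gidx <- groups$group[match(as.numeric(rownames(sens)), groups$vessel_id)]
      K_g <- vapply(seq_len(m), function(g)
        sum(sens[gidx == g, g]), numeric(1))  # group conductance, (ug/s)/kPa
      R_g <- 1 / pmax(K_g, .Machine$double.eps)
      R_f <- hp_lumen_resistance(spec$feeder_radius_um,
                                 spec$sample_length_um, spec$fluid)
      spec$system_drop_kPa * R_g / (R_g + R_f)
    },
    table = {
      if (is.null(drops_table) || length(drops_table) != m)
        stop("pressure model 'table' needs one drop per group")
      drops_table
    })
}

#' Forward-simulate an observed flow map with known truth
#'
#' Solves the network under true boundary pressures, downsamples to the
#' pixel grid (noiseless map), then adds independent zero-mean Gaussian
#' noise to every nonzero pixel and applies the registration jitter
#' (noisy map).
#'
#' @param network A [vessel_network()].
#' @param bc True [boundary_conditions()].
#' @param grid Pixel grid; defaults to [default_grid()] at the spec's
#'   pixel size.
#' @param noise_sd_ug_s,jitter_um Noise SD and rigid jitter.
#' @param seed Seed for the noise draw.
#' @param mask Optional mask matrix attached to both maps.
#' @return list of class `synthetic_truth`: network, bc, solution,
#'   noiseless and noisy [flow_map()]s, seed.
#' @export
forward_flow_map <- function(network, bc, grid, noise_sd_ug_s = 0,
                             jitter_um = c(0, 0), seed = 1, mask = NULL) {
  sol <- solve_flow(network, bc)
  noiseless <- suppressWarnings(
    downsample_to_pixels(sol, network, grid, c(0, 0), mask))
  set.seed(seed)
  noisy <- suppressWarnings(
    downsample_to_pixels(sol, network, grid, jitter_um, mask))
  nz <- noisy$values != 0
  noisy$values[nz] <- noisy$values[nz] +
    stats::rnorm(sum(nz), 0, noise_sd_ug_s)
  structure(list(network = network, bc = bc, solution = sol,
                 noiseless = noiseless, noisy = noisy, seed = seed),
            class = "synthetic_truth")
}

#' Generate a full synthetic truth instance
#'
#' Network, domain masks, true boundary pressures and noiseless/noisy flow
#' maps from one spec and seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @param drops_table Optional per-group drops for `pressure_model =
#'   "table"`.
#' @return A `synthetic_truth` with extra elements `vessels`, `groups`,
#'   `true_drops_kPa`, `grid` and `spec`.
#' @export
generate_synthetic_truth <- function(spec, seed, drops_table = NULL) {
  gen <- generate_network(spec, seed)
  net <- gen$network
  groups <- vessel_groups(net)
  set.seed(seed + 1)
  drops <- .true_drops(spec, net, groups, drops_table)
  bc <- boundary_conditions(stats::setNames(-drops, seq_along(drops)))
  grid <- default_grid(net, spec$pixel_size_um)
  mask <- domain_mask(grid, spec)
  truth <- forward_flow_map(net, bc, grid, spec$noise_sd_ug_s,
                            spec$jitter_um, seed = seed + 2, mask = mask)
  truth$vessels <- gen$vessels
  truth$groups <- groups
  truth$true_drops_kPa <- drops
  truth$grid <- grid
  truth$spec <- spec
  truth
}

#' Uniquely observable vessel groups
#'
#' A group is counted observable when at least one included pixel is
#' occupied by that group alone (a "private" pixel), which pins its
#' pressure in a noiseless fit; groups seen only through shared pixels are
#' not individually identifiable.
#'
#' @param truth A [generate_synthetic_truth()] result.
#' @return Integer vector of observable group ids.
#' @export
observable_groups <- function(truth) {
  grid <- truth$grid
  include <- include_from_mask(truth$noiseless)
  xy <- .vessel_top_xy(truth$network)
  j <- floor((xy[, 1] - grid$x0) / grid$pixel_size_um) + 1
  i <- floor((grid$y0 - xy[, 2]) / grid$pixel_size_um) + 1
  ok <- i >= 1 & i <= grid$ny & j >= 1 & j <= grid$nx
  ok[ok] <- include[cbind(i[ok], j[ok])]
  pix <- (j - 1) * grid$ny + i
  g <- truth$groups$group[match(seq_len(nrow(xy)), truth$groups$vessel_id)]
  by_pix <- tapply(g[ok], pix[ok], unique)
  solo <- vapply(by_pix, length, integer(1)) == 1
  sort(unique(unlist(by_pix[solo])))
}

#' Pressure-recovery experiment over seeds
#'
#' For each seed: generate a synthetic truth, fit per-group pressures to
#' the noisy map, and record recovery metrics.
#'
#' @param spec A [synthetic_spec()].
#' @param seeds Integer vector of seeds.
#' @return data.frame with one row per seed: median and maximal absolute
#'   drop error over observable groups (kPa), NSE of the fitted map,
#'   objective, numbers of groups and observable groups.
#' @export
recovery_experiment <- function(spec, seeds) {
  rows <- lapply(seeds, function(s) {
    truth <- generate_synthetic_truth(spec, s)
    fit <- fit_group_pressures(truth$network, truth$noisy)
    obs <- observable_groups(truth)
    err <- abs(fit$drops_kPa[obs] - truth$true_drops_kPa[obs])
    data.frame(seed = s,
               median_abs_error_kPa = stats::median(err),
               max_abs_error_kPa = max(err),
               nse = fit$nse,
               objective = fit$objective,
               n_groups = length(truth$true_drops_kPa),
               n_observable = length(obs))
  })
  do.call(rbind, rows)
}
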