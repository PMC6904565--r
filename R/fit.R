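# Inverse estimation of top boundary pressures from an observed flow map.
# All three scenarios exploit the linearity of the forward model: flows are
# linear in the imposed pressure drops, so the uniform fit is closed-form
# and the per-group fit is a bound-constrained linear least-squares problem
# whose sensitivity matrix comes from one unit-pressure solve per group.

# grid description of an observed map
.grid_of <- function(map) {
  list(pixel_size_um = map$pixel_size_um, x0 = map$x0, y0 = map$y0,
       nx = ncol(map$values), ny = nrow(map$values))
}

.new_fit_result <- function(scenario, drops, network, observed, include,
                            offset_um, k, clamped = integer(0)) {
  groups <- vessel_groups(network)
  top <- if (length(drops) == 1) -drops else -drops[groups$group]
  bc <- boundary_conditions(if (length(drops) == 1) -drops else
    stats::setNames(-drops, seq_along(drops)))
  sol <- solve_flow(network, bc)
  grid <- .grid_of(observed)
  model <- suppressWarnings(
    downsample_to_pixels(sol, network, grid, offset_um, mask = observed$mask))
  ro <- residual_objective(model, observed, include, k = k)
  o <- observed$values[include]
  m <- model$values[include]
  nse_val <- if (stats::sd(o) > 0) nse(o, m) else NA_real_
  obs_tot <- sum(o)
  structure(list(
    scenario = scenario,
    drops_kPa = drops,
    top_pressures_kPa = -drops,
    solution = sol,
    model_map = model,
    residual = ro$residual,
    smoothed_residual = ro$smoothed,
    objective = ro$objective,
    nse = nse_val,
    total_flow_rel_error = if (obs_tot != 0) (sum(m) - obs_tot) / obs_tot else NA_real_,
    vessels = sol$vessels,
    groups = sol$groups,
    clamped_groups = clamped,
    include = include,
    smoothing_k = k,
    offset_um = offset_um), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s]: objective %.6g, NSE %.4f, total-flow error %.2f%%\n",
              x$scenario, x$objective, x$nse, 100 * x$total_flow_rel_error))
  if (length(x$drops_kPa) > 1)
    cat(sprintf("  %d group pressure drops in [%.4g, %.4g] kPa (%d clamped)\n",
                length(x$drops_kPa), min(x$drops_kPa), max(x$drops_kPa),
                length(x$clamped_groups)))
  else
    cat(sprintf("  pressure drop %.6g kPa\n", x$drops_kPa))
  invisible(x)
}

#' Fit a single uniform top pressure
#'
#' Finds the scalar pressure drop whose forward flow map best matches the
#' observation under the windowed residual objective. The forward map is
#' linear in the drop, so the minimizer is closed-form from one
#' unit-pressure solve.
#'
#' @param network A [vessel_network()].
#' @param observed Observed [flow_map()].
#' @param include Optional logical matrix of pixels entering the objective
#'   (defaults to the map's mask without "excluded" pixels); pass e.g.
#'   `include_from_mask(observed, c("excluded", "outer"))` to mask the
#'   outer domain.
#' @param offset_um Registration offset applied to vessel centroids.
#' @param smooth Apply the 5x5 residual averaging (TRUE) or fit raw
#'   residuals (FALSE).
#' @return A `fit_result` (scenario "uniform").
#' @export
fit_uniform_pressure <- function(network, observed, include = NULL,
                                 offset_um = c(0, 0), smooth = TRUE) {
  if (is.null(include)) include <- include_from_mask(observed)
  if (all(observed$values[include] == 0))
    stop("fit_uniform_pressure: observed map is all zero on included pixels")
  k <- if (smooth) 5 else 1
  grid <- .grid_of(observed)
  unit <- solve_flow(network, boundary_conditions(-1))
  m1 <- suppressWarnings(downsample_to_pixels(unit, network, grid, offset_um))
  s_m <- box_smooth(`[<-`(m1$values, !include, 0), include, k = k)[include]
  s_o <- box_smooth(`[<-`(observed$values, !include, 0), include, k = k)[include]
  denom <- sum(s_m^2)
  if (denom == 0) stop("fit_uniform_pressure: network produces no flow on included pixels")
  drop <- max(sum(s_m * s_o) / denom, 0)
  .new_fit_result("uniform", drop, network, observed, include, offset_um, k)
}

#' Fit the pressure drop matching total flow
#'
#' Exact scalar: observed total flow divided by the total flow of a
#' unit-pressure solve.
#'
#' @param network A [vessel_network()].
#' @param observed_total Observed total flow in ug s-1 (> 0).
#' @param observed Optional observed [flow_map()] used to populate the
#'   modelled raster, NSE and residuals of the result.
#' @param include,offset_um,smooth As in [fit_uniform_pressure()].
#' @return A `fit_result` (scenario "total_flow"); when `observed` is NULL
#'   only the drop and the forward solution are populated.
#' @export
fit_total_flow <- function(network, observed_total, observed = NULL,
                           include = NULL, offset_um = c(0, 0), smooth = TRUE) {
  if (!is.finite(observed_total) || observed_total <= 0)
    stop("fit_total_flow: observed_total must be positive")
  unit <- solve_flow(network, boundary_conditions(-1))
  K <- total_top_flow(unit)
  if (K == 0) stop("fit_total_flow: network has zero conductance")
  drop <- observed_total / K
  if (is.null(observed)) {
    bc <- boundary_conditions(-drop)
    sol <- solve_flow(network, bc)
    return(structure(list(scenario = "total_flow", drops_kPa = drop,
                          top_pressures_kPa = -drop, solution = sol,
                          vessels = sol$vessels, groups = sol$groups,
                          objective = NA_real_, nse = NA_real_,
                          total_flow_rel_error = 0), class = "fit_result"))
  }
  if (is.null(include)) include <- include_from_mask(observed)
  .new_fit_result("total_flow", drop, network, observed, include, offset_um,
                  if (smooth) 5 else 1)
}

# per-group unit-drop sensitivity: vessel top flows for a unit (1 kPa)
# pressure drop applied to each group separately. One sparse factorization,
# one multi-RHS solve.
.group_sensitivity <- function(network, groups) {
  edges <- .network_edges(network)
  nd <- network$nodes
  ids <- nd$id
  ia <- match(edges$node_a, ids)
  ib <- match(edges$node_b, ids)
  g <- 1 / edges$resistance
  n <- length(ids)
  L <- Matrix::sparseMatrix(i = c(ia, ib, ia, ib), j = c(ia, ib, ib, ia),
                            x = c(g, g, -g, -g), dims = c(n, n))
  fixed_idx <- which(nd$tag %in% c("top", "bottom"))
  free <- setdiff(seq_len(n), fixed_idx)
  m <- max(groups$group)
  nodev <- .node_vessel(network)
  top_idx <- which(nd$tag == "top")
  top_group <- groups$group[match(nodev[top_idx], groups$vessel_id)]
  Pf <- matrix(0, length(fixed_idx), m)
  rows <- match(top_idx, fixed_idx)
  Pf[cbind(rows, top_group)] <- -1  # unit drop: top at -1 kPa, bottom 0
  rhs <- -L[free, fixed_idx, drop = FALSE] %*% Pf
  Pfree <- as.matrix(Matrix::solve(L[free, free, drop = FALSE], rhs))
  P <- matrix(0, n, m)
  P[fixed_idx, ] <- Pf
  P[free, ] <- Pfree
  # per-vessel top lumen edge
  lu_idx <- which(edges$type == "lumen")
  lu <- network$lumens
  zt <- nd$z[match(edges$node_b[lu_idx], nd$id)]
  vids <- sort(unique(lu$vessel_id))
  top_edge <- vapply(vids, function(v) {
    i <- which(lu$vessel_id == v)
    lu_idx[i[which.max(zt[i])]]
  }, numeric(1))
  vf <- (P[ia[top_edge], , drop = FALSE] - P[ib[top_edge], , drop = FALSE]) *
    g[top_edge]
  rownames(vf) <- vids
  vf  # n_vessels x n_groups
}

# symmetric pseudo-solve: unidentifiable directions (groups with
# perfectly shared pixel footprints) take the minimum-norm component
# instead of poisoning the identifiable ones
.psolve_sym <- function(A, b) {
  e <- eigen(A, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-12
  if (!any(keep)) return(rep(0, length(b)))
  as.numeric(e$vectors[, keep, drop = FALSE] %*%
    ((crossprod(e$vectors[, keep, drop = FALSE], b)) / e$values[keep]))
}

# non-negative least squares on the raw design matrix. Active-set scheme
# warm-started from the full passive set: rank-revealing (SVD) solves keep
# full precision on near-collinear footprints and give unidentifiable
# directions their minimum-norm component; negative coordinates are
# released to the bound and zero-bound coordinates with positive gradient
# re-enter until the KKT conditions hold.
.nnls_design <- function(B, y, maxit = 200) {
  m <- ncol(B)
  lsq <- function(P) {
    sv <- svd(B[, P, drop = FALSE])
    keep <- sv$d > max(sv$d) * 1e-12
    as.numeric(sv$v[, keep, drop = FALSE] %*%
      (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep]))
  }
  P <- rep(TRUE, m)
  d <- numeric(m)
  Bty <- as.numeric(crossprod(B, y))
  wtol <- 1e-9 * max(abs(Bty), .Machine$double.xmin)
  for (it in seq_len(maxit)) {
    x <- lsq(P)
    xtol <- 1e-9 * max(abs(x), 1)
    while (any(x < -xtol)) {
      drop_i <- which(P)[x < -xtol]
      P[drop_i] <- FALSE
      if (!any(P)) break
      x <- lsq(P)
      xtol <- 1e-9 * max(abs(x), 1)
    }
    d[] <- 0
    if (any(P)) d[P] <- pmax(x, 0)
    w <- Bty - as.numeric(crossprod(B, B %*% d))
    cand <- which(!P & w > wtol)
    if (length(cand) == 0) break
    P[cand[which.max(w[cand])]] <- TRUE
  }
  d
}

# bound-constrained linear least squares. With only a lower bound at zero
# (the default sign-constrained drops) this is non-negative least squares
# on the raw design; with finite bounds an L-BFGS-B start on the normal
# equations is refined by active-set polishing.
.bounded_lsq <- function(B, y, lower, upper, init,
                         maxit = 500, tol = 1e-12) {
  m <- ncol(B)
  if (all(lower == 0) && all(!is.finite(upper)))
    return(.nnls_design(B, y))
  BtB <- crossprod(B)
  Bty <- as.numeric(crossprod(B, y))
  fn <- function(d) 0.5 * sum(d * (BtB %*% d)) - sum(d * Bty)
  gr <- function(d) as.numeric(BtB %*% d - Bty)
  d <- stats::optim(pmin(pmax(init, lower), upper), fn, gr,
                    method = "L-BFGS-B", lower = lower, upper = upper,
                    control = list(maxit = maxit, factr = 10))$par
  scale <- max(abs(Bty), 1)
  for (it in seq_len(100)) {
    g <- gr(d)
    at_lo <- d <= lower + tol * scale
    at_up <- d >= upper - tol * scale
    F <- which(!((at_lo & g >= -1e-10 * scale) | (at_up & g <= 1e-10 * scale)))
    if (length(F) == 0) break
    rhs <- Bty[F]
    if (length(F) < m)
      rhs <- rhs - BtB[F, -F, drop = FALSE] %*% d[-F]
    x <- .psolve_sym(BtB[F, F, drop = FALSE], rhs)
    d_new <- d
    d_new[F] <- pmin(pmax(as.numeric(x), lower[F]), upper[F])
    if (max(abs(d_new - d)) < tol * scale) {
      d <- d_new
      break
    }
    d <- d_new
  }
  d
}

#' Fit independent top pressures per vessel group
#'
#' Because flows are linear in the pressure vector, the sensitivity matrix
#' is assembled from one unit-pressure solve per group and the windowed
#' objective becomes a bound-constrained linear least-squares problem in
#' the per-group pressure drops. Groups with no footprint on any included
#' pixel are unidentifiable and clamped to zero drop.
#'
#' @inheritParams fit_uniform_pressure
#' @param lower,upper Bounds on the per-group pressure drops in kPa
#'   (defaults 0 and Inf: sign-constrained drops).
#' @param init Optional initial drop vector; defaults to the uniform-fit
#'   best drop broadcast to all groups.
#' @return A `fit_result` (scenario "per_group") whose `drops_kPa` is the
#'   fitted per-group drop vector, with `clamped_groups` listing groups
#'   clamped for lack of observability.
#' @export
fit_group_pressures <- function(network, observed, include = NULL,
                                offset_um = c(0, 0), smooth = TRUE,
                                lower = 0, upper = Inf, init = NULL) {
  if (is.null(include)) include <- include_from_mask(observed)
  k <- if (smooth) 5 else 1
  grid <- .grid_of(observed)
  groups <- vessel_groups(network)
  m <- max(groups$group)
  sens <- .group_sensitivity(network, groups)  # vessels x groups

  # vessel -> pixel binning (same rule as downsample_to_pixels)
  xy <- .vessel_top_xy(network)
  j <- floor((xy[, 1] + offset_um[1] - grid$x0) / grid$pixel_size_um) + 1
  i <- floor((grid$y0 - (xy[, 2] + offset_um[2])) / grid$pixel_size_um) + 1
  inside <- i >= 1 & i <= grid$ny & j >= 1 & j <= grid$nx
  pix <- (j - 1) * grid$ny + i  # linear index, column-major

  B <- matrix(0, sum(include), m)
  for (gcol in seq_len(m)) {
    vsel <- which(inside & sens[, gcol] != 0)
    if (length(vsel) == 0) next
    raster <- matrix(0, grid$ny, grid$nx)
    for (v in vsel) raster[pix[v]] <- raster[pix[v]] + sens[v, gcol]
    B[, gcol] <- box_smooth(raster, include, k = k)[include]
  }
  y <- box_smooth(`[<-`(observed$values, !include, 0), include, k = k)[include]

  observable <- colSums(B != 0) > 0
  clamped <- which(!observable)
  drops <- numeric(m)
  if (any(observable)) {
    Bo <- B[, observable, drop = FALSE]
    mo <- sum(observable)
    lo <- rep_len(lower, mo)
    up <- rep_len(upper, mo)
    if (is.null(init)) {
      u <- tryCatch(fit_uniform_pressure(network, observed, include,
                                         offset_um, smooth)$drops_kPa,
                    error = function(e) 0)
      init_o <- rep(u, mo)
    } else init_o <- rep_len(init, m)[observable]
    drops[observable] <- .bounded_lsq(Bo, y, lo, up, init_o)
  }
  res <- .new_fit_result("per_group", drops, network, observed, include,
                         offset_um, k, clamped = clamped)
  attr(res, "observable") <- observable
  res
}
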