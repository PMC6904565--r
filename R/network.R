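#' Construct a vessel network
#'
#' A spatial resistance graph of xylem vessels. Nodes carry 3-D positions
#' and a boundary tag; vessel lumina are axial chains of cylindrical
#' segments; connections are inter-vessel pit fields, or vessel relays
#' decomposed into two relay pit fields bridged by a narrow relay lumen.
#'
#' @param nodes data.frame(id, x, y, z, tag) with positions in um and tag
#'   one of "top", "bottom", "interior". Node ids must be unique; all top
#'   nodes must share the maximal z and all bottom nodes the minimal z
#'   (within tolerance).
#' @param lumens data.frame(vessel_id, node_a, node_b, radius_um). Each
#'   vessel's segments must form a simple path in z.
#' @param connections data.frame(kind, node_a, node_b, area_mm2, diam_um)
#'   with kind in "pit_field", "relay_pit" (area_mm2 used) or "relay_lumen"
#'   (diam_um used). May have zero rows.
#' @param sample_length_um Axial extent of the sample in um.
#' @param xylem_area_mm2 Cross-sectional xylem area in mm2.
#' @param fluid A [fluid_constants()] object.
#' @return An object of class `vessel_network`.
#' @export
vessel_network <- function(nodes, lumens, connections = NULL,
                           sample_length_um, xylem_area_mm2,
                           fluid = fluid_constants()) {
  stopifnot(is.data.frame(nodes), is.data.frame(lumens))
  nodes <- as.data.frame(nodes)[c("id", "x", "y", "z", "tag")]
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id))
    stop("vessel_network: node ids must be unique")
  if (!all(nodes$tag %in% c("top", "bottom", "interior")))
    stop("vessel_network: node tag must be top, bottom or interior")
  tol <- 1e-6 * max(1, sample_length_um)
  zt <- nodes$z[nodes$tag == "top"]
  zb <- nodes$z[nodes$tag == "bottom"]
  if (length(zt) && diff(range(zt)) > tol)
    stop("vessel_network: top nodes must share maximal z")
  if (length(zb) && diff(range(zb)) > tol)
    stop("vessel_network: bottom nodes must share minimal z")

  lumens <- as.data.frame(lumens)[c("vessel_id", "node_a", "node_b", "radius_um")]
  lumens$node_a <- as.character(lumens$node_a)
  lumens$node_b <- as.character(lumens$node_b)
  if (any(lumens$radius_um <= 0))
    stop("vessel_network: lumen radii must be positive")
  if (any(!lumens$node_a %in% nodes$id) || any(!lumens$node_b %in% nodes$id))
    stop("vessel_network: lumen endpoint not in node table")
  # orient each segment from lower to upper z so positive flow points up
  za <- nodes$z[match(lumens$node_a, nodes$id)]
  zb2 <- nodes$z[match(lumens$node_b, nodes$id)]
  if (any(abs(za - zb2) <= 0))
    stop("vessel_network: lumen segment with zero axial extent")
  swap <- za > zb2
  tmp <- lumens$node_a[swap]
  lumens$node_a[swap] <- lumens$node_b[swap]
  lumens$node_b[swap] <- tmp

  if (is.null(connections) || nrow(connections) == 0) {
    connections <- data.frame(kind = character(), node_a = character(),
                              node_b = character(), area_mm2 = numeric(),
                              diam_um = numeric(), stringsAsFactors = FALSE)
  } else {
    connections <- as.data.frame(connections)
    for (col in c("area_mm2", "diam_um"))
      if (is.null(connections[[col]])) connections[[col]] <- NA_real_
    connections <- connections[c("kind", "node_a", "node_b", "area_mm2", "diam_um")]
    connections$node_a <- as.character(connections$node_a)
    connections$node_b <- as.character(connections$node_b)
    if (!all(connections$kind %in% c("pit_field", "relay_pit", "relay_lumen")))
      stop("vessel_network: unknown connection kind")
    pit <- connections$kind %in% c("pit_field", "relay_pit")
    if (any(!is.finite(connections$area_mm2[pit]) | connections$area_mm2[pit] <= 0))
      stop("vessel_network: pit connections need area_mm2 > 0")
    rl <- connections$kind == "relay_lumen"
    if (any(!is.finite(connections$diam_um[rl]) | connections$diam_um[rl] <= 0))
      stop("vessel_network: relay lumina need diam_um > 0")
    if (any(connections$node_a == connections$node_b))
      stop("vessel_network: self-loop connection")
  }

  net <- structure(list(
    nodes = nodes, lumens = lumens, connections = connections,
    sample_length_um = sample_length_um, xylem_area_mm2 = xylem_area_mm2,
    fluid = fluid), class = "vessel_network")
  net
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf(
    "vessel_network: %d vessels, %d nodes, %d lumen segments, %d connection edges\n",
    length(unique(x$lumens$vessel_id)), nrow(x$nodes), nrow(x$lumens),
    nrow(x$connections)))
  cat(sprintf("  sample length %.0f um, xylem area %.2f mm2\n",
              x$sample_length_um, x$xylem_area_mm2))
  invisible(x)
}

# edge table with resistances in internal units; order: lumens then connections
.network_edges <- function(network) {
  nd <- network$nodes
  lu <- network$lumens
  co <- network$connections
  pos <- function(idv) {
    i <- match(idv, nd$id)
    cbind(nd$x[i], nd$y[i], nd$z[i])
  }
  seglen <- function(a, b) sqrt(rowSums((pos(a) - pos(b))^2))
  edges <- data.frame(
    node_a = c(lu$node_a, co$node_a),
    node_b = c(lu$node_b, co$node_b),
    type = c(rep("lumen", nrow(lu)), co$kind),
    stringsAsFactors = FALSE)
  Rl <- if (nrow(lu)) hp_lumen_resistance(lu$radius_um,
                                          seglen(lu$node_a, lu$node_b),
                                          network$fluid) else numeric()
  Rc <- numeric(nrow(co))
  if (nrow(co)) {
    pit <- co$kind %in% c("pit_field", "relay_pit")
    if (any(pit))
      Rc[pit] <- pit_connection_resistance(co$area_mm2[pit], fluid = network$fluid)
    rl <- co$kind == "relay_lumen"
    if (any(rl))
      Rc[rl] <- hp_lumen_resistance(co$diam_um[rl] / 2,
                                    pmax(seglen(co$node_a[rl], co$node_b[rl]), 1),
                                    network$fluid)
  }
  edges$resistance <- c(Rl, Rc)
  edges
}

# vessel id owning each node (NA for relay/boundary-only nodes)
.node_vessel <- function(network) {
  lu <- network$lumens
  v <- c(lu$vessel_id, lu$vessel_id)
  n <- c(lu$node_a, lu$node_b)
  v[match(network$nodes$id, n)]
}

#' Partition vessels into connected groups
#'
#' Vessel groups are the connected components of the network: vessels
#' linked by pit fields or relays share a group; solitary vessels form
#' singleton groups.
#'
#' @param network A [vessel_network()].
#' @return data.frame(vessel_id, group) with one row per vessel; group ids
#'   are integers `1..n_groups`, numbered by the smallest member vessel id.
#' @export
vessel_groups <- function(network) {
  ids <- network$nodes$id
  ea <- c(network$lumens$node_a, network$connections$node_a)
  eb <- c(network$lumens$node_b, network$connections$node_b)
  gr <- igraph::graph_from_data_frame(
    data.frame(from = ea, to = eb), directed = FALSE,
    vertices = data.frame(name = ids))
  memb <- igraph::components(gr)$membership
  nodev <- .node_vessel(network)
  vids <- sort(unique(network$lumens$vessel_id))
  vcomp <- vapply(vids, function(v) {
    unname(memb[ids[which(nodev == v)[1]]])
  }, numeric(1))
  # renumber components by smallest member vessel id for stability
  mins <- tapply(vids, vcomp, min)
  ord_comp <- names(sort(mins))
  relabel <- match(as.character(vcomp), ord_comp)
  data.frame(vessel_id = vids, group = relabel)
}

#' Boundary conditions for a flow solve
#'
#' @param top_kPa Either a single pressure applied to every top node, or a
#'   vector with one pressure per vessel group (named by group id or in
#'   group order).
#' @param bottom_kPa Reference pressure at the bottom boundary (default 0).
#' @return list of class `boundary_conditions`.
#' @export
boundary_conditions <- function(top_kPa, bottom_kPa = 0) {
  stopifnot(all(is.finite(top_kPa)), is.finite(bottom_kPa))
  structure(list(top_kPa = top_kPa, bottom_kPa = bottom_kPa),
            class = "boundary_conditions")
}

# named vector of fixed pressures for a network + bc
.fixed_pressures <- function(network, bc, groups = NULL) {
  nd <- network$nodes
  fixed <- numeric(0)
  bot <- nd$id[nd$tag == "bottom"]
  top <- nd$id[nd$tag == "top"]
  if (length(bc$top_kPa) == 1) {
    p_top <- rep(bc$top_kPa, length(top))
  } else {
    if (is.null(groups)) groups <- vessel_groups(network)
    nodev <- .node_vessel(network)
    gv <- groups$group[match(nodev[match(top, nd$id)], groups$vessel_id)]
    tp <- bc$top_kPa
    if (!is.null(names(tp))) {
      p_top <- tp[as.character(gv)]
      if (any(is.na(p_top)))
        stop("boundary_conditions: missing pressure for some vessel group")
    } else {
      if (length(tp) != max(groups$group))
        stop("boundary_conditions: need one top pressure per vessel group")
      p_top <- tp[gv]
    }
    p_top <- as.numeric(p_top)
  }
  fixed <- c(stats::setNames(rep(bc$bottom_kPa, length(bot)), bot),
             stats::setNames(p_top, top))
  fixed
}

#' Solve steady flow on a vessel network
#'
#' Assembles lumen and connection resistances and solves Kirchhoff node
#' balance with Dirichlet pressures on the top and bottom boundaries.
#' Positive lumen flow points upward (+z).
#'
#' @param network A [vessel_network()].
#' @param bc A [boundary_conditions()]; a vector `top_kPa` is broadcast to
#'   each vessel group's top nodes.
#' @return An object of class `flow_solution`: node `pressures` (kPa), the
#'   edge table with `flow_ug_s`, per-vessel summary `vessels`
#'   (top/bottom slice flow in ug/s, axial gradient in MPa/m, imposed
#'   pressure drop in kPa), and the groups table.
#' @export
solve_flow <- function(network, bc) {
  groups <- vessel_groups(network)
  fixed <- .fixed_pressures(network, bc, groups)
  edges <- .network_edges(network)
  sol <- solve_resistance_network(edges, fixed)
  edges$flow_ug_s <- sol$flows

  nd <- network$nodes
  lu_idx <- which(edges$type == "lumen")
  lu <- network$lumens
  vids <- sort(unique(lu$vessel_id))
  zb <- nd$z[match(edges$node_a[lu_idx], nd$id)]
  zt <- nd$z[match(edges$node_b[lu_idx], nd$id)]
  vflow <- function(pick_top) {
    vapply(vids, function(v) {
      i <- which(lu$vessel_id == v)
      j <- if (pick_top) i[which.max(zt[i])] else i[which.min(zb[i])]
      edges$flow_ug_s[lu_idx[j]]
    }, numeric(1))
  }
  # per-vessel boundary pressures: pressure at the vessel's extreme nodes
  pdrop <- vapply(vids, function(v) {
    i <- which(lu$vessel_id == v)
    nb <- edges$node_a[lu_idx[i[which.min(zb[i])]]]
    nt <- edges$node_b[lu_idx[i[which.max(zt[i])]]]
    sol$pressures[nb] - sol$pressures[nt]
  }, numeric(1))
  vessels <- data.frame(
    vessel_id = vids,
    group = groups$group[match(vids, groups$vessel_id)],
    top_flow_ug_s = vflow(TRUE),
    bottom_flow_ug_s = vflow(FALSE),
    pressure_drop_kPa = pdrop,
    gradient_MPa_m = .kpa_per_um_to_MPa_per_m(pdrop / network$sample_length_um))

  structure(list(pressures = sol$pressures, edges = edges,
                 vessels = vessels, groups = groups, bc = bc,
                 fixed_nodes = names(fixed)),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("flow_solution: %d nodes, total top flow %.4g ug/s\n",
              length(x$pressures), total_top_flow(x)))
  invisible(x)
}

#' Total flow crossing the top boundary
#'
#' @param solution A [solve_flow()] result.
#' @return Summed per-vessel top-slice flow in ug s-1.
#' @export
total_top_flow <- function(solution) sum(solution$vessels$top_flow_ug_s)

#' Signed axial flow of one vessel at a boundary
#'
#' @param solution A [solve_flow()] result.
#' @param vessel_id Vessel identifier.
#' @param at "top" or "bottom" slice.
#' @return Flow in ug s-1 (positive upward).
#' @export
vessel_axial_flow <- function(solution, vessel_id, at = c("top", "bottom")) {
  at <- match.arg(at)
  i <- match(vessel_id, solution$vessels$vessel_id)
  if (is.na(i)) stop(sprintf("vessel_axial_flow: unknown vessel id '%s'", vessel_id))
  if (at == "top") solution$vessels$top_flow_ug_s[i]
  else solution$vessels$bottom_flow_ug_s[i]
}
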