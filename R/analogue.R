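# Ohm's-law analogue networks of heterogeneously connected xylem.
#
# A small normalized resistor network of five vessels in three staggered
# files (two upstream, one central, two downstream), with lumen elements of
# 0.25 normalized units and wall resistors of 1, driven by unit pressure at
# the upstream end node and 0 downstream. The wiring is frozen in a
# versioned fixture; six reference values (three element flows of the most
# heterogeneous variant and the three conductance ratios, see tests)
# over-determine the wiring and act as its acceptance gate. Three variants
# probe heterogeneity:
#   a: all lumina equal;
#   b: bottom-right vessel's lumen resistances doubled (narrower vessel);
#   c: additionally the central vessel's lumen resistances halved (wider).

#' Build an analogue resistor network variant
#'
#' @param panel "a" (homogeneous lumina), "b" (bottom-right vessel lumen
#'   resistances doubled) or "c" (central vessel lumen resistances halved
#'   on top of "b").
#' @param file Path to the network wiring table (defaults to the packaged
#'   fixture).
#' @return list of class `analogue_network` with the edge table (kind,
#'   vessel, element, node_a, node_b, resistance) and the end-node
#'   pressures (U = 1, D = 0 normalized units).
#' @export
build_analogue_network <- function(panel = c("a", "b", "c"),
                                   file = system.file("extdata",
                                                      "ohm_analogue_network.tsv",
                                                      package = "xylemflow")) {
  panel <- match.arg(panel)
  edges <- utils::read.delim(file, stringsAsFactors = FALSE,
                             colClasses = c(resistance = "numeric"))
  lum <- edges$kind == "lumen"
  if (panel %in% c("b", "c"))
    edges$resistance[lum & edges$vessel == "bottom_right"] <-
      edges$resistance[lum & edges$vessel == "bottom_right"] * 2
  if (panel == "c")
    edges$resistance[lum & edges$vessel == "central"] <-
      edges$resistance[lum & edges$vessel == "central"] * 0.5
  structure(list(edges = edges, panel = panel,
                 pressures = c(U = 1, D = 0)),
            class = "analogue_network")
}

#' Solve an analogue network and report element flows
#'
#' Delegates to the Kirchhoff solver with the network's unit end-node
#' pressures and reports each lumen element's flow, oriented from the
#' upstream node towards the downstream node, in normalized units. A
#' vessel's flow is the flow of its conducting element (the element
#' carrying the larger magnitude; the central vessel's downstream element
#' ends blind and carries none).
#'
#' @param network An [build_analogue_network()] result.
#' @return list(elements, vessels, total_flow): per-element and per-vessel
#'   flow tables and the total flow leaving the upstream node.
#' @export
analogue_flows <- function(network) {
  if (!inherits(network, "analogue_network"))
    stop("analogue_flows: not an analogue network")
  sol <- solve_resistance_network(network$edges, network$pressures)
  lum <- network$edges$kind == "lumen"
  el <- network$edges[lum, c("vessel", "element", "node_a", "node_b")]
  el$flow <- sol$flows[lum]
  vessels <- do.call(rbind, lapply(split(el, el$vessel), function(d) {
    data.frame(vessel = d$vessel[1], flow = d$flow[which.max(abs(d$flow))])
  }))
  rownames(vessels) <- NULL
  upstream_edges <- which(network$edges$node_a == "U")
  total <- sum(sol$flows[upstream_edges])
  list(elements = el, vessels = vessels, total_flow = total,
       pressures = sol$pressures)
}

#' Observed-to-theoretical conductance ratio
#'
#' The theoretical conductance is estimated from a quarter-length segment
#' of the network (half the lumina of the central and the two downstream
#' vessels): the lumen conductances of those half-lumina are summed and
#' divided by four to scale to the entire network. The observed conductance
#' is the total flow divided by the end-to-end pressure difference. Their
#' ratio measures how much network heterogeneity and wall resistance
#' depress bulk conductance below the lumen-based ideal.
#'
#' @param network An [build_analogue_network()] result.
#' @return Scalar ratio observed / theoretical.
#' @export
conductance_ratio <- function(network) {
  if (!inherits(network, "analogue_network"))
    stop("conductance_ratio: not an analogue network")
  seg_vessels <- c("central", "top_right", "bottom_right")
  lum <- network$edges[network$edges$kind == "lumen", ]
  if (!all(seg_vessels %in% lum$vessel))
    stop("conductance_ratio: segment vessels not identifiable in this network")
  g_half <- vapply(seg_vessels, function(v) {
    R_total <- sum(lum$resistance[lum$vessel == v])
    1 / (R_total / 2)  # conductance of half the vessel's lumina
  }, numeric(1))
  theoretical <- sum(g_half) / 4
  fl <- analogue_flows(network)
  observed <- fl$total_flow / (network$pressures[["U"]] - network$pressures[["D"]])
  observed / theoretical
}
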