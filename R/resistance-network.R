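#' Solve steady flow on an arbitrary resistance network
#'
#' Kirchhoff node balance on a graph of resistors with Dirichlet (fixed
#' pressure) boundary nodes. The weighted graph Laplacian is assembled
#' sparsely and the interior block solved by a sparse direct method.
#'
#' @param edges data.frame with columns `node_a`, `node_b` (node ids,
#'   coerced to character) and `resistance` (> 0, same units for all edges).
#' @param fixed named numeric vector of boundary pressures; names are node
#'   ids. Every connected component must contain at least one fixed node.
#' @return list with `pressures` (named numeric over all nodes) and `flows`
#'   (numeric per edge, positive from `node_a` to `node_b`, equal to the
#'   pressure difference over the resistance).
#' @export
solve_resistance_network <- function(edges, fixed) {
  stopifnot(is.data.frame(edges),
            all(c("node_a", "node_b", "resistance") %in% names(edges)))
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  R <- as.numeric(edges$resistance)
  if (any(!is.finite(R)) || any(R <= 0))
    stop("solve_resistance_network: all resistances must be positive")
  if (any(a == b))
    stop("solve_resistance_network: self-loop edges are not allowed")
  if (is.null(names(fixed)) || any(!is.finite(fixed)))
    stop("solve_resistance_network: 'fixed' must be a named finite vector")

  ids <- unique(c(a, b, names(fixed)))
  n <- length(ids)
  ia <- match(a, ids)
  ib <- match(b, ids)
  g <- 1 / R

  # components must each see a fixed pressure, otherwise the system is
  # singular; report the offending component instead of a solver failure
  gr <- igraph::graph_from_edgelist(cbind(ia, ib), directed = FALSE)
  if (igraph::vcount(gr) < n) gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
  comp <- igraph::components(gr)$membership
  fixed_idx <- match(names(fixed), ids)
  bad <- setdiff(unique(comp), unique(comp[fixed_idx]))
  if (length(bad) > 0) {
    members <- ids[comp == bad[1]]
    stop(sprintf(
      "solve_resistance_network: component with no fixed-pressure node (%d nodes, e.g. %s)",
      length(members), paste(utils::head(members, 5), collapse = ", ")))
  }

  L <- Matrix::sparseMatrix(
    i = c(ia, ib, ia, ib), j = c(ia, ib, ib, ia),
    x = c(g, g, -g, -g), dims = c(n, n))
  free <- setdiff(seq_len(n), fixed_idx)
  p <- numeric(n)
  names(p) <- ids
  p[fixed_idx] <- fixed
  if (length(free) > 0) {
    rhs <- -L[free, fixed_idx, drop = FALSE] %*% fixed
    p[free] <- as.numeric(Matrix::solve(L[free, free, drop = FALSE], rhs))
  }
  flows <- (p[ia] - p[ib]) * g
  names(flows) <- NULL
  list(pressures = p, flows = flows)
}

# interior-node balance residuals; used by tests and by solve_flow's
# self-check. Returns max |net flow| / (sum |incident flow| + eps), where
# eps is the largest nodal throughflow so that dead-end nodes carrying
# numerically zero flow do not register spurious imbalance.
.conservation_residual <- function(edges, solution, fixed_names) {
  a <- as.character(edges$node_a)
  b <- as.character(edges$node_b)
  f <- solution$flows
  net <- tapply(c(-f, f), c(a, b), sum)
  tot <- tapply(abs(c(f, f)), c(a, b), sum)
  interior <- setdiff(names(net), fixed_names)
  if (length(interior) == 0) return(0)
  eps <- max(tot, .Machine$double.eps)
  max(abs(net[interior]) / (tot[interior] + eps))
}
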