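# small networks and independent oracles built in code

# two parallel solitary vessels of radii r1, r2 spanning the sample
parallel_vessel_network <- function(r1 = 10, r2 = 20, L = 1000) {
  nodes <- data.frame(
    id = c("v1_b", "v1_t", "v2_b", "v2_t"),
    x = c(0, 0, 100, 100), y = 0, z = c(0, L, 0, L),
    tag = c("bottom", "top", "bottom", "top"))
  lumens <- data.frame(vessel_id = c(1, 2),
                       node_a = c("v1_b", "v2_b"),
                       node_b = c("v1_t", "v2_t"),
                       radius_um = c(r1, r2))
  vessel_network(nodes, lumens, NULL, sample_length_um = L,
                 xylem_area_mm2 = 1)
}

# two vessels joined by one pit field at mid-height
pitted_pair_network <- function(area_mm2 = 0.015, L = 1000) {
  nodes <- data.frame(
    id = c("v1_b", "v1_m", "v1_t", "v2_b", "v2_m", "v2_t"),
    x = c(0, 0, 0, 60, 60, 60), y = 0,
    z = c(0, L / 2, L, 0, L / 2, L),
    tag = c("bottom", "interior", "top", "bottom", "interior", "top"))
  lumens <- data.frame(
    vessel_id = c(1, 1, 2, 2),
    node_a = c("v1_b", "v1_m", "v2_b", "v2_m"),
    node_b = c("v1_m", "v1_t", "v2_m", "v2_t"),
    radius_um = c(15, 15, 25, 25))
  conns <- data.frame(kind = "pit_field", node_a = "v1_m", node_b = "v2_m",
                      area_mm2 = area_mm2, diam_um = NA_real_)
  vessel_network(nodes, lumens, conns, sample_length_um = L,
                 xylem_area_mm2 = 1)
}

# random connected resistor network on n nodes with two boundary nodes
random_resistor_network <- function(n, seed) {
  set.seed(seed)
  # spanning tree plus extra edges keeps it connected
  parent <- sapply(2:n, function(i) sample(i - 1, 1))
  edges <- data.frame(node_a = as.character(parent),
                      node_b = as.character(2:n))
  extra <- max(1, round(n / 2))
  ea <- sample(n, extra, replace = TRUE)
  eb <- sample(n, extra, replace = TRUE)
  keep <- ea != eb
  edges <- rbind(edges, data.frame(node_a = as.character(ea[keep]),
                                   node_b = as.character(eb[keep])))
  edges$resistance <- stats::rlnorm(nrow(edges), 0, 1)
  fixed <- c("1" = 1, "2" = 0)  # unit drive between nodes 1 and 2
  list(edges = edges, fixed = fixed)
}

# dense direct-solve oracle for the Kirchhoff system
dense_solve_oracle <- function(edges, fixed) {
  ids <- unique(c(edges$node_a, edges$node_b, names(fixed)))
  n <- length(ids)
  G <- matrix(0, n, n)
  ia <- match(edges$node_a, ids)
  ib <- match(edges$node_b, ids)
  for (k in seq_len(nrow(edges))) {
    g <- 1 / edges$resistance[k]
    G[ia[k], ia[k]] <- G[ia[k], ia[k]] + g
    G[ib[k], ib[k]] <- G[ib[k], ib[k]] + g
    G[ia[k], ib[k]] <- G[ia[k], ib[k]] - g
    G[ib[k], ia[k]] <- G[ib[k], ia[k]] - g
  }
  fi <- match(names(fixed), ids)
  free <- setdiff(seq_len(n), fi)
  p <- numeric(n)
  names(p) <- ids
  p[fi] <- fixed
  p[free] <- solve(G[free, free, drop = FALSE],
                   -G[free, fi, drop = FALSE] %*% fixed)
  p
}

# union-find oracle for vessel group partitions
union_find_groups <- function(network) {
  vids <- sort(unique(network$lumens$vessel_id))
  parent <- stats::setNames(vids, vids)
  find <- function(v) {
    while (parent[[as.character(v)]] != v) v <- parent[[as.character(v)]]
    v
  }
  nodev <- stats::setNames(rep(NA_real_, nrow(network$nodes)),
                           network$nodes$id)
  for (i in seq_len(nrow(network$lumens))) {
    nodev[network$lumens$node_a[i]] <- network$lumens$vessel_id[i]
    nodev[network$lumens$node_b[i]] <- network$lumens$vessel_id[i]
  }
  # relay chains: resolve connections through non-vessel nodes by joining
  # everything reachable through the connection edge list
  co <- network$connections
  if (nrow(co) > 0) {
    # iterative label propagation over connection endpoints
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(co))) {
        va <- nodev[co$node_a[i]]
        vb <- nodev[co$node_b[i]]
        if (is.na(va) && !is.na(vb)) { nodev[co$node_a[i]] <- vb; changed <- TRUE }
        if (is.na(vb) && !is.na(va)) { nodev[co$node_b[i]] <- va; changed <- TRUE }
        va <- nodev[co$node_a[i]]; vb <- nodev[co$node_b[i]]
        if (!is.na(va) && !is.na(vb) && find(va) != find(vb)) {
          parent[[as.character(find(va))]] <- find(vb)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  roots <- vapply(vids, find, numeric(1))
  match(roots, unique(roots))
}

# naive double-loop oracle for the masked k x k moving average
box_smooth_oracle <- function(values, include, k) {
  h <- (k - 1) / 2
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!include[i, j]) next
    acc <- 0; cnt <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && include[ii, jj]) {
        acc <- acc + values[ii, jj]
        cnt <- cnt + 1
      }
    }
    if (cnt > 0) out[i, j] <- acc / cnt
  }
  out
}

# small synthetic spec for fast tests
small_spec <- function(...) {
  synthetic_spec(n_vessels = 80, stem_radius_um = 1000, pith_radius_um = 420,
                 ...)
}
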