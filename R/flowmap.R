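#' Flow-map raster
#'
#' A 2-D raster of mass flow rate per pixel (ug/s), as produced by flow MRI
#' or by downsampling a model solution. Pixels are indexed row-major from
#' the top-left: pixel (i, j) covers x in [x0 + (j-1) px, x0 + j px) and
#' y in (y0 - i px, y0 - (i-1) px].
#'
#' @param values Numeric matrix of per-pixel flow (ug/s).
#' @param pixel_size_um Pixel edge length in um (> 0).
#' @param x0,y0 Physical position (um) of the raster's top-left corner.
#' @param mask Optional character matrix of domain labels, same shape.
#'   Recognized labels combine a radial part ("inner"/"outer") and a
#'   tangential part ("dorsal_ventral"/"lateral") joined by ".", plus
#'   "excluded" for pixels outside the xylem.
#' @return Object of class `flow_map`.
#' @export
flow_map <- function(values, pixel_size_um, x0 = 0, y0 = 0, mask = NULL) {
  stopifnot(is.matrix(values), pixel_size_um > 0)
  if (!is.null(mask)) {
    stopifnot(is.matrix(mask), all(dim(mask) == dim(values)))
    mask <- matrix(as.character(mask), nrow(mask))
  }
  structure(list(values = values, pixel_size_um = pixel_size_um,
                 x0 = x0, y0 = y0, mask = mask),
            class = "flow_map")
}

#' @export
print.flow_map <- function(x, ...) {
  cat(sprintf("flow_map: %d x %d pixels at %.0f um, total %.4g ug/s\n",
              nrow(x$values), ncol(x$values), x$pixel_size_um,
              sum(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Pixel grid covering a network cross-section
#'
#' @param network A [vessel_network()].
#' @param pixel_size_um Pixel size in um.
#' @param pad_um Margin added around the node bounding box.
#' @return list(pixel_size_um, x0, y0, nx, ny) describing the grid.
#' @export
default_grid <- function(network, pixel_size_um = 78, pad_um = pixel_size_um) {
  nd <- network$nodes
  x0 <- min(nd$x) - pad_um
  y0 <- max(nd$y) + pad_um
  nx <- ceiling((max(nd$x) + pad_um - x0) / pixel_size_um)
  ny <- ceiling((y0 - (min(nd$y) - pad_um)) / pixel_size_um)
  list(pixel_size_um = pixel_size_um, x0 = x0, y0 = y0,
       nx = max(nx, 1), ny = max(ny, 1))
}

# top-slice centroid (x, y) per vessel: position of its top-most node
.vessel_top_xy <- function(network) {
  nd <- network$nodes
  lu <- network$lumens
  vids <- sort(unique(lu$vessel_id))
  t(vapply(vids, function(v) {
    nids <- unique(c(lu$node_a[lu$vessel_id == v], lu$node_b[lu$vessel_id == v]))
    i <- match(nids, nd$id)
    j <- i[which.max(nd$z[i])]
    c(nd$x[j], nd$y[j])
  }, numeric(2)))
}

#' Downsample vessel flows to a pixel raster
#'
#' Sums the top-slice flows of all vessels whose top centroid falls inside
#' each pixel. Vessels whose (offset) centroid falls outside the grid are
#' dropped with a warning.
#'
#' @param solution A [solve_flow()] result.
#' @param network The network the solution was computed on.
#' @param grid A grid as returned by [default_grid()].
#' @param offset_um length-2 rigid registration offset (dx, dy) in um
#'   applied to vessel centroids before binning.
#' @param mask Optional mask matrix forwarded to the returned [flow_map()].
#' @return A [flow_map()].
#' @export
downsample_to_pixels <- function(solution, network, grid,
                                 offset_um = c(0, 0), mask = NULL) {
  if (grid$pixel_size_um <= 0) stop("downsample_to_pixels: pixel size must be positive")
  xy <- .vessel_top_xy(network)
  x <- xy[, 1] + offset_um[1]
  y <- xy[, 2] + offset_um[2]
  j <- floor((x - grid$x0) / grid$pixel_size_um) + 1
  i <- floor((grid$y0 - y) / grid$pixel_size_um) + 1
  inside <- i >= 1 & i <= grid$ny & j >= 1 & j <= grid$nx
  if (any(!inside))
    warning(sprintf("downsample_to_pixels: %d vessel(s) outside the grid dropped",
                    sum(!inside)))
  vals <- matrix(0, grid$ny, grid$nx)
  f <- solution$vessels$top_flow_ug_s
  for (k in which(inside))
    vals[i[k], j[k]] <- vals[i[k], j[k]] + f[k]
  fm <- flow_map(vals, grid$pixel_size_um, grid$x0, grid$y0, mask)
  attr(fm, "vessel_pixel") <- data.frame(
    vessel_id = solution$vessels$vessel_id, row = i, col = j, inside = inside)
  fm
}

#' Mask-aware 5x5 moving average
#'
#' Averages each included pixel over the included pixels of its k x k
#' neighbourhood (dividing by the in-window included count, so borders and
#' mask edges are handled without bias). Excluded pixels return NA.
#'
#' @param values Numeric matrix.
#' @param include Logical matrix of pixels taking part (default all).
#' @param k Window edge length (odd, default 5).
#' @return Matrix of smoothed values with NA outside `include`.
#' @export
box_smooth <- function(values, include = NULL, k = 5) {
  stopifnot(k %% 2 == 1)
  if (is.null(include)) include <- matrix(TRUE, nrow(values), ncol(values))
  stopifnot(all(dim(include) == dim(values)))
  h <- (k - 1) / 2
  nr <- nrow(values); nc <- ncol(values)
  v <- values
  v[!include] <- 0
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (di in -h:h) {
    ri <- intersect(seq_len(nr), seq_len(nr) - di)  # rows whose shifted row exists
    for (dj in -h:h) {
      cj <- intersect(seq_len(nc), seq_len(nc) - dj)
      acc[ri, cj] <- acc[ri, cj] + v[ri + di, cj + dj]
      cnt[ri, cj] <- cnt[ri, cj] + include[ri + di, cj + dj]
    }
  }
  out <- matrix(NA_real_, nr, nc)
  ok <- include & cnt > 0
  out[ok] <- acc[ok] / cnt[ok]
  out
}

#' Windowed residual objective
#'
#' Residual (model - observed) per included pixel, averaged over a 5x5
#' pixel neighbourhood (to absorb small registration mismatch), then summed
#' as squares.
#'
#' @param model_map,observed_map [flow_map()]s of identical shape.
#' @param include Optional logical matrix; defaults to the observed map's
#'   mask with "excluded" pixels dropped, or all pixels if no mask.
#' @param k Averaging window (default 5; use 1 to disable smoothing).
#' @return list(objective, residual, smoothed): scalar objective >= 0 and
#'   the raw and smoothed residual rasters.
#' @export
residual_objective <- function(model_map, observed_map, include = NULL, k = 5) {
  m <- model_map$values
  o <- observed_map$values
  if (!all(dim(m) == dim(o)))
    stop("residual_objective: raster shapes differ")
  if (is.null(include)) include <- include_from_mask(observed_map)
  resid <- matrix(NA_real_, nrow(o), ncol(o))
  resid[include] <- m[include] - o[include]
  sm <- box_smooth(`[<-`(resid, !include, 0), include, k = k)
  list(objective = sum(sm[include]^2), residual = resid, smoothed = sm)
}

#' Logical include matrix from a flow-map mask
#'
#' @param map A [flow_map()].
#' @param drop Labels to exclude (matched against the full label and its
#'   "."-separated parts).
#' @return Logical matrix.
#' @export
include_from_mask <- function(map, drop = "excluded") {
  if (is.null(map$mask)) return(matrix(TRUE, nrow(map$values), ncol(map$values)))
  lab <- map$mask
  hit <- matrix(FALSE, nrow(lab), ncol(lab))
  for (d in drop)
    hit <- hit | lab == d |
      vapply(strsplit(as.vector(lab), ".", fixed = TRUE),
             function(p) d %in% p, logical(1))
  !hit
}

#' Flow-weighted pixel pressure map
#'
#' Per pixel, the flow-weighted mean of the member vessels' imposed
#' pressure drops. Pixels containing no vessel, or only vessels with zero
#' total flow, are NA.
#'
#' @param solution A [solve_flow()] result.
#' @param network The underlying network.
#' @param grid Pixel grid (see [default_grid()]).
#' @param offset_um Registration offset as in [downsample_to_pixels()].
#' @return A [flow_map()] whose values are pressure drops in kPa.
#' @export
pixel_pressure_map <- function(solution, network, grid, offset_um = c(0, 0)) {
  fm <- suppressWarnings(
    downsample_to_pixels(solution, network, grid, offset_um))
  vp <- attr(fm, "vessel_pixel")
  drops <- solution$vessels$pressure_drop_kPa
  w <- solution$vessels$top_flow_ug_s
  num <- matrix(0, grid$ny, grid$nx)
  den <- matrix(0, grid$ny, grid$nx)
  for (kk in which(vp$inside)) {
    num[vp$row[kk], vp$col[kk]] <- num[vp$row[kk], vp$col[kk]] + w[kk] * drops[kk]
    den[vp$row[kk], vp$col[kk]] <- den[vp$row[kk], vp$col[kk]] + w[kk]
  }
  vals <- matrix(NA_real_, grid$ny, grid$nx)
  ok <- den != 0
  vals[ok] <- num[ok] / den[ok]
  flow_map(vals, grid$pixel_size_um, grid$x0, grid$y0)
}
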