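# File formats. Networks are stored as a sectioned plain-text table or a
# single YAML document; flow maps as headered CSV or 32-bit float TIFF.
# All writers round-trip losslessly through their readers.

#' Write a vessel network to the sectioned text format
#'
#' Plain-text format with a HEADER section (sample_length_um,
#' xylem_area_mm2, fluid constants) and NODES / LUMENS / CONNECTIONS
#' sections, tab-separated, full double precision.
#'
#' @param network A [vessel_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con)
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  w("# xylemflow vessel network v1")
  w("HEADER")
  w("sample_length_um", fmt(network$sample_length_um))
  w("xylem_area_mm2", fmt(network$xylem_area_mm2))
  w("viscosity_MPa_s", fmt(network$fluid$viscosity_MPa_s))
  w("density_kg_m3", fmt(network$fluid$density_kg_m3))
  w("NODES")
  w("id", "x", "y", "z", "tag")
  nd <- network$nodes
  for (i in seq_len(nrow(nd)))
    w(nd$id[i], fmt(nd$x[i]), fmt(nd$y[i]), fmt(nd$z[i]), nd$tag[i])
  w("LUMENS")
  w("vessel_id", "node_a", "node_b", "radius_um")
  lu <- network$lumens
  for (i in seq_len(nrow(lu)))
    w(lu$vessel_id[i], lu$node_a[i], lu$node_b[i], fmt(lu$radius_um[i]))
  w("CONNECTIONS")
  w("kind", "node_a", "node_b", "area_mm2", "diam_um")
  co <- network$connections
  for (i in seq_len(nrow(co)))
    w(co$kind[i], co$node_a[i], co$node_b[i], fmt(co$area_mm2[i]),
      fmt(co$diam_um[i]))
  invisible(path)
}

#' Read a vessel network from the sectioned text format
#'
#' @param path File written by [write_network()].
#' @return A [vessel_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  sec_at <- function(name) {
    i <- which(lines == name)
    if (length(i) != 1)
      stop(sprintf("read_network: missing section %s in %s", name, path))
    i
  }
  bounds <- c(HEADER = sec_at("HEADER"), NODES = sec_at("NODES"),
              LUMENS = sec_at("LUMENS"), CONNECTIONS = sec_at("CONNECTIONS"))
  if (is.unsorted(bounds)) stop("read_network: sections out of order")
  section <- function(name) {
    i <- bounds[[name]]
    nxt <- c(bounds[-1][bounds[-1] > i], length(lines) + 1)[1]
    lines[(i + 1):(nxt - 1)]
  }
  parse_tab <- function(txt, line0) {
    if (length(txt) < 1) stop("read_network: empty section")
    hdr <- strsplit(txt[1], "\t")[[1]]
    rows <- strsplit(txt[-1], "\t")
    bad <- which(vapply(rows, length, integer(1)) != length(hdr))
    if (length(bad))
      stop(sprintf("read_network: malformed record at line %d of %s",
                   line0 + 1 + bad[1], path))
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- hdr
    df
  }
  hd <- strsplit(section("HEADER"), "\t")
  hv <- stats::setNames(vapply(hd, `[`, "", 2), vapply(hd, `[`, "", 1))
  nodes <- parse_tab(section("NODES"), bounds[["NODES"]])
  for (col in c("x", "y", "z")) nodes[[col]] <- as.numeric(nodes[[col]])
  lumens <- parse_tab(section("LUMENS"), bounds[["LUMENS"]])
  lumens$radius_um <- as.numeric(lumens$radius_um)
  if (any(!is.finite(lumens$radius_um) | lumens$radius_um <= 0)) {
    bad <- which(!is.finite(lumens$radius_um) | lumens$radius_um <= 0)[1]
    stop(sprintf("read_network: non-positive radius for lumen record %d (vessel %s)",
                 bad, lumens$vessel_id[bad]))
  }
  lumens$vessel_id <- as.integer(lumens$vessel_id)
  ctxt <- section("CONNECTIONS")
  conns <- if (length(ctxt) > 1) {
    co <- parse_tab(ctxt, bounds[["CONNECTIONS"]])
    co$area_mm2 <- suppressWarnings(as.numeric(co$area_mm2))
    co$diam_um <- suppressWarnings(as.numeric(co$diam_um))
    co
  } else NULL
  vessel_network(nodes, lumens, conns,
                 sample_length_um = as.numeric(hv[["sample_length_um"]]),
                 xylem_area_mm2 = as.numeric(hv[["xylem_area_mm2"]]),
                 fluid = fluid_constants(as.numeric(hv[["viscosity_MPa_s"]]),
                                         as.numeric(hv[["density_kg_m3"]])))
}

#' Write / read a vessel network as a single YAML document
#'
#' Same schema as the sectioned text format in one structured document.
#'
#' @param network A [vessel_network()].
#' @param path File path.
#' @return `path` invisibly (writer); a [vessel_network()] (reader).
#' @export
write_network_yaml <- function(network, path) {
  doc <- list(
    format = "xylemflow vessel network v1",
    header = list(sample_length_um = network$sample_length_um,
                  xylem_area_mm2 = network$xylem_area_mm2,
                  viscosity_MPa_s = network$fluid$viscosity_MPa_s,
                  density_kg_m3 = network$fluid$density_kg_m3),
    nodes = as.list(network$nodes),
    lumens = as.list(network$lumens),
    connections = as.list(network$connections))
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_network_yaml
#' @export
read_network_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  conns <- if (length(doc$connections$kind) > 0)
    as.data.frame(lapply(doc$connections, unlist), stringsAsFactors = FALSE)
  else NULL
  vessel_network(as.data.frame(doc$nodes, stringsAsFactors = FALSE),
                 as.data.frame(doc$lumens, stringsAsFactors = FALSE),
                 conns,
                 sample_length_um = doc$header$sample_length_um,
                 xylem_area_mm2 = doc$header$xylem_area_mm2,
                 fluid = fluid_constants(doc$header$viscosity_MPa_s,
                                         doc$header$density_kg_m3))
}

#' Write a flow map
#'
#' CSV dialect: comment header lines (`# key value`) with pixel size and
#' origin, then the value matrix; an optional companion `<path>.mask.csv`
#' stores the labels. TIFF dialect: single-channel 32-bit float TIFF (no
#' geometry header; pass pixel size when reading).
#'
#' @param map A [flow_map()].
#' @param path Output path; format chosen by extension (".csv" or ".tif"/
#'   ".tiff").
#' @return `path`, invisibly.
#' @export
write_flowmap <- function(map, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    con <- file(path, "w")
    writeLines(c(sprintf("# pixel_size_um %.17g", map$pixel_size_um),
                 sprintf("# x0 %.17g", map$x0),
                 sprintf("# y0 %.17g", map$y0)), con)
    writeLines(apply(map$values, 1, function(r)
      paste(sprintf("%.17g", r), collapse = ",")), con)
    close(con)
    if (!is.null(map$mask))
      utils::write.table(map$mask, paste0(path, ".mask.csv"), sep = ",",
                         row.names = FALSE, col.names = FALSE)
  } else if (ext %in% c("tif", "tiff")) {
    # the tiff writer stores samples in [0, 1]; values are affinely
    # rescaled and the range recorded in a sidecar next to the geometry
    rng <- range(map$values, finite = TRUE)
    span <- if (diff(rng) > 0) diff(rng) else 1
    tiff::writeTIFF((map$values - rng[1]) / span, path,
                    bits.per.sample = 32, reduce = FALSE)
    writeLines(c(sprintf("pixel_size_um %.17g", map$pixel_size_um),
                 sprintf("x0 %.17g", map$x0),
                 sprintf("y0 %.17g", map$y0),
                 sprintf("vmin %.17g", rng[1]),
                 sprintf("vspan %.17g", span)),
               paste0(path, ".geom.txt"))
    if (!is.null(map$mask))
      utils::write.table(map$mask, paste0(path, ".mask.csv"), sep = ",",
                         row.names = FALSE, col.names = FALSE)
  } else stop("write_flowmap: unsupported extension ", ext)
  invisible(path)
}

#' Read a flow map
#'
#' @param path CSV (written by [write_flowmap()]) or single-channel TIFF.
#' @param pixel_size_um,x0,y0 Geometry for TIFF input (CSV carries its
#'   own).
#' @return A [flow_map()] (with mask when a companion mask file exists).
#' @export
read_flowmap <- function(path, pixel_size_um = NULL, x0 = 0, y0 = 0) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), " "))
    geom <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
    vals <- as.matrix(utils::read.csv(text = lines[!grepl("^#", lines)],
                                      header = FALSE))
    dimnames(vals) <- NULL
    maskfile <- paste0(path, ".mask.csv")
    mask <- if (file.exists(maskfile))
      as.matrix(utils::read.csv(maskfile, header = FALSE,
                                colClasses = "character"))
    else NULL
    if (!is.null(mask)) dimnames(mask) <- NULL
    flow_map(vals, geom[["pixel_size_um"]], geom[["x0"]], geom[["y0"]], mask)
  } else if (ext %in% c("tif", "tiff")) {
    vals <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(vals)) == 3) vals <- vals[, , 1]
    geomfile <- paste0(path, ".geom.txt")
    if (file.exists(geomfile)) {
      kv <- do.call(rbind, strsplit(readLines(geomfile), " "))
      g <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
      vals <- vals * g[["vspan"]] + g[["vmin"]]
      pixel_size_um <- g[["pixel_size_um"]]
      x0 <- g[["x0"]]; y0 <- g[["y0"]]
    } else if (is.null(pixel_size_um)) {
      stop("read_flowmap: pixel_size_um required for TIFF without sidecar")
    }
    maskfile <- paste0(path, ".mask.csv")
    mask <- if (file.exists(maskfile)) {
      mm <- as.matrix(utils::read.csv(maskfile, header = FALSE,
                                      colClasses = "character"))
      dimnames(mm) <- NULL
      mm
    } else NULL
    flow_map(vals, pixel_size_um, x0, y0, mask)
  } else stop("read_flowmap: unsupported extension ", ext)
}

#' Run configuration
#'
#' @param ... Named fields overriding the defaults: `seed`, `scenarios`
#'   (subset of "uniform", "uniform_masked", "total_flow", "per_group"),
#'   `spec` (a [synthetic_spec()] or list of its arguments), `offset_um`,
#'   `out_dir`.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(seed = 1,
              scenarios = c("uniform", "uniform_masked", "total_flow",
                            "per_group"),
              spec = list(),
              offset_um = c(0, 0),
              out_dir = "results")
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @param config A [run_config()].
#' @return A [run_config()] (reader); `path` invisibly (writer).
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  do.call(run_config, doc)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates the synthetic truth, fits the requested scenarios, computes
#' summary statistics and writes all outputs (network, maps, per-vessel
#' tables, fit summary, stats, resolved configuration) under the output
#' directory. Deterministic for a fixed configuration.
#'
#' @param config A [run_config()] or path to its YAML form.
#' @return Invisibly, a list with the truth, fits and summary table.
#' @export
pipeline_run <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  spec <- if (inherits(config$spec, "synthetic_spec")) config$spec
          else do.call(synthetic_spec, config$spec)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("xylemflow %s | R %s", as.character(utils::packageVersion("xylemflow")),
          paste(R.version$major, R.version$minor, sep = "."))
  logline("seed %d", config$seed)

  truth <- generate_synthetic_truth(spec, config$seed)
  write_network(truth$network, file.path(config$out_dir, "network.txt"))
  write_flowmap(truth$noiseless, file.path(config$out_dir, "flow_noiseless.csv"))
  write_flowmap(truth$noisy, file.path(config$out_dir, "flow_observed.csv"))

  obs <- truth$noisy
  fits <- list()
  summ <- list()
  for (sc in config$scenarios) {
    fit <- switch(sc,
      uniform = fit_uniform_pressure(truth$network, obs,
                                     offset_um = config$offset_um),
      uniform_masked = fit_uniform_pressure(
        truth$network, obs,
        include = include_from_mask(obs, c("excluded", "outer")),
        offset_um = config$offset_um),
      total_flow = fit_total_flow(truth$network,
                                  sum(obs$values[include_from_mask(obs)]),
                                  observed = obs,
                                  offset_um = config$offset_um),
      per_group = fit_group_pressures(truth$network, obs,
                                      offset_um = config$offset_um),
      stop("pipeline_run: unknown scenario ", sc))
    fits[[sc]] <- fit
    utils::write.csv(fit$vessels,
                     file.path(config$out_dir,
                               sprintf("vessels_%s.csv", sc)),
                     row.names = FALSE)
    summ[[sc]] <- data.frame(scenario = sc, objective = fit$objective,
                             nse = fit$nse,
                             total_flow_rel_error = fit$total_flow_rel_error,
                             mean_drop_kPa = mean(fit$drops_kPa))
    logline("scenario %s: objective %.8g NSE %.6f", sc, fit$objective, fit$nse)
  }
  summary_df <- do.call(rbind, summ)
  utils::write.csv(summary_df, file.path(config$out_dir, "fit_summary.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(config$out_dir, "resolved_config.yaml"))
  invisible(list(truth = truth, fits = fits, summary = summary_df))
}
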