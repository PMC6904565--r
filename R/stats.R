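# Summary statistics and hypothesis tests on fitted solutions.

#' Nash-Sutcliffe efficiency
#'
#' `1 - sum((o - m)^2) / sum((o - mean(o))^2)`. Ranges from -Inf to 1; 0
#' means the model predicts no better than the observation mean, 1 is a
#' perfect match.
#'
#' @param observed,modelled Numeric vectors (or matrices) of equal length;
#'   NA pairs are dropped.
#' @return Scalar NSE.
#' @export
nse <- function(observed, modelled) {
  o <- as.numeric(observed)
  m <- as.numeric(modelled)
  if (length(o) != length(m)) stop("nse: lengths differ")
  ok <- is.finite(o) & is.finite(m)
  o <- o[ok]; m <- m[ok]
  if (length(o) < 2) stop("nse: need at least two observations")
  denom <- sum((o - mean(o))^2)
  if (denom == 0) stop("nse: observations are constant")
  1 - sum((o - m)^2) / denom
}

#' Flow-weighted mean and standard deviation
#'
#' Weighted mean with the weighted variance in its reliability-weights
#' form, `sum(w (x - mu)^2) / (sum(w) - sum(w^2)/sum(w))`, which reduces to
#' the ordinary sample variance under equal weights and is invariant to a
#' common rescaling of the weights.
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights (e.g. flows), summing to > 0.
#' @return list(mean, sd, n, weight_total) of class `weighted_summary`.
#' @export
flow_weighted_summary <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  if (any(weights < 0)) stop("flow_weighted_summary: negative weights")
  W <- sum(weights)
  if (W <= 0) stop("flow_weighted_summary: weights sum to zero")
  mu <- sum(weights * values) / W
  denom <- W - sum(weights^2) / W
  if (denom <= 0) {
    warning("flow_weighted_summary: variance undefined for a single effective weight; SD set to 0")
    s <- 0
  } else {
    s <- sqrt(sum(weights * (values - mu)^2) / denom)
  }
  structure(list(mean = mu, sd = s, n = length(values), weight_total = W),
            class = "weighted_summary")
}

#' @export
print.weighted_summary <- function(x, ...) {
  cat(sprintf("weighted mean %.4g +/- %.4g (n = %d)\n", x$mean, x$sd, x$n))
  invisible(x)
}

#' Transverse pressure gradients between adjacent pixels
#'
#' For every 4-neighbour pair of non-empty pixels of a pixel pressure map,
#' the absolute pressure difference over the pixel distance, each unordered
#' pair counted once. Diagonal neighbours are excluded.
#'
#' @param pressure_map A [flow_map()] whose values are pressures in kPa,
#'   with NA marking empty pixels (see [pixel_pressure_map()]).
#' @return list(gradients_MPa_m, n, mean, median) of class
#'   `gradient_distribution`.
#' @export
transverse_gradients <- function(pressure_map) {
  p <- pressure_map$values
  px <- pressure_map$pixel_size_um
  grads <- c(
    abs(p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]),   # vertical pairs
    abs(p[, -1, drop = FALSE] - p[, -ncol(p), drop = FALSE]))   # horizontal pairs
  grads <- grads[is.finite(grads)]
  g <- .kpa_per_um_to_MPa_per_m(grads / px)
  structure(list(gradients_MPa_m = g, n = length(g),
                 mean = if (length(g)) mean(g) else NA_real_,
                 median = if (length(g)) stats::median(g) else NA_real_),
            class = "gradient_distribution")
}

#' @export
print.gradient_distribution <- function(x, ...) {
  cat(sprintf("transverse gradients: n = %d, mean %.3g, median %.3g MPa/m\n",
              x$n, x$mean, x$median))
  invisible(x)
}

#' Sliding-window t-test of deviations from Hagen-Poiseuille flow
#'
#' Residuals between vessel flows and the idealized flow-radius curve at a
#' fixed gradient are tested in a sliding radius window (two-tailed
#' one-sample t-test of mean 0), evaluated at 1-um steps across the
#' observed radius range. Windows with fewer than two vessels are skipped.
#'
#' @param radii_um Vessel radii in um.
#' @param flows_ug_s Vessel flows in ug s-1.
#' @param gradient_MPa_m Reference axial gradient for the idealized curve.
#' @param window_um Window width in um (default 6).
#' @param fluid A [fluid_constants()] object.
#' @return data.frame(center_radius_um, n, t, df, p) for evaluated windows.
#' @export
hp_deviation_test <- function(radii_um, flows_ug_s, gradient_MPa_m,
                              window_um = 6, fluid = fluid_constants()) {
  stopifnot(length(radii_um) == length(flows_ug_s))
  resid <- flows_ug_s - hp_theoretical_curve(radii_um, gradient_MPa_m, fluid)
  centers <- seq(ceiling(min(radii_um)), floor(max(radii_um)), by = 1)
  rows <- lapply(centers, function(cc) {
    sel <- abs(radii_um - cc) <= window_um / 2
    n <- sum(sel)
    if (n < 2) return(NULL)
    r <- resid[sel]
    if (stats::sd(r) == 0) {
      # degenerate window: all residuals identical
      t_val <- if (mean(r) == 0) 0 else Inf * sign(mean(r))
      p_val <- if (mean(r) == 0) 1 else 0
    } else {
      tt <- stats::t.test(r, mu = 0, alternative = "two.sided")
      t_val <- unname(tt$statistic)
      p_val <- tt$p.value
    }
    data.frame(center_radius_um = cc, n = n, t = t_val, df = n - 1, p = p_val)
  })
  skipped <- length(centers) - sum(!vapply(rows, is.null, logical(1)))
  if (skipped > 0)
    warning(sprintf("hp_deviation_test: %d window(s) with < 2 vessels skipped", skipped))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(center_radius_um = numeric(), n = integer(),
                      t = numeric(), df = numeric(), p = numeric())
  out
}

#' Robustness of the deviation test over window widths
#'
#' Re-runs [hp_deviation_test()] over a range of window widths.
#'
#' @inheritParams hp_deviation_test
#' @param widths_um Window widths to evaluate (default 4 to 12 um).
#' @return data.frame with a `window_um` column stacked over widths.
#' @export
hp_deviation_profile <- function(radii_um, flows_ug_s, gradient_MPa_m,
                                 widths_um = seq(4, 12, by = 2),
                                 fluid = fluid_constants()) {
  do.call(rbind, lapply(widths_um, function(w) {
    d <- suppressWarnings(
      hp_deviation_test(radii_um, flows_ug_s, gradient_MPa_m, w, fluid))
    if (nrow(d)) d$window_um <- w
    d
  }))
}

#' Two-way fixed-effects ANOVA across xylem domains
#'
#' Type II sums of squares on a possibly unbalanced layout, with
#' interaction, as appropriate for radial (inner/outer) by tangential
#' (dorsal-ventral/lateral) domain comparisons.
#'
#' @param values Response (e.g. per-vessel gradient or radius).
#' @param factor_a,factor_b Factors (coerced), e.g. radial and tangential
#'   domain labels.
#' @return data.frame(term, sum_sq, df, F, p).
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  tab <- table(a, b)
  if (any(tab == 0))
    stop("two_way_anova: empty cell in the factor layout")
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("two_way_anova: both factors need at least two levels")
  fit <- stats::lm(values ~ a * b)
  an <- car::Anova(fit, type = "II")
  data.frame(term = c("factor_a", "factor_b", "interaction", "residuals"),
             sum_sq = an[["Sum Sq"]], df = an[["Df"]],
             F = an[["F value"]], p = an[["Pr(>F)"]])
}

#' Per-domain vessel counts, flow shares and conductivities
#'
#' @param solution A [solve_flow()] result.
#' @param domains Character vector of domain labels, one per vessel (in
#'   `solution$vessels` order); a partition, so labels must not overlap.
#' @param domain_areas_mm2 Named vector of cross-sectional areas per
#'   domain label (for specific conductivity); optional.
#' @return data.frame(domain, n_vessels, vessel_fraction, flow_ug_s,
#'   flow_fraction, gradient_MPa_m, conductivity) where gradient is the
#'   flow-weighted mean and conductivity is [specific_conductivity()]
#'   (NA without areas or with non-positive gradient).
#' @export
flow_share_report <- function(solution, domains, domain_areas_mm2 = NULL) {
  v <- solution$vessels
  stopifnot(length(domains) == nrow(v))
  labs <- unique(domains)
  tot <- sum(v$top_flow_ug_s)
  rows <- lapply(labs, function(d) {
    sel <- domains == d
    fl <- sum(v$top_flow_ug_s[sel])
    g <- if (any(sel) && sum(abs(v$top_flow_ug_s[sel])) > 0)
      suppressWarnings(flow_weighted_summary(
        v$gradient_MPa_m[sel], pmax(v$top_flow_ug_s[sel], 0)))$mean
    else NA_real_
    cond <- if (!is.null(domain_areas_mm2) && is.finite(g) && g > 0)
      specific_conductivity(fl, g, domain_areas_mm2[[d]]) else NA_real_
    data.frame(domain = d, n_vessels = sum(sel),
               vessel_fraction = mean(sel), flow_ug_s = fl,
               flow_fraction = if (tot != 0) fl / tot else NA_real_,
               gradient_MPa_m = g, conductivity = cond)
  })
  do.call(rbind, rows)
}

#' Flow redirection between two fitted scenarios
#'
#' Per-vessel flow changes between two fits of the same network (e.g.
#' uniform-pressure versus per-group), the share of total flow redirected,
#' and the fraction of flow lost by wide (above-mean-radius) vessels.
#'
#' @param fit_a,fit_b `fit_result`s on the same network (A = reference,
#'   e.g. uniform; B = comparison, e.g. per-group).
#' @param radii_um Vessel radii in um (solution vessel order).
#' @param mean_radius_um Threshold radius separating wide from narrow
#'   vessels; defaults to the flow-weighted mean radius under fit B.
#' @return list(per_vessel, redirected_share, wide_loss_fraction,
#'   mean_radius_um) where per_vessel is a data.frame of flows and changes.
#' @export
flow_redirection <- function(fit_a, fit_b, radii_um, mean_radius_um = NULL) {
  va <- fit_a$vessels
  vb <- fit_b$vessels
  if (!identical(va$vessel_id, vb$vessel_id))
    stop("flow_redirection: fits are not on the same network")
  stopifnot(length(radii_um) == nrow(va))
  if (is.null(mean_radius_um))
    mean_radius_um <- flow_weighted_summary(radii_um,
                                            pmax(vb$top_flow_ug_s, 0))$mean
  delta <- vb$top_flow_ug_s - va$top_flow_ug_s
  tot <- sum(vb$top_flow_ug_s)
  wide <- radii_um > mean_radius_um
  loss_wide <- -sum(delta[wide & delta < 0])
  flow_wide_a <- sum(va$top_flow_ug_s[wide])
  list(per_vessel = data.frame(vessel_id = va$vessel_id,
                               radius_um = radii_um,
                               flow_a = va$top_flow_ug_s,
                               flow_b = vb$top_flow_ug_s,
                               delta = delta, wide = wide),
       redirected_share = if (tot != 0) sum(delta[delta > 0]) / tot else NA_real_,
       wide_loss_fraction = if (flow_wide_a != 0) loss_wide / flow_wide_a else NA_real_,
       mean_radius_um = mean_radius_um)
}
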