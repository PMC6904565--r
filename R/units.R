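# Internal working units: pressure kPa, mass flow ug/s, length um.
# Resistance therefore carries kPa per (ug/s). Converters live here so the
# rest of the package never multiplies by raw powers of ten.

#' Fluid constants
#'
#' Properties of the transported fluid used to convert geometry into
#' hydraulic resistances. Defaults are water at 20 degrees C.
#'
#' @param viscosity_MPa_s Dynamic viscosity in MPa s (1.002e-9 MPa s =
#'   1.002e-3 Pa s for water at 20 C).
#' @param density_kg_m3 Fluid density in kg m-3.
#' @return A list with class `fluid_constants`.
#' @export
fluid_constants <- function(viscosity_MPa_s = 1.002e-9,
                            density_kg_m3 = 998) {
  stopifnot(viscosity_MPa_s > 0, density_kg_m3 > 0)
  structure(list(viscosity_MPa_s = viscosity_MPa_s,
                 density_kg_m3 = density_kg_m3),
            class = "fluid_constants")
}

# volumetric resistance [Pa s m-3] -> internal mass-flow resistance
# [kPa per (ug/s)]: divide by density (kg m-3), then Pa -> kPa (1e-3)
# and (kg/s) -> (ug/s) (1e-9) in the denominator.
.resistance_vol_to_internal <- function(R_vol_Pa_s_m3, density_kg_m3) {
  R_vol_Pa_s_m3 / density_kg_m3 * 1e-12
}

# kPa per um -> MPa per m (x 1e-3 MPa/kPa / 1e-6 m/um)
.kpa_per_um_to_MPa_per_m <- function(x) x * 1e3

#' Hagen-Poiseuille lumen resistance
#'
#' Resistance of a cylindrical lumen segment to mass flow,
#' `8 eta L / (pi r^4)` converted to mass-flow units via the fluid density.
#'
#' @param radius_um Lumen radius in um (> 0).
#' @param length_um Segment length in um (> 0).
#' @param fluid A [fluid_constants()] object.
#' @return Resistance in kPa per (ug s-1).
#' @examples
#' hp_lumen_resistance(20, 3300)
#' @export
hp_lumen_resistance <- function(radius_um, length_um,
                                fluid = fluid_constants()) {
  if (any(!is.finite(radius_um)) || any(radius_um <= 0))
    stop("hp_lumen_resistance: radius_um must be positive and finite")
  if (any(!is.finite(length_um)) || any(length_um <= 0))
    stop("hp_lumen_resistance: length_um must be positive and finite")
  eta_Pa_s <- fluid$viscosity_MPa_s * 1e6
  r_m <- radius_um * 1e-6
  L_m <- length_um * 1e-6
  R_vol <- 8 * eta_Pa_s * L_m / (pi * r_m^4)
  .resistance_vol_to_internal(R_vol, fluid$density_kg_m3)
}

#' Pit-field connection resistance
#'
#' Resistance of an inter-vessel pit field, the area-specific pit resistance
#' divided by membrane area. The grapevine literature value of the constant
#' is 168, conventionally quoted with units MPa m-1 s-1; those units do not
#' reduce to a conventional area-specific resistance, so the constant is
#' interpreted here as MPa s m-1 such that `r_pit / A` is a volumetric
#' resistance (Pa s m-3 after conversion). The number itself is used
#' verbatim.
#'
#' @param area_mm2 Pit membrane area in mm2 (> 0).
#' @param r_pit_MPa_s_m Area-specific pit resistance (default 168).
#' @param fluid A [fluid_constants()] object.
#' @return Resistance in kPa per (ug s-1).
#' @examples
#' pit_connection_resistance(0.015)
#' @export
pit_connection_resistance <- function(area_mm2, r_pit_MPa_s_m = 168,
                                      fluid = fluid_constants()) {
  if (any(!is.finite(area_mm2)) || any(area_mm2 <= 0))
    stop("pit_connection_resistance: area_mm2 must be positive")
  if (r_pit_MPa_s_m <= 0)
    stop("pit_connection_resistance: r_pit must be positive")
  A_m2 <- area_mm2 * 1e-6
  R_vol <- (r_pit_MPa_s_m * 1e6) / A_m2
  .resistance_vol_to_internal(R_vol, fluid$density_kg_m3)
}

#' Specific conductivity of a tissue domain
#'
#' Total mass flow divided by the flow-weighted mean pressure gradient and
#' the domain cross-sectional area.
#'
#' @param total_flow_ug_s Summed mass flow in ug s-1.
#' @param gradient_MPa_m Flow-weighted mean axial pressure gradient in
#'   MPa m-1 (> 0).
#' @param area_mm2 Domain cross-sectional area in mm2 (> 0).
#' @return Specific conductivity in kg m-1 MPa-1 s-1.
#' @export
specific_conductivity <- function(total_flow_ug_s, gradient_MPa_m, area_mm2) {
  if (!is.finite(gradient_MPa_m) || gradient_MPa_m <= 0)
    stop("specific_conductivity: gradient must be positive")
  if (!is.finite(area_mm2) || area_mm2 <= 0)
    stop("specific_conductivity: area must be positive")
  (total_flow_ug_s * 1e-9) / (gradient_MPa_m * area_mm2 * 1e-6)
}

#' Idealized Hagen-Poiseuille flow-radius curve
#'
#' Mass flow rate of an unobstructed lumen of radius `r` under a fixed axial
#' pressure gradient: `Q(r) = rho pi r^4 g / (8 eta)`.
#'
#' @param radius_um Radii in um.
#' @param gradient_MPa_m Axial pressure gradient in MPa m-1 (> 0).
#' @param fluid A [fluid_constants()] object.
#' @return Mass flow rates in ug s-1, same length as `radius_um`.
#' @export
hp_theoretical_curve <- function(radius_um, gradient_MPa_m,
                                 fluid = fluid_constants()) {
  if (!is.finite(gradient_MPa_m) || gradient_MPa_m <= 0)
    stop("hp_theoretical_curve: gradient must be positive")
  eta_Pa_s <- fluid$viscosity_MPa_s * 1e6
  r_m <- radius_um * 1e-6
  Qv <- pi * r_m^4 * (gradient_MPa_m * 1e6) / (8 * eta_Pa_s)
  Qv * fluid$density_kg_m3 * 1e9
}
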