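#' Fluid properties of a blood-mimicking fluid
#'
#' Container for the density and dynamic viscosity of the working fluid.
#' The kinematic viscosity is derived (`nu = mu / rho`) and kept consistent.
#' Defaults correspond to a water/glycerol/urea blood-mimicking fluid:
#' density 1144 kg/m3 and dynamic viscosity 4.17 mPa.s, both within the
#' physiological range of blood.
#'
#' @param density Fluid density in kg/m3. Must be positive.
#' @param dynamic_viscosity Dynamic viscosity in Pa.s. Must be positive.
#' @return An object of class `fluid_props` with fields `density` (kg/m3),
#'   `dynamic_viscosity` (Pa.s) and `kinematic_viscosity` (m2/s).
#' @examples
#' bmf <- fluid_props()
#' bmf$kinematic_viscosity  # ~3.65e-6 m2/s
#' @export
fluid_props <- function(density = 1144, dynamic_viscosity = 4.17e-3) {
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0)
    stop("`density` must be a single positive number (kg/m3)")
  if (!is.numeric(dynamic_viscosity) || length(dynamic_viscosity) != 1L ||
      !is.finite(dynamic_viscosity) || dynamic_viscosity <= 0)
    stop("`dynamic_viscosity` must be a single positive number (Pa.s)")
  structure(
    list(density = density,
         dynamic_viscosity = dynamic_viscosity,
         kinematic_viscosity = dynamic_viscosity / density),
    class = "fluid_props")
}

#' @export
print.fluid_props <- function(x, ...) {
  cat("Fluid properties\n")
  cat(sprintf("  density            : %g kg/m3\n", x$density))
  cat(sprintf("  dynamic viscosity  : %g Pa.s\n", x$dynamic_viscosity))
  cat(sprintf("  kinematic viscosity: %g m2/s\n", x$kinematic_viscosity))
  invisible(x)
}

#' Femoral bifurcation vessel geometry
#'
#' Geometry parameters of the common (CFA), superficial (SFA) and deep (DFA)
#' femoral arteries. Defaults are population-averaged diameters of
#' 8.9 / 6.2 / 6.1 mm, a planar 37.5 degree bifurcation angle, and a 75%
#' area-reduction concentric stenosis for the stenosed configuration.
#'
#' @param cfa_diameter,sfa_diameter,dfa_diameter Vessel diameters in mm.
#' @param bifurcation_angle Angle between the SFA and DFA in degrees.
#' @param stenosis_area_reduction Fractional cross-sectional area reduction of
#'   the CFA stenosis, in `[0, 1)`; 0 means no stenosis.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(cfa_diameter = 8.9, sfa_diameter = 6.2,
                        dfa_diameter = 6.1, bifurcation_angle = 37.5,
                        stenosis_area_reduction = 0.75) {
  d <- c(cfa_diameter, sfa_diameter, dfa_diameter)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("all vessel diameters must be positive")
  if (!is.finite(stenosis_area_reduction) || stenosis_area_reduction < 0 ||
      stenosis_area_reduction >= 1)
    stop("`stenosis_area_reduction` must lie in [0, 1)")
  structure(
    list(cfa_diameter = cfa_diameter, sfa_diameter = sfa_diameter,
         dfa_diameter = dfa_diameter, bifurcation_angle = bifurcation_angle,
         stenosis_area_reduction = stenosis_area_reduction),
    class = "vessel_spec")
}

#' @export
print.vessel_spec <- function(x, ...) {
  cat("Femoral bifurcation geometry\n")
  cat(sprintf("  CFA / SFA / DFA diameter: %g / %g / %g mm\n",
              x$cfa_diameter, x$sfa_diameter, x$dfa_diameter))
  cat(sprintf("  bifurcation angle       : %g deg\n", x$bifurcation_angle))
  cat(sprintf("  stenosis area reduction : %g\n", x$stenosis_area_reduction))
  invisible(x)
}
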