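#' Orbital-shaker shear model
#'
#' Operating parameters of a circular well swirled on an orbital shaker,
#' from which the wall shear stress at the cell layer is estimated. The
#' defaults describe the coculture assay: 135 rpm on a 9.5 mm orbit with
#' 2 mL of culture medium in a 6-well plate (35 mm well), medium density
#' ~1000 kg m^-3 and viscosity 7.8e-4 Pa s (DMEM-like at 37 °C).
#'
#' @param rpm shaker rotation speed, rotations per minute.
#' @param orbital_radius_m orbit radius in metres.
#' @param fluid_density medium density, kg m^-3.
#' @param fluid_viscosity medium dynamic viscosity, Pa s.
#' @param well_diameter_m well diameter in metres.
#' @param medium_volume_ml medium volume in millilitres.
#' @return An object of class `shear_model`.
#' @export
shear_model <- function(rpm = 135, orbital_radius_m = 0.0095,
                        fluid_density = 1000, fluid_viscosity = 7.8e-4,
                        well_diameter_m = 0.035, medium_volume_ml = 2) {
  vals <- c(
    orbital_radius_m = orbital_radius_m, fluid_density = fluid_density,
    fluid_viscosity = fluid_viscosity, well_diameter_m = well_diameter_m,
    medium_volume_ml = medium_volume_ml
  )
  if (rpm < 0 || any(vals <= 0)) {
    stop_wm("All shear-model parameters must be positive (rpm >= 0).",
      "config_error")
  }
  structure(
    c(list(rpm = rpm), as.list(vals)),
    class = "shear_model"
  )
}

#' @export
print.shear_model <- function(x, ...) {
  cat(sprintf(
    "<shear_model> %g rpm, orbit %.1f mm, rho %g kg/m^3, mu %.2g Pa s -> tau %.2f Pa\n",
    x$rpm, 1000 * x$orbital_radius_m, x$fluid_density, x$fluid_viscosity,
    stokes_wss(x)
  ))
  invisible(x)
}

#' Closed-form orbital wall shear stress
#'
#' The standard Stokes-second-problem estimate of the peak wall shear
#' stress under an orbitally swirled fluid layer:
#' \deqn{\tau = r_{orb} \sqrt{\rho \mu \omega^3},}
#' with \eqn{\omega = 2\pi\,\mathrm{rpm}/60} the angular frequency. The
#' formula treats the rotating wave as an oscillating boundary layer and
#' returns the cycle-peak stress at the wall in pascals; it is strictly
#' increasing in rpm, viscosity, density and orbital radius, and scales as
#' rpm^(3/2).
#'
#' @param model a [shear_model()].
#' @return Peak wall shear stress in Pa.
#' @examples
#' stokes_wss(shear_model()) # ~0.45 Pa at 135 rpm
#' @export
stokes_wss <- function(model) {
  stopifnot(inherits(model, "shear_model"))
  omega <- 2 * pi * model$rpm / 60
  model$orbital_radius_m *
    sqrt(model$fluid_density * model$fluid_viscosity * omega^3)
}

#' Zone-level shear summary with published reference windows
#'
#' Combines the analytical estimate with the literature windows for a
#' 6-well plate at 135 rpm: mean WSS 0.4-1.2 Pa in the peripheral zone
#' (pulsatile, near-laminar flow) and 0.3-0.8 Pa in the central zone
#' (disturbed, multidirectional flow). The windows are annotations from
#' published hydrodynamic simulations, reported as-is regardless of the
#' model parameters; the consistency flag records whether the analytical
#' value falls inside the peripheral window.
#'
#' @param model a [shear_model()].
#' @param geom optional [well_geometry()] echoed into the output.
#' @return A tibble with `zone`, `wss_low_pa`, `wss_high_pa`, `regime`,
#'   `tau_analytical_pa`, `consistent`.
#' @export
zone_shear_summary <- function(model, geom = NULL) {
  tau <- stokes_wss(model)
  tibble(
    zone = c("periphery", "center"),
    wss_low_pa = c(0.4, 0.3),
    wss_high_pa = c(1.2, 0.8),
    regime = c("pulsatile-laminar", "disturbed"),
    tau_analytical_pa = tau,
    consistent = c(tau >= 0.4 && tau <= 1.2, NA)
  )
}

#' Shaker frequency as heart-rate equivalent
#'
#' One rotation per beat: the rotation frequency maps one-to-one onto a
#' beats-per-minute scale, annotated with the physiological band it falls
#' into. Default band edges: 0 = none, below 100 bpm resting, 100-190 bpm
#' exercise, above supraphysiological.
#'
#' @param rpm rotation speed (>= 0).
#' @param resting_max,exercise_max upper band edges in bpm.
#' @return A tibble with `rpm`, `bpm`, `band`.
#' @export
rpm_to_beat_equivalent <- function(rpm, resting_max = 100, exercise_max = 190) {
  if (any(rpm < 0)) stop_wm("`rpm` must be >= 0.", "config_error")
  tibble(
    rpm = rpm,
    bpm = rpm,
    band = dplyr::case_when(
      rpm == 0 ~ "none",
      rpm < resting_max ~ "resting",
      rpm <= exercise_max ~ "exercise",
      TRUE ~ "supraphysiological"
    )
  )
}
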