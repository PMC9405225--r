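#' Kinematic viscosity of water
#'
#' Evaluates the dynamic viscosity of pure water with the Vogel (VFT)
#' equation, mu = 1e-3 * exp(A + B / (T_K + C)) Pa s, divides by the Kell
#' density polynomial and returns the kinematic viscosity. At the reference
#' culture temperature of 21.0 C the value is 9.80e-7 m2/s, within 0.5% of
#' the 9.78e-7 m2/s used for the flow simulations this package post-processes.
#'
#' @param temperature Water temperature in degrees Celsius, in (0, 100).
#' @param coef Named numeric vector of Vogel coefficients `A`, `B`, `C`
#'   (`B` in Kelvin, `C` in Kelvin offset). Defaults are for pure water.
#' @return Kinematic viscosity in m2/s.
#' @seealso [water_density()], [oxygen_diffusivity()], [schmidt()]
#' @export
#' @examples
#' water_viscosity(21)   # ~9.80e-7 m2/s
water_viscosity <- function(temperature,
                            coef = c(A = -3.7188, B = 578.919, C = -137.546)) {
  stopifnot(is.numeric(temperature))
  if (any(temperature <= 0 | temperature >= 100)) {
    stop("water_viscosity(): temperature must lie in (0, 100) degC", call. = FALSE)
  }
  mu <- water_dynamic_viscosity(temperature, coef = coef)
  mu / water_density(temperature)
}

#' Dynamic viscosity of water (Vogel equation)
#'
#' @inheritParams water_viscosity
#' @return Dynamic viscosity in Pa s.
#' @export
water_dynamic_viscosity <- function(temperature,
                                    coef = c(A = -3.7188, B = 578.919, C = -137.546)) {
  if (any(temperature <= 0 | temperature >= 100)) {
    stop("water_dynamic_viscosity(): temperature must lie in (0, 100) degC",
         call. = FALSE)
  }
  tk <- temperature + 273.15
  1e-3 * exp(coef[["A"]] + coef[["B"]] / (tk + coef[["C"]]))
}

#' Density of water (Kell polynomial)
#'
#' Kell (1975) fit for air-free water at atmospheric pressure.
#'
#' @inheritParams water_viscosity
#' @return Density in kg/m3.
#' @export
water_density <- function(temperature) {
  if (any(temperature <= 0 | temperature >= 100)) {
    stop("water_density(): temperature must lie in (0, 100) degC", call. = FALSE)
  }
  t <- temperature
  (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 - 46.170461e-6 * t^3 +
     105.56302e-9 * t^4 - 280.54253e-12 * t^5) / (1 + 16.897850e-3 * t)
}

#' Oxygen-water molecular diffusivity
#'
#' Linear-in-temperature fit D_AB(T) = c0 + c1 * T, the functional form used
#' to interpolate literature diffusivities across the experimental
#' temperature span. The default coefficients anchor D_AB(21.0 C) =
#' 2.10e-9 m2/s exactly, with slope 4.5e-11 m2/s/degC.
#'
#' @param temperature Temperature in degrees Celsius, in (0, 60).
#' @param coef Numeric vector `c(c0, c1)`: intercept (m2/s) and slope
#'   (m2/s per degC).
#' @return Molecular diffusivity in m2/s.
#' @export
#' @examples
#' oxygen_diffusivity(21)  # 2.10e-9 exactly
oxygen_diffusivity <- function(temperature, coef = c(1.155e-9, 4.5e-11)) {
  stopifnot(is.numeric(temperature), length(coef) == 2)
  if (any(temperature <= 0 | temperature >= 60)) {
    stop("oxygen_diffusivity(): temperature must lie in (0, 60) degC", call. = FALSE)
  }
  d <- coef[1] + coef[2] * temperature
  if (any(d <= 0)) {
    stop("oxygen_diffusivity(): configured coefficients give non-positive D_AB",
         call. = FALSE)
  }
  d
}

#' Dissolved-oxygen saturation concentration
#'
#' Henry-law equilibrium concentration of oxygen in water, using the
#' Benson-Krause (1984) solubility correlation (the basis of the USGS DO
#' tables) at its reference oxygen mole fraction, scaled linearly in the
#' supplied oxygen partial pressure.
#'
#' @param temperature Temperature in degrees Celsius, in (0, 40).
#' @param pO2 Oxygen partial pressure in atm, in (0, 1]. Default 0.2095
#'   (ambient air).
#' @return Saturation concentration C_sat in mol/m3.
#' @export
#' @examples
#' oxygen_saturation(25)            # ~0.258 mol/m3
#' oxygen_saturation(37) < oxygen_saturation(21)
oxygen_saturation <- function(temperature, pO2 = 0.2095) {
  stopifnot(is.numeric(temperature), is.numeric(pO2))
  if (any(temperature <= 0 | temperature >= 40)) {
    stop("oxygen_saturation(): temperature must lie in (0, 40) degC", call. = FALSE)
  }
  if (any(pO2 <= 0 | pO2 > 1)) {
    stop("oxygen_saturation(): pO2 must lie in (0, 1] atm", call. = FALSE)
  }
  tk <- temperature + 273.15
  # Benson-Krause: ln(DO / (mg/L)) at 1 atm moist air, x_O2 = 0.20946
  do_mgL <- exp(-139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
                  1.2438e10 / tk^3 - 8.621949e11 / tk^4)
  (do_mgL / 31.9988) * (pO2 / 0.20946)  # mg/L -> mol/m3, rescale to pO2
}

#' Bundle of temperature-indexed medium properties
#'
#' Assembles kinematic viscosity, molecular diffusivity, density, dynamic
#' viscosity and oxygen saturation concentration for water at one
#' temperature. Downstream dimensionless groups and post-processing
#' operators consume this object.
#'
#' @param temperature Temperature in degrees Celsius.
#' @param pO2 Oxygen partial pressure in atm for `C_sat`.
#' @param diffusivity_coef Coefficients passed to [oxygen_diffusivity()].
#' @param viscosity_coef Coefficients passed to [water_viscosity()].
#' @return An object of class `medium_properties` with fields `T`, `nu`,
#'   `D_AB`, `rho`, `mu`, `C_sat` (SI units, temperature in degC).
#' @export
#' @examples
#' medium_properties(21)
medium_properties <- function(temperature, pO2 = 0.2095,
                              diffusivity_coef = c(1.155e-9, 4.5e-11),
                              viscosity_coef = c(A = -3.7188, B = 578.919,
                                                 C = -137.546)) {
  stopifnot(length(temperature) == 1)
  rho <- water_density(temperature)
  mu <- water_dynamic_viscosity(temperature, coef = viscosity_coef)
  props <- structure(list(
    T = temperature,
    nu = mu / rho,
    D_AB = oxygen_diffusivity(temperature, coef = diffusivity_coef),
    rho = rho,
    mu = mu,
    C_sat = oxygen_saturation(temperature, pO2 = pO2)
  ), class = "medium_properties")
  stopifnot(all(unlist(props) > 0))
  props
}

#' @export
print.medium_properties <- function(x, ...) {
  cat("Medium properties (water) at", x$T, "degC\n")
  cat(sprintf("  nu    = %.4g m2/s\n", x$nu))
  cat(sprintf("  D_AB  = %.4g m2/s\n", x$D_AB))
  cat(sprintf("  rho   = %.2f kg/m3\n", x$rho))
  cat(sprintf("  mu    = %.4g Pa s\n", x$mu))
  cat(sprintf("  C_sat = %.4g mol/m3\n", x$C_sat))
  invisible(x)
}

#' Bioreactor operating point
#'
#' Captures one operating condition of the surface-aerated vessel: agitation
#' rate, working volume, gas-liquid contact area, wheel diameter and
#' temperature. Agitation is accepted in rpm at this interface and stored in
#' rev/s; volume and area are accepted in the bench units of the instrument
#' (mL, cm2) or SI.
#'
#' @param rpm Agitation rate in revolutions per minute (>= 0).
#' @param volume_mL Working volume in mL (alternatively give `V` in m3).
#' @param area_cm2 Gas-liquid contact area in cm2 (alternatively `A` in m2,
#'   or `specific_area` in 1/m from which A = specific_area * V).
#' @param diameter Wheel diameter in m; default 0.0414 m (configured
#'   package default, see the methods vignette).
#' @param temperature Temperature in degrees Celsius.
#' @param V,A Optional SI overrides for volume (m3) and area (m2).
#' @param specific_area Optional specific area a = A/V in 1/m.
#' @return An object of class `operating_point` with fields `N` (rev/s),
#'   `V` (m3), `A` (m2), `D` (m), `T` (degC).
#' @export
#' @examples
#' operating_point(rpm = 60, volume_mL = 100, specific_area = 16.4)
operating_point <- function(rpm = NULL, volume_mL = NULL, area_cm2 = NULL,
                            diameter = 0.0414, temperature = 21,
                            V = NULL, A = NULL, specific_area = NULL) {
  if (is.null(V)) {
    stopifnot(!is.null(volume_mL))
    V <- volume_mL * 1e-6
  }
  if (is.null(A)) {
    if (!is.null(area_cm2)) {
      A <- area_cm2 * 1e-4
    } else if (!is.null(specific_area)) {
      A <- specific_area * V
    } else {
      stop("operating_point(): supply area_cm2, A or specific_area", call. = FALSE)
    }
  }
  stopifnot(!is.null(rpm), rpm >= 0, V > 0, A > 0, diameter > 0)
  a <- A / V
  if (a <= 1 || a >= 100) {
    stop(sprintf("operating_point(): specific area %.3g 1/m outside the sane (1, 100) range", a),
         call. = FALSE)
  }
  structure(list(N = rpm / 60, V = V, A = A, D = diameter, T = temperature),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("Operating point: %.3g rpm, V = %.3g mL, A = %.3g cm2 (a = %.3g 1/m), D = %.3g m, T = %.3g degC\n",
              x$N * 60, x$V * 1e6, x$A * 1e4, x$A / x$V, x$D, x$T))
  invisible(x)
}

#' Impeller Reynolds number
#'
#' Re = N D^2 / nu with N the agitation rate in rev/s and D the wheel
#' diameter (impeller convention).
#'
#' @param op An [operating_point()].
#' @param props A [medium_properties()] (or a list with field `nu`).
#' @return Dimensionless Reynolds number.
#' @export
reynolds <- function(op, props) {
  stopifnot(op$N >= 0, op$D > 0, props$nu > 0)
  op$N * op$D^2 / props$nu
}

#' Schmidt number
#'
#' Sc = nu / D_AB, the ratio of momentum to oxygen mass diffusivity.
#'
#' @param props A [medium_properties()] (or list with `nu`, `D_AB`).
#' @return Dimensionless Schmidt number.
#' @export
schmidt <- function(props) {
  stopifnot(props$nu > 0, props$D_AB > 0)
  props$nu / props$D_AB
}

#' Geometric number G
#'
#' G = D * A / V: the wheel diameter relative to the equivalent liquid
#' height V/A. This dimensionless group corrects the Sherwood correlation
#' for changes in the working volume.
#'
#' @param op An [operating_point()].
#' @return Dimensionless geometric number.
#' @export
#' @examples
#' op <- operating_point(rpm = 60, volume_mL = 60, specific_area = 26.1)
#' geometric_number(op)  # ~1.08
geometric_number <- function(op) {
  stopifnot(op$D > 0, op$A > 0, op$V > 0)
  op$D * op$A / op$V
}

#' Sherwood number from a mass-transfer coefficient, and back
#'
#' Sh = kL * D / D_AB with D the wheel diameter as characteristic length.
#' `kl_from_sherwood()` is the exact inverse.
#'
#' @param kL Liquid-side mass-transfer coefficient in m/s.
#' @param Sh Sherwood number.
#' @param D Characteristic length (wheel diameter) in m.
#' @param D_AB Molecular diffusivity in m2/s.
#' @return `sherwood_from_kl()` the Sherwood number; `kl_from_sherwood()`
#'   kL in m/s.
#' @export
sherwood_from_kl <- function(kL, D, D_AB) {
  stopifnot(kL >= 0, D > 0, D_AB > 0)
  kL * D / D_AB
}

#' @rdname sherwood_from_kl
#' @export
kl_from_sherwood <- function(Sh, D, D_AB) {
  stopifnot(Sh >= 0, D > 0, D_AB > 0)
  Sh * D_AB / D
}

#' Assemble the dimensionless groups of one condition
#'
#' @param op An [operating_point()].
#' @param props A [medium_properties()]; defaults to water at the operating
#'   temperature.
#' @param kL Optional kL (m/s) from which Sh is also computed.
#' @return A list of class `dimensionless_groups` with `Re`, `Sc`, `G` and,
#'   when `kL` is given, `Sh`.
#' @export
dimensionless_groups <- function(op, props = medium_properties(op$T), kL = NULL) {
  g <- list(Re = reynolds(op, props), Sc = schmidt(props), G = geometric_number(op))
  if (!is.null(kL)) g$Sh <- sherwood_from_kl(kL, op$D, props$D_AB)
  structure(g, class = "dimensionless_groups")
}

#' Tabulated property report
#'
#' Evaluates the property correlations over a set of temperatures; a tidy
#' table suitable for writing with [write_table()].
#'
#' @param temperatures Numeric vector of temperatures in degC.
#' @param pO2 Oxygen partial pressure in atm.
#' @return data.frame with columns `temperature_C`, `nu_m2s`, `D_AB_m2s`,
#'   `C_sat_molm3`, `Sc`.
#' @export
properties_report <- function(temperatures, pO2 = 0.2095) {
  rows <- lapply(temperatures, function(tt) {
    p <- medium_properties(tt, pO2 = pO2)
    data.frame(temperature_C = tt, nu_m2s = p$nu, D_AB_m2s = p$D_AB,
               C_sat_molm3 = p$C_sat, Sc = schmidt(p))
  })
  do.call(rbind, rows)
}
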