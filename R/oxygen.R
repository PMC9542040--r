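# Oxygen physics: vapour pressure, solubility, partial-pressure conversions,
# and the Pcrit -> factorial aerobic scope map.

#' Describe the water a measurement was made in
#'
#' Bundles temperature, salinity and total atmospheric pressure, the three
#' quantities that determine oxygen solubility and the partial pressure of
#' oxygen in air-saturated water.
#'
#' @param temperature Water temperature in degrees Celsius; must lie in
#'   \[-2, 45\], the range spanned by fish respirometry work from polar
#'   seawater to warm ponds.
#' @param salinity Practical salinity (PSU), \eqn{\ge 0}. 0 for freshwater,
#'   about 35 for open ocean.
#' @param pressure Total atmospheric pressure in kPa. Defaults to 101.325
#'   (= 760 mmHg), standard pressure at sea level.
#' @return An object of class `water_state`.
#' @examples
#' water_state(15, salinity = 0)
#' @export
water_state <- function(temperature, salinity = 0, pressure = 101.325) {
  stopifnot(is.numeric(temperature), is.numeric(salinity), is.numeric(pressure))
  if (any(temperature < -2 | temperature > 45)) {
    stop("temperature must lie in [-2, 45] degC", call. = FALSE)
  }
  if (any(salinity < 0)) stop("salinity must be >= 0 PSU", call. = FALSE)
  if (any(pressure <= 0)) stop("pressure must be > 0 kPa", call. = FALSE)
  structure(
    list(temperature = temperature, salinity = salinity, pressure = pressure),
    class = "water_state"
  )
}

#' @export
print.water_state <- function(x, ...) {
  cat(sprintf(
    "<water_state> %g degC, %g PSU, %g kPa\n",
    x$temperature, x$salinity, x$pressure
  ))
  invisible(x)
}

#' Saturated water vapour pressure
#'
#' Buck's (1981) equation for the saturation vapour pressure of water,
#' accurate to better than 0.05% over environmental temperatures. Needed to
#' convert air-saturation percentages to oxygen partial pressures: the gas
#' phase above water is saturated with vapour, so only
#' `pressure - water_vapor_pressure(t)` is available to dry air.
#'
#' @param temperature Temperature in degrees Celsius, in \[-2, 100\].
#' @return Vapour pressure in kPa.
#' @examples
#' water_vapor_pressure(15)  # ~1.71 kPa
#' water_vapor_pressure(100) # ~101.3 kPa: boiling at standard pressure
#' @export
water_vapor_pressure <- function(temperature) {
  stopifnot(is.numeric(temperature))
  if (any(temperature < -2 | temperature > 100)) {
    stop("temperature out of supported range [-2, 100] degC", call. = FALSE)
  }
  0.61121 * exp((18.678 - temperature / 234.5) *
                  (temperature / (257.14 + temperature)))
}

# Garcia & Gordon (1992) combined fit of the Benson & Krause oxygen
# solubility data, umol/kg coefficient set.
.gg_A <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
.gg_B <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
.gg_C0 <- -2.75915e-7

#' Oxygen saturation concentration of water
#'
#' Equilibrium O2 concentration of water in contact with humid air, from the
#' Garcia & Gordon (1992) combined fit to the Benson & Krause data — the
#' de-facto standard solubility formula in oceanography and respirometry.
#' The fit is nominally per kilogram of water; per litre differs by the
#' water density (< 3% even in seawater), which is well inside the precision
#' of literature Pcrit conversions, so the two are treated interchangeably
#' here.
#'
#' At non-standard total pressure the concentration is scaled by the ratio
#' of dry-air pressures, `(p - pv) / (101.325 - pv)`.
#'
#' @param state A [water_state()].
#' @return Saturation concentration in umol O2 per kg (~ per L) of water.
#' @examples
#' o2_saturation_concentration(water_state(0, 0))   # ~457 umol/kg
#' o2_saturation_concentration(water_state(20, 35)) # ~225 umol/kg
#' @export
o2_saturation_concentration <- function(state) {
  stopifnot(inherits(state, "water_state"))
  t <- state$temperature
  s <- state$salinity
  ts <- log((298.15 - t) / (273.15 + t))
  lnc <- .gg_A[1] + .gg_A[2] * ts + .gg_A[3] * ts^2 + .gg_A[4] * ts^3 +
    .gg_A[5] * ts^4 + .gg_A[6] * ts^5 +
    s * (.gg_B[1] + .gg_B[2] * ts + .gg_B[3] * ts^2 + .gg_B[4] * ts^3) +
    .gg_C0 * s^2
  pv <- water_vapor_pressure(t)
  exp(lnc) * (state$pressure - pv) / (101.325 - pv)
}

# mole fraction of O2 in dry air; molar mass of O2 (g/mol)
.o2_mole_fraction <- 0.2095
.o2_molar_mass <- 31.998

#' Partial pressure of oxygen in air-saturated water
#'
#' @param state A [water_state()].
#' @return pO2 in kPa: `0.2095 * (pressure - water_vapor_pressure(t))`.
#' @export
o2_air_saturation_kpa <- function(state) {
  stopifnot(inherits(state, "water_state"))
  .o2_mole_fraction * (state$pressure - water_vapor_pressure(state$temperature))
}

.pcrit_units <- c("kPa", "mmHg", "percent_airsat", "mg_per_L", "umol_per_L")

#' Convert an oxygen tension or concentration to kPa
#'
#' Converts the units found in the Pcrit literature to a common partial
#' pressure. Pressure units rescale exactly; percent air saturation uses the
#' humidity-corrected pO2 of air-saturated water; concentration units use
#' Henry-law proportionality through the saturation concentration,
#' `pO2 = conc / sat_conc * pO2_sat`.
#'
#' @param value Numeric value in `unit`.
#' @param unit One of `"kPa"`, `"mmHg"`, `"percent_airsat"`, `"mg_per_L"`,
#'   `"umol_per_L"`.
#' @param state A [water_state()]; required for `percent_airsat` and the
#'   concentration units, ignored for pure pressure units.
#' @return Partial pressure of O2 in kPa.
#' @seealso [from_kpa()] for the inverse map.
#' @examples
#' to_kpa(760, "mmHg")                                  # 101.325
#' to_kpa(100, "percent_airsat", water_state(15, 0))    # ~20.87
#' @export
to_kpa <- function(value, unit, state = NULL) {
  unit <- match.arg(unit, .pcrit_units)
  if (unit %in% c("percent_airsat", "mg_per_L", "umol_per_L") &&
      !inherits(state, "water_state")) {
    stop("unit '", unit, "' requires a water_state (temperature, salinity, ",
         "pressure)", call. = FALSE)
  }
  switch(unit,
    kPa = value,
    mmHg = value * 101.325 / 760,
    percent_airsat = value / 100 * o2_air_saturation_kpa(state),
    mg_per_L = {
      conc <- value / .o2_molar_mass * 1000
      conc / o2_saturation_concentration(state) * o2_air_saturation_kpa(state)
    },
    umol_per_L =
      value / o2_saturation_concentration(state) * o2_air_saturation_kpa(state)
  )
}

#' Convert an oxygen partial pressure in kPa back to another unit
#'
#' Exact inverse of [to_kpa()] at a fixed [water_state()].
#'
#' @inheritParams to_kpa
#' @param value Partial pressure in kPa.
#' @return Value expressed in `unit`.
#' @export
from_kpa <- function(value, unit, state = NULL) {
  unit <- match.arg(unit, .pcrit_units)
  if (unit %in% c("percent_airsat", "mg_per_L", "umol_per_L") &&
      !inherits(state, "water_state")) {
    stop("unit '", unit, "' requires a water_state", call. = FALSE)
  }
  switch(unit,
    kPa = value,
    mmHg = value * 760 / 101.325,
    percent_airsat = value / o2_air_saturation_kpa(state) * 100,
    mg_per_L = value / o2_air_saturation_kpa(state) *
      o2_saturation_concentration(state) * .o2_molar_mass / 1000,
    umol_per_L = value / o2_air_saturation_kpa(state) *
      o2_saturation_concentration(state)
  )
}

#' Factorial aerobic scope from critical oxygen tension
#'
#' Maps Pcrit to factorial aerobic scope under the assumption that standard
#' metabolic rate scales proportionally with ambient oxygen tension:
#' `FAS = 21 / Pcrit`, with Pcrit floored at 2 kPa so that FAS is capped at
#' 10.5. The numerator is the nominal atmospheric pO2 of 21 kPa (not
#' humidity-corrected), matching the convention of the source formula.
#'
#' @param pcrit Critical oxygen tension in kPa, > 0. Vectorized.
#' @param numerator Reference oxygen tension in kPa (default 21).
#' @param floor Lower clip for Pcrit in kPa (default 2); caps FAS at
#'   `numerator / floor`.
#' @return A data.frame with columns `pcrit_input`, `pcrit_clipped`, `fas`.
#' @examples
#' fas_from_pcrit(21)      # fas = 1
#' fas_from_pcrit(1)$fas   # 10.5, the cap
#' @export
fas_from_pcrit <- function(pcrit, numerator = 21, floor = 2) {
  stopifnot(is.numeric(pcrit))
  if (any(!is.finite(pcrit)) || any(pcrit <= 0)) {
    stop("pcrit must be finite and > 0", call. = FALSE)
  }
  clipped <- pmax(pcrit, floor)
  out <- data.frame(
    pcrit_input = pcrit,
    pcrit_clipped = clipped,
    fas = numerator / clipped
  )
  class(out) <- c("fas_result", "data.frame")
  out
}

#' Project factorial aerobic scope over a temperature grid
#'
#' Evaluates the fitted model's posterior-mean fixed effects on a grid of
#' water temperatures for a hypothetical fish of given body mass and genome
#' size, in freshwater (salinity 0) or seawater (35 PSU), then maps the
#' predicted Pcrit through [fas_from_pcrit()]. Random effects are set to 0
#' (a "typical" species) and residual metabolic rate to 0 (average
#' metabolism), so the surface reflects the fixed-effect structure only.
#'
#' @param temps Numeric vector (or single-column data.frame) of water
#'   temperatures in degrees Celsius, one per grid cell.
#' @param salinity_class `"fresh"` (salinity 0) or `"marine"` (35 PSU).
#' @param log10_mass log10 body mass (g) of the projected fish.
#' @param log10_gs log10 genome size (pg).
#' @param posterior A fitted model from [fit_pcrit()].
#' @param numerator,floor Passed to [fas_from_pcrit()].
#' @return A data.frame with `temperature`, `pcrit_pred`, `pcrit_clipped`,
#'   `fas` and a logical `extrapolated` flag for cells outside the fitted
#'   temperature range (a warning is issued when any is flagged).
#' @export
project_fas_grid <- function(temps, salinity_class = c("marine", "fresh"),
                             log10_mass, log10_gs, posterior,
                             numerator = 21, floor = 2) {
  salinity_class <- match.arg(salinity_class)
  if (is.data.frame(temps)) temps <- temps[[ncol(temps)]]
  stopifnot(is.numeric(temps), inherits(posterior, "pcrit_fit"))
  sal <- if (salinity_class == "marine") 35 else 0
  newdata <- data.frame(
    species = "grid", temp_meas = temps, rel_acclim = 0, salinity = sal,
    log10_mass = log10_mass, log10_gs = log10_gs, resid_mr = 0,
    log10_pct = 0, log10_maxbm = log10_mass, respirometry = "intermittent",
    stringsAsFactors = FALSE
  )
  X <- build_design(newdata, posterior$spec, check_species = FALSE)$X
  beta <- posterior_mean_beta(posterior)
  pred <- drop(X %*% beta)
  rng <- posterior$temp_range
  extrap <- !is.null(rng) & (temps < rng[1] | temps > rng[2])
  if (any(extrap)) {
    warning(sum(extrap), " grid cell(s) outside the fitted temperature range [",
            signif(rng[1], 4), ", ", signif(rng[2], 4), "]; FAS extrapolated",
            call. = FALSE)
  }
  clipped <- pmax(pred, floor)
  data.frame(
    temperature = temps,
    pcrit_pred = pred,
    pcrit_clipped = clipped,
    fas = numerator / clipped,
    extrapolated = extrap
  )
}
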