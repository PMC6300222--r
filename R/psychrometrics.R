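# Moist-air state functions: saturation vapor pressure (Magnus), water
# content, latent heat of vaporization (saturated steam table), air density.

#' Moist air state
#'
#' @param temperature degC, in (-50, 60).
#' @param relative_humidity fraction in `[0, 1]`.
#' @param pressure total pressure (Pa), default sea level.
#' @return list of class `air_state`.
#' @export
air_state <- function(temperature, relative_humidity, pressure = 101325) {
  if (!is.finite(temperature) || temperature <= -50 || temperature >= 60)
    stop("temperature out of range (-50, 60) degC")
  if (relative_humidity < 0 || relative_humidity > 1)
    stop("relative humidity must be a fraction in [0, 1]")
  if (pressure <= 0) stop("pressure must be positive")
  structure(list(temperature = temperature,
                 relative_humidity = relative_humidity,
                 pressure = pressure), class = "air_state")
}

#' Saturation vapor pressure over water (Magnus formula)
#'
#' `e_s = 610.94 * exp(17.625 T / (T + 243.04))` Pa, accurate to a fraction
#' of a percent over the physiological range.
#'
#' @param t_c temperature (degC), in (-45, 60).
#' @return Pa; vectorised.
#' @export
saturation_vapor_pressure <- function(t_c) {
  if (any(!is.finite(t_c)) || any(t_c <= -45) || any(t_c >= 60))
    stop("temperature out of Magnus validity range (-45, 60) degC")
  610.94 * exp(17.625 * t_c / (t_c + 243.04))
}

#' Water content of moist air
#'
#' Mixing ratio `w = 0.622 rh e_s / (p - rh e_s)` (kg water per kg dry air)
#' or the specific-humidity ("mass fraction") convention `w / (1 + w)`
#' (kg water per kg moist air).  Both are reported in g/kg; the two
#' conventions differ by a few percent at physiological temperatures.
#'
#' @param state an [air_state()], or a temperature (degC) combined with `rh`.
#' @param convention `"mass_fraction"` (default) or `"mixing_ratio"`.
#' @param rh,pressure used when `state` is given as a bare temperature.
#' @return g water per kg air.
#' @export
water_content <- function(state, convention = c("mass_fraction",
                                                "mixing_ratio"),
                          rh = 1, pressure = 101325) {
  convention <- match.arg(convention)
  if (!inherits(state, "air_state")) state <- air_state(state, rh, pressure)
  e <- state$relative_humidity * saturation_vapor_pressure(state$temperature)
  if (e >= state$pressure)
    stop("vapor pressure meets or exceeds total pressure")
  w <- 0.622 * e / (state$pressure - e)
  1000 * switch(convention, mixing_ratio = w, mass_fraction = w / (1 + w))
}

#' Saturated steam table (latent heat of vaporization)
#'
#' Temperature (degC, 0-100 in 5 degC steps) against the latent heat of
#' vaporization of water at saturation, from standard saturated-steam
#' property tables (stored as kJ/kg, reported in cal/g).
#'
#' @format data.frame with `t_c` and `dh_vap_kj_kg`.
#' @export
steam_table <- data.frame(
  t_c = seq(0, 100, by = 5),
  dh_vap_kj_kg = c(2500.9, 2489.0, 2477.2, 2465.4, 2453.5, 2441.7, 2429.8,
                   2417.9, 2406.0, 2394.0, 2382.0, 2369.8, 2357.6, 2345.4,
                   2333.0, 2320.6, 2308.0, 2295.3, 2282.5, 2269.5, 2256.4))

#' Latent heat of vaporization of water
#'
#' Linear interpolation in the bundled [steam_table]; strictly decreasing in
#' temperature.  Extrapolation outside 0-100 degC is an error.
#'
#' @param t_c temperature (degC).
#' @return cal/g; vectorised.
#' @export
latent_heat <- function(t_c) {
  if (any(t_c < 0) || any(t_c > 100))
    stop("temperature outside steam table range 0-100 degC")
  stats::approx(steam_table$t_c, steam_table$dh_vap_kj_kg, xout = t_c)$y / 4.184
}

#' Density of (dry) air
#'
#' Ideal gas: `rho = p / (287.05 T_K)`.  At 35 degC and sea level this is
#' 1.146 g/L, the constant used in the respiratory air-mass budget.
#'
#' @param t_c temperature (degC).
#' @param pressure Pa.
#' @return g/L (numerically equal to kg/m^3); vectorised.
#' @export
air_density <- function(t_c, pressure = 101325) {
  pressure / (287.05 * (t_c + 273.15))
}
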