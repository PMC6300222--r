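# Flow-regime diagnostics: Reynolds and Womersley numbers, regime
# classification, the reversed-Reynolds maximum laminar flow estimate, and
# Hagen-Poiseuille duct resistance.

#' Physical properties of air
#'
#' Defaults are for air near 15 degC.  Thermal conductivity is evaluated at a
#' given temperature by [air_conductivity()] where temperature dependence
#' matters.
#'
#' @param kinematic_viscosity m^2/s (default 1.412e-5, air at 15 degC).
#' @param dynamic_viscosity Pa s.
#' @param thermal_conductivity W/(m K).
#' @param specific_heat J/(kg K).
#' @param reference_temperature degC.
#' @return list of class `fluid_properties`.
#' @export
air_properties <- function(kinematic_viscosity = 1.412e-5,
                           dynamic_viscosity = 1.78e-5,
                           thermal_conductivity = 0.0253,
                           specific_heat = 1004,
                           reference_temperature = 15) {
  vals <- c(kinematic_viscosity, dynamic_viscosity, thermal_conductivity,
            specific_heat)
  if (any(vals <= 0)) stop("fluid properties must be positive")
  structure(as.list(environment()), class = "fluid_properties")
}

#' Thermal conductivity of air at temperature T
#' @param t_c temperature (degC).
#' @return W/(m K); linear fit over the physiological range.
#' @export
air_conductivity <- function(t_c) 0.02414 + 7.36e-5 * t_c

#' Reynolds number of duct flow
#'
#' `Re = 4 Q / (P nu)` for volumetric flow `Q` through a cross section of
#' wetted perimeter `P`.
#'
#' @param q volumetric flow rate (m^3/s), >= 0.
#' @param perimeter wetted perimeter (m).
#' @param nu kinematic viscosity (m^2/s).
#' @return dimensionless; vectorised.
#' @export
reynolds <- function(q, perimeter, nu = 1.412e-5) {
  if (any(perimeter <= 0) || any(nu <= 0))
    stop("perimeter and viscosity must be positive")
  if (any(q < 0)) stop("flow rate must be >= 0")
  4 * q / (perimeter * nu)
}

#' Womersley number of oscillatory duct flow
#'
#' `Wo = (Dh / 2) * sqrt(2 pi f / nu)`; below 1 the flow is quasi-steady.
#'
#' @param dh hydraulic diameter (m).
#' @param f oscillation (breathing) frequency (Hz), >= 0.
#' @param nu kinematic viscosity (m^2/s).
#' @return dimensionless; vectorised.
#' @export
womersley <- function(dh, f, nu = 1.412e-5) {
  if (any(dh <= 0)) stop("hydraulic diameter must be positive")
  if (any(f < 0)) stop("frequency must be >= 0")
  (dh / 2) * sqrt(2 * pi * f / nu)
}

#' Classify flow regime and steadiness
#'
#' Laminar below Re 2000, transitional on the closed interval 2000-4000,
#' turbulent above 4000.  Quasi-steady below Wo 1, unsteady above 10,
#' intermediate otherwise (boundaries inclusive to intermediate).
#'
#' @param re Reynolds number(s), >= 0.
#' @param wo Womersley number(s), >= 0.
#' @return data.frame with `regime` and `steadiness`.
#' @export
classify_flow <- function(re, wo) {
  if (any(re < 0) || any(wo < 0)) stop("Re and Wo must be >= 0")
  regime <- ifelse(re < 2000, "laminar",
                   ifelse(re <= 4000, "transitional", "turbulent"))
  steadiness <- ifelse(wo < 1, "quasi_steady",
                       ifelse(wo <= 10, "intermediate", "unsteady"))
  data.frame(regime = regime, steadiness = steadiness,
             stringsAsFactors = FALSE)
}

#' Reversed-Reynolds maximum laminar flow
#'
#' Solves the Reynolds equation for flow at a fixed target Reynolds number at
#' every cross section of the main flow path and returns the minimum:
#' `Q = min_i Re_target * P_i * nu / 4`.  At the returned flow no station on
#' the path exceeds `re_target`, making it an upper bound for laminar resting
#' flow.
#'
#' @param x an [airway()].
#' @param re_target target Reynolds number (default 2000, the transition to
#'   turbulence).
#' @param nu kinematic viscosity (m^2/s).
#' @param include_trachea include the artificial tracheal extension in the
#'   cross-sectional scan (default FALSE).
#' @return flow rate (m^3/s); the governing station index (within the scanned
#'   path) is attached as attribute `"station"`.
#' @export
reversed_reynolds_flow <- function(x, re_target = 2000, nu = 1.412e-5,
                                   include_trachea = FALSE) {
  path <- main_path(x, include_trachea = include_trachea)
  if (nrow(path) == 0L) stop("airway has no main-path stations")
  q_i <- re_target * path$perimeter * nu / 4
  i <- which.min(q_i)
  structure(q_i[i], station = i)
}

#' Hagen-Poiseuille resistance of a serial pipe
#'
#' `R = 8 mu l / (pi r^4)`; resistance is proportional to length and to the
#' inverse fourth power of the radius.
#'
#' @param mu dynamic viscosity (Pa s).
#' @param l pipe length (m).
#' @param r pipe radius (m).
#' @return resistance (Pa s / m^3).
#' @export
resistance_serial <- function(mu, l, r) {
  if (any(mu <= 0) || any(l <= 0) || any(r <= 0))
    stop("viscosity, length and radius must be positive")
  8 * mu * l / (pi * r^4)
}

#' Combined resistance of parallel channels
#'
#' Reciprocal of the summed channel conductances, as for resistors in
#' parallel; always at most the smallest input.
#'
#' @param r_channels vector of channel resistances (Pa s / m^3), all > 0.
#' @export
resistance_parallel <- function(r_channels) {
  if (length(r_channels) == 0L) stop("need at least one channel")
  if (any(r_channels <= 0)) stop("channel resistances must be positive")
  1 / sum(1 / r_channels)
}

#' Per-station flow-regime report
#'
#' @param x an [airway()].
#' @param q volumetric flow rate (m^3/s).
#' @param f breathing frequency (Hz).
#' @param nu kinematic viscosity (m^2/s).
#' @param re_target Reynolds target for the reversed-Reynolds summary.
#' @param include_trachea scan the tracheal extension too?
#' @return list of class `regime_report`: `stations` (s, Dh, Re, Wo, regime,
#'   steadiness) and `summary` (max Re, max Wo, reversed-Reynolds flow).
#' @export
regime_report <- function(x, q, f, nu = 1.412e-5, re_target = 2000,
                          include_trachea = FALSE) {
  path <- main_path(x, include_trachea = include_trachea)
  dh <- hydraulic_diameter(path$area, path$perimeter)
  re <- reynolds(q, path$perimeter, nu)
  wo <- womersley(dh, f, nu)
  cls <- classify_flow(re, wo)
  stations <- data.frame(s = path$s, region = path$region, Dh = dh,
                         Re = re, Wo = wo, regime = cls$regime,
                         steadiness = cls$steadiness,
                         stringsAsFactors = FALSE)
  structure(list(stations = stations,
                 summary = list(max_Re = max(re), max_Wo = max(wo),
                                reversed_reynolds_Q =
                                  as.numeric(reversed_reynolds_flow(
                                    x, re_target, nu, include_trachea)))),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<regime report: %d stations, max Re %.0f, max Wo %.2f, ",
              nrow(x$stations), s$max_Re, s$max_Wo))
  cat(sprintf("reversed-Reynolds Q %.4g m^3/s (%.1f L/min)>\n",
              s$reversed_reynolds_Q, s$reversed_reynolds_Q * 60000))
  invisible(x)
}
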