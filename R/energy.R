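# Respiratory caloric and water budgets: cost of conditioning inspired air,
# recovery on expiration, efficiency and water-savings fractions, and the
# comparative extant-taxa arithmetic.

#' Sensible heating cost
#'
#' `cost = m_air * Cp * dT` (thermal calories).
#'
#' @param m_air_g mass of air (g), > 0.
#' @param cp specific heat of air (cal/(g degC)), default 0.24.
#' @param dt_c temperature change (degC).
#' @return cal; vectorised.
#' @export
sensible_cost <- function(m_air_g, cp = 0.24, dt_c) {
  if (any(m_air_g <= 0)) stop("air mass must be positive")
  if (any(cp <= 0)) stop("specific heat must be positive")
  m_air_g * cp * dt_c
}

#' Latent cost (or savings) between two air states
#'
#' Absolute difference in water content between the two states, times the
#' air mass, priced at the latent heat of vaporization of the destination
#' temperature (evaporation at the warm end, condensation at the cool end).
#'
#' @param m_air_g mass of air (g).
#' @param state_in,state_out [air_state()] at entry and exit.
#' @param convention water-content convention, see [water_content()].
#' @return cal.
#' @export
latent_cost <- function(m_air_g, state_in, state_out,
                        convention = "mass_fraction") {
  if (any(m_air_g <= 0)) stop("air mass must be positive")
  dw <- abs(water_content(state_out, convention) -
              water_content(state_in, convention))       # g/kg
  water_g <- dw * m_air_g / 1000
  water_g * latent_heat(state_out$temperature)
}

#' Describe one breath for budget accounting
#'
#' @param ambient [air_state()] of inspired air (default 15 degC, 50% rh).
#' @param body_temperature_c core temperature (degC), default 35.
#' @param expired_temperature_c air temperature at the nostril on expiration
#'   (degC); must lie between ambient and body temperature.
#' @param tidal_volume_l tidal volume (L); used to compute `air_mass_g` when
#'   that is not given.
#' @param air_mass_g mass of air per breath (g).
#' @param cp specific heat of air (cal/(g degC)).
#' @return list of class `breath_scenario`.
#' @export
breath_scenario <- function(ambient = air_state(15, 0.5),
                            body_temperature_c = 35,
                            expired_temperature_c,
                            tidal_volume_l = NULL,
                            air_mass_g = NULL,
                            cp = 0.24) {
  if (is.null(air_mass_g)) {
    if (is.null(tidal_volume_l))
      stop("give tidal_volume_l or air_mass_g")
    air_mass_g <- air_mass(tidal_volume_l)
  }
  if (expired_temperature_c > body_temperature_c)
    stop("expired air cannot be warmer than the body")
  if (expired_temperature_c < ambient$temperature)
    stop("expired air cannot be cooler than ambient for recovery accounting")
  if (cp <= 0) stop("specific heat must be positive")
  structure(list(ambient = ambient,
                 body_temperature_c = body_temperature_c,
                 expired_temperature_c = expired_temperature_c,
                 air_mass_g = air_mass_g, cp = cp),
            class = "breath_scenario")
}

saturated <- function(t_c, pressure = 101325) air_state(t_c, 1, pressure)

#' Caloric budget of one breath
#'
#' Inspiration costs: sensible heating from ambient to body temperature plus
#' latent cost of humidifying to saturation at body temperature (priced at
#' body temperature).  Expiration savings: sensible cooling from body to the
#' expired temperature plus latent recovery between saturation at body and
#' saturation at expired temperature (priced at the expired temperature,
#' since expired air leaves saturated).  Fractions are savings over costs.
#'
#' @param scenario a [breath_scenario()].
#' @param convention water-content convention, see [water_content()].
#' @return list of class `energy_budget` with sensible/latent/total costs and
#'   savings (cal), `heat_savings_fraction` and `water_savings_fraction`.
#' @export
expiration_savings <- function(scenario, convention = "mass_fraction") {
  stopifnot(inherits(scenario, "breath_scenario"))
  amb <- scenario$ambient
  tb <- scenario$body_temperature_c
  tex <- scenario$expired_temperature_c
  m <- scenario$air_mass_g
  p <- amb$pressure
  s_cost <- sensible_cost(m, scenario$cp, tb - amb$temperature)
  l_cost <- latent_cost(m, amb, saturated(tb, p), convention)
  s_save <- sensible_cost(m, scenario$cp, tb - tex)
  l_save <- latent_cost(m, saturated(tb, p), saturated(tex, p), convention)
  budget <- list(sensible_cost = s_cost, latent_cost = l_cost,
                 total_cost = s_cost + l_cost,
                 sensible_saved = s_save, latent_saved = l_save,
                 total_saved = s_save + l_save,
                 heat_savings_fraction = (s_save + l_save) / (s_cost + l_cost),
                 water_savings_fraction =
                   water_savings_fraction(scenario, convention))
  class(budget) <- "energy_budget"
  budget
}

#' @export
print.energy_budget <- function(x, ...) {
  cat(sprintf(paste0("<energy budget: cost %.0f cal (%.0f sensible + %.0f ",
                     "latent), recovered %.0f cal, heat savings %.0f%%, ",
                     "water savings %.0f%%>\n"),
              x$total_cost, x$sensible_cost, x$latent_cost, x$total_saved,
              100 * x$heat_savings_fraction, 100 * x$water_savings_fraction))
  invisible(x)
}

#' Fraction of respiratory water recovered
#'
#' Countercurrent water-recovery accounting: water condensed out of saturated
#' body-temperature air on its way down to the expired temperature, divided
#' by the water added to the inspired breath (saturation at body temperature
#' minus ambient water content).
#'
#' @param scenario a [breath_scenario()].
#' @param convention water-content convention, see [water_content()].
#' @return fraction in `[0, 1]`.
#' @export
water_savings_fraction <- function(scenario, convention = "mass_fraction") {
  stopifnot(inherits(scenario, "breath_scenario"))
  amb <- scenario$ambient
  p <- amb$pressure
  w_body <- water_content(saturated(scenario$body_temperature_c, p),
                          convention)
  w_exp <- water_content(saturated(scenario$expired_temperature_c, p),
                         convention)
  w_amb <- water_content(amb, convention)
  denom <- w_body - w_amb
  if (denom <= 0) stop("no net water added on inspiration (denominator <= 0)")
  (w_body - w_exp) / denom
}

#' Comparative heat budgets for extant taxa
#'
#' Reproduces the published per-taxon arithmetic: heat capacity = air mass x
#' 0.24 cal/(g degC), energy = heat capacity x temperature change.  Because
#' the published tables round intermediates inconsistently, an explicit
#' `heat_capacity` column (printed values) takes precedence; where absent it
#' is recomputed to 3 significant figures.
#'
#' @param rows data.frame with `mass_air_g`, `dt_c` and optionally
#'   `heat_capacity_cal_c` (NA to recompute) and any id columns.
#' @param cp specific heat (cal/(g degC)).
#' @return `rows` with `heat_capacity_cal_c` and `energy_cal` filled in.
#' @export
comparative_budget <- function(rows, cp = 0.24) {
  stopifnot(is.data.frame(rows))
  if (!all(c("mass_air_g", "dt_c") %in% names(rows)))
    stop("rows must have mass_air_g and dt_c columns")
  if (is.null(rows$heat_capacity_cal_c))
    rows$heat_capacity_cal_c <- NA_real_
  idx <- is.na(rows$heat_capacity_cal_c)
  rows$heat_capacity_cal_c[idx] <- signif(rows$mass_air_g[idx] * cp, 3)
  rows$energy_cal <- rows$heat_capacity_cal_c * rows$dt_c
  rows
}
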