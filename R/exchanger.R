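# Reduced-order quasi-1D heat and moisture exchanger along the airway
# centerline.  Bulk air temperature and water content relax toward the wall
# state at a rate set by a laminar constant-wall-temperature Nusselt number
# with a Dean-number curvature enhancement, a wall conduction resistance in
# series, and a Lewis-analogy mass-transfer coefficient.  Integration is a
# fixed-step RK4 march at station resolution with linear property
# interpolation.

#' Mucosal wall properties
#'
#' Defaults are tissue-database values for nasal mucosa with an effective
#' conduction path of 0.5 mm between the airway and the adjacent vasculature.
#'
#' @param thickness_m wall thickness (m), default 5e-4.
#' @param conductivity_w_mk thermal conductivity (W/(m K)), default 0.34.
#' @param density_kg_m3 wall density (kg/m^3), default 1102.
#' @param specific_heat_j_kgk wall specific heat (J/(kg K)), default 3150.
#' @return list of class `wall_properties`; the wall surface is always taken
#'   to be saturated (100% relative humidity).
#' @export
wall_properties <- function(thickness_m = 5e-4, conductivity_w_mk = 0.34,
                            density_kg_m3 = 1102,
                            specific_heat_j_kgk = 3150) {
  vals <- c(thickness_m, conductivity_w_mk, density_kg_m3,
            specific_heat_j_kgk)
  if (any(vals <= 0)) stop("wall properties must be positive")
  structure(list(thickness_m = thickness_m,
                 conductivity_w_mk = conductivity_w_mk,
                 density_kg_m3 = density_kg_m3,
                 specific_heat_j_kgk = specific_heat_j_kgk,
                 wall_rh = 1), class = "wall_properties")
}

#' Exchanger model configuration
#'
#' @param nu0 laminar constant-wall-temperature Nusselt number, default 3.66.
#' @param alpha curvature (Dean) enhancement coefficient in
#'   `Nu = nu0 * (1 + alpha * sqrt(De))`, default 0.1; 0 disables the
#'   enhancement.
#' @param moisture simulate water transfer (Lewis analogy, Sh = Nu)?
#' @param use_film_properties evaluate air conductivity at the local film
#'   temperature (mean of bulk and wall) rather than at the ambient reference.
#' @param include_trachea integrate through the artificial tracheal
#'   extension (default FALSE: the path ends at the choana).
#' @param share_basis `"sensible"` (temperature-rise share, default) or
#'   `"enthalpy"` (sensible + latent) for per-region heating shares.
#' @param expiration_wall `"mirror"` (wall profile equals the local inspired
#'   air temperature, default) or `"uniform_offset"` (body temperature minus
#'   the inspiratory warming, applied uniformly).
#' @return list of class `exchanger_config`.
#' @export
exchanger_config <- function(nu0 = 3.66, alpha = 0.1, moisture = TRUE,
                             use_film_properties = TRUE,
                             include_trachea = FALSE,
                             share_basis = c("sensible", "enthalpy"),
                             expiration_wall = c("mirror",
                                                 "uniform_offset")) {
  if (nu0 <= 0) stop("nu0 must be positive")
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(nu0 = nu0, alpha = alpha, moisture = moisture,
                 use_film_properties = use_film_properties,
                 include_trachea = include_trachea,
                 share_basis = match.arg(share_basis),
                 expiration_wall = match.arg(expiration_wall)),
            class = "exchanger_config")
}

# effective heat transfer coefficient (W/m^2K): laminar Nu with Dean
# enhancement, in series with the wall conduction film
h_effective <- function(perimeter, dh, kappa, q, t_bulk, t_wall, wall,
                        config, fluid) {
  re <- 4 * q / (perimeter * fluid$kinematic_viscosity)
  de <- re * sqrt(pmax(dh * kappa / 2, 0))
  nu_number <- config$nu0 * (1 + config$alpha * sqrt(de))
  k_air <- if (config$use_film_properties)
    air_conductivity((t_bulk + t_wall) / 2) else fluid$thermal_conductivity
  h_conv <- nu_number * k_air / dh
  1 / (1 / h_conv + wall$thickness_m / wall$conductivity_w_mk)
}

# RK4 march of (T, w) along the station grid; wall_t / wall_w are per-station
# wall temperature (degC) and saturated water content (g/kg).  Returns the
# per-station bulk state.
march_exchange <- function(s, perimeter, dh, kappa, wall_t, wall_w, q,
                           t0, w0, mdot_cp, wall, config, fluid) {
  n <- length(s)
  t_air <- numeric(n); w_air <- numeric(n)
  t_air[1L] <- t0; w_air[1L] <- w0
  interp <- function(v, i, frac) v[i] + frac * (v[i + 1L] - v[i])
  deriv <- function(i, frac, tt, ww) {
    p_l <- interp(perimeter, i, frac)
    dh_l <- interp(dh, i, frac)
    k_l <- interp(kappa, i, frac)
    tw_l <- interp(wall_t, i, frac)
    ww_l <- interp(wall_w, i, frac)
    h <- h_effective(p_l, dh_l, k_l, q, tt, tw_l, wall, config, fluid)
    lam <- h * p_l
    c(dT = lam * (tw_l - tt) / mdot_cp,
      dW = if (config$moisture) lam * (ww_l - ww) / mdot_cp else 0)
  }
  for (i in seq_len(n - 1L)) {
    hstep <- s[i + 1L] - s[i]
    y <- c(t_air[i], w_air[i])
    k1 <- deriv(i, 0, y[1L], y[2L])
    k2 <- deriv(i, 0.5, y[1L] + hstep / 2 * k1[1L], y[2L] + hstep / 2 * k1[2L])
    k3 <- deriv(i, 0.5, y[1L] + hstep / 2 * k2[1L], y[2L] + hstep / 2 * k2[2L])
    k4 <- deriv(i, 1, y[1L] + hstep * k3[1L], y[2L] + hstep * k3[2L])
    y <- y + hstep / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    # bulk air cannot hold more water than saturation at its own temperature
    if (config$moisture) {
      w_sat <- water_content(air_state(y[1L], 1), "mass_fraction")
      y[2L] <- min(y[2L], w_sat)
    }
    t_air[i + 1L] <- y[1L]
    w_air[i + 1L] <- y[2L]
  }
  list(t_air = t_air, w_air = w_air)
}

region_shares <- function(region, t_air, w_air, cp, config) {
  n <- length(t_air)
  dtp <- diff(t_air)
  gain <- cp * dtp
  if (config$share_basis == "enthalpy")
    gain <- gain + 2.45e6 * diff(w_air) / 1000   # J/kg per g/kg of water
  reg <- region[-n]                               # interval -> upstream region
  tot <- sum(gain)
  if (abs(tot) < 1e-12) {
    shares <- tapply(gain, reg, sum) * 0
  } else {
    shares <- tapply(gain, reg, sum) / tot
  }
  out <- as.numeric(shares)
  names(out) <- names(shares)
  out
}

finish_result <- function(path, st, q, phase, wall_t, cp, config) {
  profile <- data.frame(s = path$s, region = path$region,
                        T_air = st$t_air, w_gkg = st$w_air,
                        wall_T = wall_t, stringsAsFactors = FALSE)
  exit_i <- if (phase == "inspiration") nrow(profile) else 1L
  structure(list(profile = profile,
                 exit_temperature = st$t_air[exit_i],
                 exit_water = st$w_air[exit_i],
                 region_heating_share =
                   region_shares(path$region, st$t_air, st$w_air, cp, config),
                 Q = q, phase = phase),
            class = "exchange_result")
}

#' @export
print.exchange_result <- function(x, ...) {
  cat(sprintf("<%s at Q = %.1f L/min: exit %.2f degC, %.2f g/kg>\n",
              x$phase, x$Q * 60000, x$exit_temperature, x$exit_water))
  invisible(x)
}

prepare_path <- function(x, config) {
  path <- main_path(x, include_trachea = config$include_trachea)
  if (nrow(path) < 3L) stop("too few main-path stations to integrate")
  path$dh <- hydraulic_diameter(path$area, path$perimeter)
  path$kappa <- centerline_curvature(path)
  path
}

#' Simulate inspiratory heat and moisture exchange
#'
#' Marches ambient air from the nostril to the choana past walls held at body
#' temperature and saturation.  Emits a warning when any station Reynolds
#' number exceeds 4000 (the laminar closure is then optimistic).
#'
#' @param x an [airway()].
#' @param q volumetric flow rate (m^3/s).
#' @param ambient inspired [air_state()], default 15 degC / 50% rh.
#' @param body_t_c wall (core) temperature, degC.
#' @param wall [wall_properties()].
#' @param config [exchanger_config()].
#' @param fluid [air_properties()].
#' @return `exchange_result`: per-station profile (s, region, T_air, w_gkg,
#'   wall_T), exit state at the choana, per-region heating shares, flow and
#'   phase.
#' @export
simulate_inspiration <- function(x, q, ambient = air_state(15, 0.5),
                                 body_t_c = 35, wall = wall_properties(),
                                 config = exchanger_config(),
                                 fluid = air_properties()) {
  if (q <= 0) stop("flow rate must be positive")
  path <- prepare_path(x, config)
  re_max <- max(reynolds(q, path$perimeter, fluid$kinematic_viscosity))
  if (re_max > 4000)
    warning(sprintf("max station Reynolds number %.0f exceeds 4000; %s",
                    re_max, "laminar exchange closure is optimistic"))
  # air_density returns g/L = kg/m^3, so Q * rho is kg/s
  mdot_kg <- q * air_density(ambient$temperature, ambient$pressure)
  mdot_cp <- mdot_kg * fluid$specific_heat
  wall_t <- rep(body_t_c, nrow(path))
  wall_w <- rep(water_content(air_state(body_t_c, 1, ambient$pressure),
                              "mass_fraction"), nrow(path))
  st <- march_exchange(path$s, path$perimeter, path$dh, path$kappa,
                       wall_t, wall_w, q,
                       t0 = ambient$temperature,
                       w0 = water_content(ambient, "mass_fraction"),
                       mdot_cp = mdot_cp,
                       wall = wall, config = config, fluid = fluid)
  finish_result(path, st, q, "inspiration", wall_t, fluid$specific_heat,
                config)
}

#' Simulate expiratory heat and moisture recovery
#'
#' Air enters the choana at body temperature, saturated, and runs back to the
#' nostril.  The wall temperature profile is set from the paired inspiration:
#' either mirroring the local inspired-air temperature (the heat given to
#' inspired air cooled the wall by the same amount) or a uniform offset equal
#' to the inspiratory warming.
#'
#' @param x the same [airway()] used for the inspiration run.
#' @param q volumetric flow rate (m^3/s).
#' @param inspiration the paired inspiratory `exchange_result`.
#' @param body_t_c core temperature, degC.
#' @param wall,config,fluid as for [simulate_inspiration()].
#' @return `exchange_result` with the exit state at the nostril.
#' @export
simulate_expiration <- function(x, q, inspiration, body_t_c = 35,
                                wall = wall_properties(),
                                config = exchanger_config(),
                                fluid = air_properties()) {
  stopifnot(inherits(inspiration, "exchange_result"))
  if (inspiration$phase != "inspiration")
    stop("`inspiration` must be an inspiratory exchange_result")
  path <- prepare_path(x, config)
  if (nrow(path) != nrow(inspiration$profile) ||
      max(abs(path$s - inspiration$profile$s)) > 1e-9)
    stop("geometry does not match the inspiration result")
  wall_t <- switch(config$expiration_wall,
                   mirror = inspiration$profile$T_air,
                   uniform_offset = {
    warming <- inspiration$exit_temperature - inspiration$profile$T_air[1L]
    rep(body_t_c - warming, nrow(path))
  })
  pressure <- 101325
  wall_w <- vapply(wall_t, function(tw)
    water_content(air_state(tw, 1, pressure), "mass_fraction"), numeric(1L))
  mdot_kg <- q * air_density(body_t_c, pressure)
  mdot_cp <- mdot_kg * fluid$specific_heat
  rev_i <- rev(seq_len(nrow(path)))
  s_rev <- max(path$s) - path$s[rev_i]
  st <- march_exchange(s_rev, path$perimeter[rev_i], path$dh[rev_i],
                       path$kappa[rev_i], wall_t[rev_i], wall_w[rev_i], q,
                       t0 = body_t_c,
                       w0 = water_content(air_state(body_t_c, 1, pressure),
                                          "mass_fraction"),
                       mdot_cp = mdot_cp,
                       wall = wall, config = config, fluid = fluid)
  # restore nostril-to-choana order
  st$t_air <- rev(st$t_air)
  st$w_air <- rev(st$w_air)
  finish_result(path, st, q, "expiration", wall_t, fluid$specific_heat,
                config)
}

#' Sweep airway variants and flow rates through the exchanger
#'
#' Runs paired inspiration/expiration simulations for the soft-tissue airway
#' and optionally the bony-bounded airway at the profile's low and high flow
#' rates, plus the shortened ("basic") and straightened variants at the low
#' rate, then feeds the expired-air temperatures into the caloric budget.
#'
#' @param st_airway soft-tissue corrected [airway()].
#' @param profile an [animal_profile()].
#' @param bb_airway optional bony-bounded [airway()].
#' @param flows subset of `c("low", "high")`.
#' @param ambient ambient [air_state()].
#' @param wall,config,fluid exchanger settings.
#' @return data.frame ranked by total energy recovered (greatest savings
#'   first): model, flow, flow_lmin, choana_T (inspiratory exit), expired_T,
#'   budget columns and savings fractions.
#' @export
variant_sweep <- function(st_airway, profile, bb_airway = NULL,
                          flows = c("low", "high"),
                          ambient = air_state(15, 0.5),
                          wall = wall_properties(),
                          config = exchanger_config(),
                          fluid = air_properties()) {
  stopifnot(inherits(profile, "animal_profile"))
  flows <- match.arg(flows, c("low", "high"), several.ok = TRUE)
  body_t <- profile$body_temperature_c
  q_of <- function(flow) switch(flow, low = profile$flow_low_lmin,
                                high = profile$flow_high_lmin) / 60000
  cases <- list()
  for (fl in flows) {
    cases[[paste0("ST_", fl)]] <- list(x = st_airway, flow = fl)
    if (!is.null(bb_airway))
      cases[[paste0("BB_", fl)]] <- list(x = bb_airway, flow = fl)
  }
  # hypothetical variants only run under the conservative low-flow condition
  if ("low" %in% flows) {
    cases[["basic_low"]] <- list(x = make_basic(st_airway), flow = "low")
    cases[["straightened_low"]] <- list(x = make_straightened(st_airway),
                                        flow = "low")
  }
  rows <- lapply(names(cases), function(nm) {
    cs <- cases[[nm]]
    q <- q_of(cs$flow)
    insp <- suppressWarnings(simulate_inspiration(cs$x, q, ambient, body_t,
                                                  wall, config, fluid))
    ex <- suppressWarnings(simulate_expiration(cs$x, q, insp, body_t, wall,
                                               config, fluid))
    t_exp <- max(ex$exit_temperature, ambient$temperature)
    budget <- expiration_savings(breath_scenario(
      ambient = ambient, body_temperature_c = body_t,
      expired_temperature_c = t_exp,
      tidal_volume_l = profile$tidal_volume_ml / 1000))
    data.frame(model = sub("_(low|high)$", "", nm), flow = cs$flow,
               flow_lmin = q * 60000,
               choana_T = insp$exit_temperature,
               expired_T = ex$exit_temperature,
               sensible_saved = budget$sensible_saved,
               latent_saved = budget$latent_saved,
               total_saved = budget$total_saved,
               heat_savings_fraction = budget$heat_savings_fraction,
               water_savings_fraction = budget$water_savings_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$total_saved), , drop = FALSE]
  rownames(out) <- NULL
  out
}
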