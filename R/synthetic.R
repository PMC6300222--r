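# Parametric, seedable airway generator.  Emulates CT-derived centerline
# models: a long coiled vestibule, an expanded cavum nasi proprium (CNP), a
# nasopharyngeal duct and an artificial tracheal extension.

#' Specify a synthetic airway
#'
#' Cross sections are flattened ducts parameterised by their hydraulic
#' diameter ("caliber", the mucosal gap) and a perimeter elongation factor
#' `f >= 1`: `P = f * pi * d` and `A = f * pi * d^2 / 4`, so `Dh = d` for any
#' `f` (a circle is `f = 1`).  The vestibule is a helical coil of `n_loops`
#' turns whose diameter is `loop_plane_extent_mm`; its axial rise is derived
#' from the requested arc length, so the requested length is met exactly.
#'
#' @param vestibule_length_mm,vestibule_caliber_mm vestibule arc length and
#'   mean caliber (mm).
#' @param n_loops number of coil turns (0 gives a straight tube).
#' @param loop_plane_extent_mm bounding diameter of the coil (mm).
#' @param cnp_length_mm,cnp_caliber_mm cavum nasi proprium dimensions (mm).
#' @param duct_length_mm,duct_caliber_mm nasopharyngeal duct dimensions (mm).
#' @param trachea_length_mm,trachea_caliber_mm tracheal extension dimensions
#'   (mm).
#' @param vestibule_perimeter_factor,cnp_perimeter_factor,
#'   duct_perimeter_factor,trachea_perimeter_factor cross-section elongation
#'   factors (>= 1).
#' @param caliber_noise_cv coefficient of variation of multiplicative
#'   lognormal caliber noise, in `[0, 0.5)`; 0 disables noise.
#' @param seed integer RNG seed recorded in the spec.
#' @param spacing_mm station spacing along the centerline (mm).
#' @param name airway name.
#' @return an object of class `airway_spec`.
#' @export
airway_spec <- function(vestibule_length_mm = 200,
                        vestibule_caliber_mm = 10,
                        n_loops = 0,
                        loop_plane_extent_mm = 50,
                        cnp_length_mm = 100,
                        cnp_caliber_mm = 25,
                        duct_length_mm = 80,
                        duct_caliber_mm = 15,
                        trachea_length_mm = 150,
                        trachea_caliber_mm = 15,
                        vestibule_perimeter_factor = 1,
                        cnp_perimeter_factor = 1,
                        duct_perimeter_factor = 1,
                        trachea_perimeter_factor = 1,
                        caliber_noise_cv = 0.05,
                        seed = 1L,
                        spacing_mm = 1,
                        name = "synthetic") {
  spec <- as.list(environment())
  lens <- c(vestibule_length_mm, cnp_length_mm, duct_length_mm,
            trachea_length_mm)
  cals <- c(vestibule_caliber_mm, cnp_caliber_mm, duct_caliber_mm,
            trachea_caliber_mm)
  if (any(lens <= 0) || any(cals <= 0) || spacing_mm <= 0)
    stop("lengths, calibers and spacing must be positive")
  if (n_loops < 0) stop("n_loops must be >= 0")
  if (loop_plane_extent_mm <= 0) stop("loop_plane_extent_mm must be positive")
  if (caliber_noise_cv < 0 || caliber_noise_cv >= 0.5)
    stop("caliber_noise_cv must be in [0, 0.5)")
  fs <- c(vestibule_perimeter_factor, cnp_perimeter_factor,
          duct_perimeter_factor, trachea_perimeter_factor)
  if (any(fs < 1)) stop("perimeter factors must be >= 1")
  class(spec) <- "airway_spec"
  spec
}

# straight-segment stations appended after `origin` along unit vector `u`
straight_block <- function(s0, origin, u, length_m, spacing_m, region) {
  nseg <- max(1L, round(length_m / spacing_m))
  s_loc <- seq(length_m / nseg, length_m, length.out = nseg)
  data.frame(s = s0 + s_loc,
             x = origin[1L] + s_loc * u[1L],
             y = origin[2L] + s_loc * u[2L],
             z = origin[3L] + s_loc * u[3L],
             region = region)
}

#' Generate a synthetic centerline airway
#'
#' Deterministic for a given `spec$seed` (the global RNG state is saved and
#' restored).  The vestibule coil achieves the requested arc length exactly;
#' regions are appended in anatomical order along the coil axis.
#'
#' @param spec an [airway_spec()].
#' @return an [airway()]; the spec is attached as attribute `"spec"`.
#' @export
generate_airway <- function(spec) {
  stopifnot(inherits(spec, "airway_spec"))
  sp_m <- spec$spacing_mm / 1000
  lv <- spec$vestibule_length_mm / 1000
  r <- spec$loop_plane_extent_mm / 2000
  n <- spec$n_loops

  if (n > 0) {
    per_turn <- lv / (2 * pi * n)       # = sqrt(r^2 + c^2)
    if (per_turn <= r)
      stop("infeasible coil: requested vestibule length ", spec$vestibule_length_mm,
           " mm cannot be reached with ", n, " loop(s) of extent ",
           spec$loop_plane_extent_mm, " mm (needs length > 2*pi*R*n)")
    cpitch <- sqrt(per_turn^2 - r^2)
    nseg <- max(2L, round(lv / sp_m))
    s_v <- seq(0, lv, length.out = nseg + 1L)
    theta <- s_v / per_turn
    vest <- data.frame(s = s_v,
                       x = r * cos(theta) - r,
                       y = r * sin(theta),
                       z = cpitch * theta,
                       region = "vestibule")
    end <- c(0, 0, cpitch * 2 * pi * n)
    axis <- c(0, 0, 1)
  } else {
    nseg <- max(2L, round(lv / sp_m))
    s_v <- seq(0, lv, length.out = nseg + 1L)
    vest <- data.frame(s = s_v, x = 0, y = 0, z = s_v, region = "vestibule")
    end <- c(0, 0, lv)
    axis <- c(0, 0, 1)
  }

  s0 <- lv
  blocks <- list(vest)
  segs <- list(c("cnp", spec$cnp_length_mm),
               c("nasopharyngeal_duct", spec$duct_length_mm),
               c("tracheal_extension", spec$trachea_length_mm))
  for (sg in segs) {
    lb <- as.numeric(sg[2L]) / 1000
    blk <- straight_block(s0, end, axis, lb, sp_m, sg[1L])
    nb <- nrow(blk)
    end <- as.numeric(blk[nb, c("x", "y", "z")])
    s0 <- blk$s[nb]
    blocks <- c(blocks, list(blk))
  }
  st <- do.call(rbind, blocks)

  cal_mm <- c(vestibule = spec$vestibule_caliber_mm,
              cnp = spec$cnp_caliber_mm,
              nasopharyngeal_duct = spec$duct_caliber_mm,
              tracheal_extension = spec$trachea_caliber_mm)
  fac <- c(vestibule = spec$vestibule_perimeter_factor,
           cnp = spec$cnp_perimeter_factor,
           nasopharyngeal_duct = spec$duct_perimeter_factor,
           tracheal_extension = spec$trachea_perimeter_factor)
  d <- cal_mm[st$region] / 1000
  f <- fac[st$region]

  if (spec$caliber_noise_cv > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
    sdlog <- sqrt(log(1 + spec$caliber_noise_cv^2))
    d <- d * stats::rlnorm(length(d), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }

  st$area <- f * pi * d^2 / 4
  st$perimeter <- f * pi * d
  out <- airway(st[, c("s", "area", "perimeter", "x", "y", "z", "region")],
                name = spec$name, variant = "custom")
  attr(out, "spec") <- spec
  out
}

# perimeter (m) at which a target Reynolds number yields flow Q (m^3/s)
perimeter_for_flow <- function(q_m3s, re = 2000, nu = 1.412e-5) 4 * q_m3s / (re * nu)

#' Preset airway specifications
#'
#' Named specs emulating the study geometries.  The two ankylosaur vestibules
#' follow the published lengths and mean calibers (Panoplosaurus: 440 mm,
#' BB caliber 15.8 mm; Euoplocephalus: 808.74 mm, BB caliber 22.9 mm; ST
#' variants compressed to 10 mm).  Coil extents are solved so the straight
#' nostril-to-CNP distance matches the published shortened ("basic")
#' vestibules (200 and 162.14 mm), ST perimeter factors so the vestibule
#' perimeter reproduces the published low (reversed-Reynolds) flow rates
#' (37 and 48 L/min at Re = 2000), and BB factors so vestibule volume matches
#' the published bony-bounded casts.  Specimen presets are noise-free; the
#' caliber-noise default only applies to custom robustness fixtures.
#'
#' @param seed seed stored in each spec.
#' @return named list of [airway_spec()] objects: `panoplosaurus_bb`,
#'   `panoplosaurus_st`, `euoplocephalus_bb`, `euoplocephalus_st`,
#'   `pigeon_like`, `micro_duct`.
#' @export
airway_presets <- function(seed = 1L) {
  # Panoplosaurus: arc 440 mm, straight-line 200 mm, 2 loops
  ext_pano <- 2 * sqrt(440^2 - 200^2) / (4 * pi)
  # Euoplocephalus: arc 808.74 mm, straight-line 162.14 mm, 3 loops
  ext_euo <- 2 * sqrt(808.74^2 - 162.14^2) / (6 * pi)
  f_st_pano <- 1000 * perimeter_for_flow(37 / 60000) / (pi * 10)
  f_st_euo <- 1000 * perimeter_for_flow(48 / 60000) / (pi * 10)
  f_bb_pano <- 4 * (157134 / 440) / (pi * 15.8^2)   # published cast volume
  f_bb_euo <- 4 * (436740 / 808.74) / (pi * 22.9^2)
  pano <- list(cnp_length_mm = 150, cnp_caliber_mm = 25,
               cnp_perimeter_factor = 2,
               duct_length_mm = 100, duct_caliber_mm = 15,
               duct_perimeter_factor = 2.5,
               trachea_length_mm = 250, trachea_caliber_mm = 18)
  euo <- list(cnp_length_mm = 200, cnp_caliber_mm = 30,
              cnp_perimeter_factor = 2,
              duct_length_mm = 120, duct_caliber_mm = 18,
              duct_perimeter_factor = 2.5,
              trachea_length_mm = 300, trachea_caliber_mm = 20)
  mk <- function(base, ...) do.call(airway_spec,
                                    c(list(...), base,
                                      list(caliber_noise_cv = 0, seed = seed)))
  list(
    panoplosaurus_bb = mk(pano, name = "panoplosaurus_bb",
                          vestibule_length_mm = 440,
                          vestibule_caliber_mm = 15.8, n_loops = 2,
                          loop_plane_extent_mm = ext_pano,
                          vestibule_perimeter_factor = f_bb_pano),
    panoplosaurus_st = mk(pano, name = "panoplosaurus_st",
                          vestibule_length_mm = 440,
                          vestibule_caliber_mm = 10, n_loops = 2,
                          loop_plane_extent_mm = ext_pano,
                          vestibule_perimeter_factor = f_st_pano),
    euoplocephalus_bb = mk(euo, name = "euoplocephalus_bb",
                           vestibule_length_mm = 808.74,
                           vestibule_caliber_mm = 22.9, n_loops = 3,
                           loop_plane_extent_mm = ext_euo,
                           vestibule_perimeter_factor = f_bb_euo),
    euoplocephalus_st = mk(euo, name = "euoplocephalus_st",
                           vestibule_length_mm = 808.74,
                           vestibule_caliber_mm = 10, n_loops = 3,
                           loop_plane_extent_mm = ext_euo,
                           vestibule_perimeter_factor = f_st_euo),
    pigeon_like = airway_spec(name = "pigeon_like",
                              vestibule_length_mm = 30,
                              vestibule_caliber_mm = 2, n_loops = 1,
                              loop_plane_extent_mm = 8,
                              cnp_length_mm = 15, cnp_caliber_mm = 4,
                              duct_length_mm = 10, duct_caliber_mm = 2,
                              trachea_length_mm = 30, trachea_caliber_mm = 3,
                              vestibule_perimeter_factor = 1.5,
                              cnp_perimeter_factor = 1.5,
                              duct_perimeter_factor = 1.5,
                              caliber_noise_cv = 0, seed = seed),
    micro_duct = airway_spec(name = "micro_duct",
                             vestibule_length_mm = 3,
                             vestibule_caliber_mm = 2, n_loops = 0,
                             loop_plane_extent_mm = 2,
                             cnp_length_mm = 2, cnp_caliber_mm = 3,
                             duct_length_mm = 2, duct_caliber_mm = 2,
                             trachea_length_mm = 2, trachea_caliber_mm = 2,
                             caliber_noise_cv = 0, seed = seed)
  )
}
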