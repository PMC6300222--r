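# Fixtures are built in code, independently of the package generator where
# they serve as oracles.

# straight multi-region tube along +z; circular cross sections unless a
# perimeter factor is given
make_tube <- function(lengths_mm = c(vestibule = 60, cnp = 20,
                                     nasopharyngeal_duct = 20),
                      caliber_mm = 10, f = 1, spacing_mm = 1,
                      name = "tube") {
  s <- 0
  rows <- list()
  z0 <- 0
  for (i in seq_along(lengths_mm)) {
    l <- lengths_mm[i] / 1000
    nseg <- max(1L, round(l / (spacing_mm / 1000)))
    s_loc <- if (i == 1L) seq(0, l, length.out = nseg + 1L)
             else seq(l / nseg, l, length.out = nseg)
    rows[[i]] <- data.frame(s = s + s_loc, x = 0, y = 0, z = z0 + s_loc,
                            region = names(lengths_mm)[i])
    s <- s + l
    z0 <- z0 + l
  }
  st <- do.call(rbind, rows)
  d <- caliber_mm / 1000
  st$area <- f * pi * d^2 / 4
  st$perimeter <- f * pi * d
  airway(st[, c("s", "area", "perimeter", "x", "y", "z", "region")],
         name = name)
}

# helix polyline with s = cumulative chord length (a valid airway), plus the
# closed-form arc length of the underlying curve as an independent oracle
make_helix_fixture <- function(radius_mm = 30, pitch_mm = 40, n_turns = 2,
                               n_pts = 600, caliber_mm = 8) {
  r <- radius_mm / 1000
  cpitch <- pitch_mm / 1000 / (2 * pi)
  theta <- seq(0, 2 * pi * n_turns, length.out = n_pts)
  pts <- cbind(x = r * cos(theta) - r, y = r * sin(theta),
               z = cpitch * theta)
  chord <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                           pts[-n_pts, , drop = FALSE])^2))
  s <- c(0, cumsum(chord))
  d <- caliber_mm / 1000
  st <- data.frame(s = s, area = pi * d^2 / 4, perimeter = pi * d,
                   x = as.numeric(pts[, 1L]), y = as.numeric(pts[, 2L]),
                   z = as.numeric(pts[, 3L]), region = "vestibule")
  # small downstream block so the airway has anatomical structure
  tail_n <- 5L
  ds <- s[n_pts] / n_pts
  end <- unname(pts[n_pts, ])
  tail <- data.frame(s = s[n_pts] + ds * seq_len(tail_n),
                     area = pi * d^2 / 4, perimeter = pi * d,
                     x = end[1L], y = end[2L],
                     z = end[3L] + ds * seq_len(tail_n),
                     region = "cnp")
  list(airway = airway(rbind(st, tail), name = "helix"),
       arc_mm = 1000 * 2 * pi * n_turns * sqrt(r^2 + cpitch^2),
       curvature = r / (r^2 + cpitch^2))
}

# closed-form exit temperature for a uniform straight duct with constant wall
# temperature and constant transfer coefficient:
# T(L) = Tw - (Tw - T0) * exp(-h P L / (mdot cp))
oracle_exit_temp <- function(tube, q, t0, tw, wall, fluid) {
  p <- tube$perimeter[1L]
  dh <- hydraulic_diameter(tube$area[1L], p)
  h_conv <- 3.66 * fluid$thermal_conductivity / dh
  h_eff <- 1 / (1 / h_conv + wall$thickness_m / wall$conductivity_w_mk)
  l <- max(main_path(tube)$s)
  mdot_cp <- q * air_density(t0) * fluid$specific_heat
  tw - (tw - t0) * exp(-h_eff * p * l / mdot_cp)
}

# generated preset airways shared across tests
fx <- new.env()
fx$presets <- airway_presets()
fx$pano_st <- generate_airway(fx$presets$panoplosaurus_st)
fx$pano_bb <- generate_airway(fx$presets$panoplosaurus_bb)
fx$euo_st <- generate_airway(fx$presets$euoplocephalus_st)
fx$euo_bb <- generate_airway(fx$presets$euoplocephalus_bb)

extdata <- function(name) {
  path <- system.file("extdata", name, package = "vestibulum")
  if (!nzchar(path)) path <- file.path("..", "..", "inst", "extdata", name)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
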