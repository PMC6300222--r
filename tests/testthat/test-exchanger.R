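plain_config <- exchanger_config(alpha = 0, moisture = FALSE,
                                 use_film_properties = FALSE)

test_that("the surrogate matches the closed-form exponential on a tube", {
  tube <- make_tube(lengths_mm = c(vestibule = 300, cnp = 100,
                                   nasopharyngeal_duct = 100),
                    caliber_mm = 8)
  q <- 10 / 60000
  res <- simulate_inspiration(tube, q, ambient = air_state(15, 0),
                              config = plain_config)
  expected <- oracle_exit_temp(tube, q, 15, 35, wall_properties(),
                               air_properties())
  expect_equal(res$exit_temperature, expected, tolerance = 1e-6)
})

test_that("a long enough duct equilibrates with the wall", {
  long <- make_tube(lengths_mm = c(vestibule = 3000, cnp = 500,
                                   nasopharyngeal_duct = 500),
                    caliber_mm = 6, spacing_mm = 2)
  res <- simulate_inspiration(long, 5 / 60000)
  expect_equal(res$exit_temperature, 35, tolerance = 1e-4)
  expect_equal(res$exit_water, water_content(air_state(35, 1)),
               tolerance = 1e-3)
})

test_that("heat gained by the air equals the integrated wall flux", {
  res <- simulate_inspiration(fx$euo_st, 48 / 60000,
                              config = exchanger_config(moisture = FALSE))
  prof <- res$profile
  wall <- wall_properties(); fluid <- air_properties()
  q <- res$Q
  mdot_cp <- q * air_density(15) * fluid$specific_heat
  path <- main_path(fx$euo_st)
  dh <- hydraulic_diameter(path$area, path$perimeter)
  kappa <- centerline_curvature(path)
  flux <- vapply(seq_len(nrow(prof)), function(i) {
    h <- vestibulum:::h_effective(path$perimeter[i], dh[i], kappa[i], q,
                                  prof$T_air[i], prof$wall_T[i], wall,
                                  exchanger_config(moisture = FALSE), fluid)
    h * path$perimeter[i] * (prof$wall_T[i] - prof$T_air[i])
  }, numeric(1L))
  gained <- mdot_cp * (res$exit_temperature - prof$T_air[1L])
  integral <- sum(diff(prof$s) * (flux[-1L] + flux[-length(flux)]) / 2)
  expect_equal(gained, integral, tolerance = 1e-3)
})

test_that("exit temperature rises with airway length and falls with flow", {
  exits_l <- sapply(c(100, 200, 400, 800), function(l)
    simulate_inspiration(make_tube(lengths_mm = c(vestibule = l, cnp = 50,
                                                  nasopharyngeal_duct = 50)),
                         20 / 60000)$exit_temperature)
  expect_true(all(diff(exits_l) > 0))
  exits_q <- sapply(c(10, 20, 40, 80) / 60000, function(q)
    suppressWarnings(simulate_inspiration(fx$pano_st, q))$exit_temperature)
  expect_true(all(diff(exits_q) < 0))
})

test_that("without curvature enhancement, coiling is irrelevant", {
  cfg <- exchanger_config(alpha = 0)
  straight <- make_straightened(fx$pano_st)
  r1 <- simulate_inspiration(fx$pano_st, 37 / 60000, config = cfg)
  r2 <- simulate_inspiration(straight, 37 / 60000, config = cfg)
  expect_equal(r1$exit_temperature, r2$exit_temperature, tolerance = 1e-10)
  expect_equal(r1$profile$T_air, r2$profile$T_air, tolerance = 1e-10)
  # with the enhancement on, the coiled vestibule transfers more heat
  expect_gt(simulate_inspiration(fx$pano_st, 37 / 60000)$exit_temperature,
            simulate_inspiration(straight, 37 / 60000)$exit_temperature)
})

test_that("halving the station spacing barely moves the exit state", {
  sp <- airway_presets()$euoplocephalus_st
  sp_fine <- sp; sp_fine$spacing_mm <- 0.5
  coarse <- simulate_inspiration(generate_airway(sp), 48 / 60000)
  fine <- simulate_inspiration(generate_airway(sp_fine), 48 / 60000)
  expect_lt(abs(coarse$exit_temperature - fine$exit_temperature), 0.1)
})

test_that("region heating shares are a partition of unity", {
  res <- simulate_inspiration(fx$euo_st, 48 / 60000)
  expect_equal(sum(res$region_heating_share), 1, tolerance = 1e-6)
  res2 <- simulate_inspiration(fx$euo_st, 48 / 60000,
                               config = exchanger_config(
                                 share_basis = "enthalpy"))
  expect_equal(sum(res2$region_heating_share), 1, tolerance = 1e-6)
})

test_that("low-flow soft-tissue exchange approaches complete conditioning", {
  res <- simulate_inspiration(fx$euo_st, 48 / 60000)
  expect_lt(35 - res$exit_temperature, 1)
  expect_gte(res$region_heating_share[["vestibule"]], 0.9)
})

test_that("turbulent-range flows trigger a closure warning", {
  expect_warning(simulate_inspiration(fx$euo_st, 110 / 60000), "4000")
})

test_that("expiration recovers heat against the cooled wall profile", {
  q <- 37 / 60000
  insp <- simulate_inspiration(fx$pano_st, q)
  ex <- simulate_expiration(fx$pano_st, q, insp)
  expect_gte(ex$exit_temperature, 15)
  expect_lte(ex$exit_temperature, 35)
  # walls uniformly at body temperature return no heat: simulate with air
  # already at body conditions so the mirrored wall profile is flat at 35
  warm <- simulate_inspiration(fx$pano_st, q, ambient = air_state(35, 1))
  ex_warm <- simulate_expiration(fx$pano_st, q, warm)
  expect_equal(ex_warm$exit_temperature, 35, tolerance = 1e-9)
  # geometry mismatch is rejected
  expect_error(simulate_expiration(fx$euo_st, q, insp), "match")
  # the shortened vestibule loses much more heat on expiration
  basic <- make_basic(fx$pano_st)
  insp_b <- simulate_inspiration(basic, q)
  ex_b <- simulate_expiration(basic, q, insp_b)
  expect_gt(ex_b$exit_temperature - ex$exit_temperature, 4)
  # the uniform-offset wall option also recovers heat
  cfg_u <- exchanger_config(expiration_wall = "uniform_offset")
  insp_u <- simulate_inspiration(fx$pano_st, q, config = cfg_u)
  ex_u <- simulate_expiration(fx$pano_st, q, insp_u, config = cfg_u)
  expect_lt(ex_u$exit_temperature, 35)
  expect_gte(ex_u$exit_temperature, 15)
})

test_that("variant sweeps rank geometries and flows as published", {
  pr <- default_profiles()
  sw <- variant_sweep(fx$pano_st, pr$panoplosaurus, bb_airway = fx$pano_bb)
  expect_identical(nrow(sw), 6L)
  key <- paste(sw$model, sw$flow, sep = "_")
  saved <- stats::setNames(sw$total_saved, key)
  # soft-tissue beats straightened beats shortened at the low flow rate
  expect_gt(saved[["ST_low"]], saved[["straightened_low"]])
  expect_gt(saved[["straightened_low"]], saved[["basic_low"]])
  # the natural geometry at low flow recovers the most; the shortened
  # vestibule the least
  expect_identical(key[1L], "ST_low")
  expect_identical(key[length(key)], "basic_low")
  # lower flow always beats higher flow on the same geometry
  expect_gt(saved[["ST_low"]], saved[["ST_high"]])
  expect_gt(saved[["BB_low"]], saved[["BB_high"]])
  expect_true(all(sw$heat_savings_fraction >= 0 &
                    sw$heat_savings_fraction <= 1))
  expect_true(all(sw$water_savings_fraction >= 0 &
                    sw$water_savings_fraction <= 1))
  # a single variant at a single flow gives a single row
  one <- variant_sweep(fx$pano_st, pr$panoplosaurus, flows = "high")
  expect_identical(nrow(one), 1L)
  expect_identical(one$model, "ST")
})
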