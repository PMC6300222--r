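test_that("hydraulic diameter matches closed forms for canonical sections", {
  r <- 0.007
  expect_equal(hydraulic_diameter(pi * r^2, 2 * pi * r), 2 * r)
  a <- 0.004
  expect_equal(hydraulic_diameter(a^2, 4 * a), a)
  expect_equal(hydraulic_diameter(1.0e-4, 0.05), 8.0e-3)
  expect_error(hydraulic_diameter(-1e-4, 0.05), "invalid geometry")
  expect_error(hydraulic_diameter(1e-4, 0), "invalid geometry")
})

test_that("airway validation rejects broken geometry with row locations", {
  tube <- make_tube()
  bad <- tube; bad$area[5L] <- -1
  expect_error(airway(as.data.frame(bad)), "row 5")
  bad <- tube; bad$s[10L] <- bad$s[8L]
  expect_error(airway(as.data.frame(bad)), "strictly increasing")
  bad <- tube; bad$x[20L] <- bad$x[20L] + 0.05   # chord > arc
  expect_error(airway(as.data.frame(bad)), "chord exceeds arc")
  bad <- tube; bad$perimeter[3L] <- sqrt(pi * bad$area[3L])  # < circle
  expect_error(airway(as.data.frame(bad)), "isoperimetric")
  bad <- as.data.frame(tube)
  bad$region[bad$region == "vestibule"] <- "cnp"
  bad$region[bad$region == "nasopharyngeal_duct"] <- "vestibule"
  expect_error(airway(bad), "anatomical order")
})

test_that("mean caliber is the arc-weighted mean hydraulic diameter", {
  tube <- make_tube(caliber_mm = 10)
  expect_equal(mean_caliber(tube, "vestibule"), 10)
  # two equal halves of caliber 8 and 12 average to 10
  half <- make_tube(lengths_mm = c(vestibule = 200), caliber_mm = 8)
  d2 <- 12 / 1000
  half$area[half$s >= 0.1] <- pi * d2^2 / 4
  half$perimeter[half$s >= 0.1] <- pi * d2
  expect_equal(mean_caliber(half, "vestibule"), 10, tolerance = 0.01)
  # generator round-trip at the bony-bounded target caliber
  expect_equal(mean_caliber(fx$pano_bb, "vestibule"), 15.8, tolerance = 0.1)
  expect_error(mean_caliber(tube, "olfactory_recess"), "absent")
})

test_that("region metrics recover length, volume and tortuosity", {
  tube <- make_tube(lengths_mm = c(vestibule = 200, cnp = 50))
  m <- region_metrics(tube, "vestibule")
  expect_equal(m$length_mm, 200)
  expect_equal(m$tortuosity, 1.0)
  expect_equal(m$volume_mm3, (pi * 10^2 / 4) * 200, tolerance = 1e-6)
  hx <- make_helix_fixture()
  mh <- region_metrics(hx$airway, "vestibule")
  expect_equal(mh$length_mm, hx$arc_mm, tolerance = 0.005)
  expect_gt(mh$tortuosity, 1)
  # published vestibule length reproduced by the preset geometry
  expect_equal(region_metrics(fx$euo_st, "vestibule")$length_mm, 808.74,
               tolerance = 0.005 * 808.74)
  expect_error(region_metrics(tube, "tracheal_extension"), "absent")
})

test_that("discrete curvature matches the analytic helix curvature", {
  hx <- make_helix_fixture()
  vest <- hx$airway[hx$airway$region == "vestibule", ]
  kappa <- centerline_curvature(vest)
  interior <- kappa[10:(length(kappa) - 10L)]
  expect_equal(mean(interior), hx$curvature, tolerance = 0.01)
})

test_that("basic transform shortens the vestibule to the straight path", {
  b <- make_basic(fx$pano_st)
  expect_equal(attr(b, "length_reduction"), 0.55, tolerance = 0.01)
  expect_identical(attr(b, "variant"), "basic")
  be <- make_basic(fx$euo_st)
  expect_equal(attr(be, "length_reduction"), 0.80, tolerance = 0.01)
  # downstream regions untouched
  expect_equal(region_metrics(b, "cnp")$volume_mm3,
               region_metrics(fx$pano_st, "cnp")$volume_mm3)
  # never increases vestibule length
  expect_lte(region_metrics(b, "vestibule")$length_mm,
             region_metrics(fx$pano_st, "vestibule")$length_mm)
  # an already-straight vestibule is left unchanged
  straight <- generate_airway(airway_spec(vestibule_length_mm = 100,
                                          n_loops = 0, caliber_noise_cv = 0))
  b0 <- make_basic(straight)
  expect_equal(attr(b0, "length_reduction"), 0, tolerance = 1e-9)
  expect_equal(region_metrics(b0, "vestibule")$length_mm,
               region_metrics(straight, "vestibule")$length_mm)
})

test_that("straightening preserves arc length, sections and connectivity", {
  st <- make_straightened(fx$euo_st)
  expect_identical(attr(st, "variant"), "straightened")
  expect_equal(region_metrics(st, "vestibule")$length_mm,
               region_metrics(fx$euo_st, "vestibule")$length_mm)
  expect_equal(region_metrics(st, "vestibule")$tortuosity, 1.0,
               tolerance = 1e-9)
  vest_old <- fx$euo_st[fx$euo_st$region == "vestibule", ]
  vest_new <- st[st$region == "vestibule", ]
  expect_equal(hydraulic_diameter(vest_new$area, vest_new$perimeter),
               hydraulic_diameter(vest_old$area, vest_old$perimeter))
  expect_equal(region_metrics(st, "vestibule")$volume_mm3,
               region_metrics(fx$euo_st, "vestibule")$volume_mm3)
  # curvature removed
  expect_gt(total_curvature(fx$euo_st), 1)
  expect_lt(total_curvature(st), 1e-6)
  expect_silent(validate_airway(st))
})

test_that("soft-tissue correction rescales sections shape-preservingly", {
  st <- soft_tissue_correct(fx$euo_bb, 10)
  expect_equal(mean_caliber(st, "vestibule"), 10, tolerance = 0.05)
  expect_identical(attr(st, "variant"), "ST")
  k <- attr(st, "caliber_scale")
  expect_equal(k, 10 / 22.9, tolerance = 1e-6)
  expect_equal(region_metrics(st, "vestibule")$volume_mm3,
               k^2 * region_metrics(fx$euo_bb, "vestibule")$volume_mm3)
  # identity when the target equals the current caliber
  same <- soft_tissue_correct(fx$euo_bb, mean_caliber(fx$euo_bb, "vestibule"))
  expect_equal(same$area, fx$euo_bb$area)
  # monotone: larger target -> larger volume
  v <- sapply(c(8, 10, 12, 15), function(tc)
    region_metrics(soft_tissue_correct(fx$euo_bb, tc), "vestibule")$volume_mm3)
  expect_true(all(diff(v) > 0))
  expect_error(soft_tissue_correct(fx$euo_bb, -2), "positive")
})
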