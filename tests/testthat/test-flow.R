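test_that("Reynolds number follows 4Q/(P nu)", {
  expect_equal(reynolds(0, 0.05), 0)
  # 37 L/min through the published vestibule perimeter sits at Re 2000
  expect_equal(reynolds(6.1667e-4, 0.08734, 1.412e-5), 2000, tolerance = 1e-3)
  expect_equal(reynolds(2 * 3e-4, 0.05), 2 * reynolds(3e-4, 0.05))
  expect_error(reynolds(1e-4, 0), "positive")
  expect_error(reynolds(-1e-4, 0.05), ">= 0")
})

test_that("Womersley number flags quasi-steady breathing", {
  expect_equal(womersley(0.01, 0), 0)
  wo <- womersley(0.010, 0.025, 1.412e-5)   # 1.5 breaths/min, 10 mm duct
  expect_equal(wo, 0.527, tolerance = 0.01)
  expect_identical(classify_flow(500, wo)$steadiness, "quasi_steady")
  expect_equal(womersley(0.02, 0.025), 2 * womersley(0.01, 0.025))
})

test_that("regime classification honours the published thresholds", {
  expect_identical(unlist(classify_flow(1999, 0.5), use.names = FALSE),
                   c("laminar", "quasi_steady"))
  expect_identical(unlist(classify_flow(4001, 11), use.names = FALSE),
                   c("turbulent", "unsteady"))
  expect_identical(unlist(classify_flow(3000, 5), use.names = FALSE),
                   c("transitional", "intermediate"))
  # boundaries: 2000 and 4000 belong to the transition zone, 1 and 10 to
  # intermediate steadiness
  expect_identical(classify_flow(2000, 1)$regime, "transitional")
  expect_identical(classify_flow(4000, 10)$regime, "transitional")
  expect_identical(classify_flow(2000, 1)$steadiness, "intermediate")
  expect_identical(classify_flow(100, 10)$steadiness, "intermediate")
  # exhaustive and mutually exclusive over a random grid
  set.seed(11)
  cls <- classify_flow(runif(200, 0, 8000), runif(200, 0, 20))
  expect_true(all(cls$regime %in% c("laminar", "transitional", "turbulent")))
  expect_true(all(cls$steadiness %in% c("quasi_steady", "intermediate",
                                        "unsteady")))
})

test_that("reversed-Reynolds flow is the narrowest-perimeter bound", {
  tube <- make_tube(caliber_mm = 10,
                    f = 0.08734 / (pi * 0.01))  # perimeter 87.34 mm
  q <- reversed_reynolds_flow(tube)
  expect_equal(as.numeric(q), 6.1667e-4, tolerance = 1e-4)
  expect_equal(as.numeric(q) * 60000, 37.0, tolerance = 0.05)
  # plugging the result back in recovers the target exactly at the
  # governing station
  path <- main_path(tube)
  i <- attr(q, "station")
  expect_equal(reynolds(as.numeric(q), path$perimeter[i]), 2000)
  # min rule: the smaller perimeter governs
  two <- make_tube(lengths_mm = c(vestibule = 50, cnp = 50), caliber_mm = 10)
  two$perimeter[two$region == "vestibule"] <- 0.05
  two$perimeter[two$region == "cnp"] <- 0.10
  expect_equal(as.numeric(reversed_reynolds_flow(two)),
               2000 * 0.05 * 1.412e-5 / 4)
  # monotone in the target and under perimeter dilation
  q1 <- as.numeric(reversed_reynolds_flow(tube, re_target = 1000))
  q2 <- as.numeric(reversed_reynolds_flow(tube, re_target = 2000))
  expect_lt(q1, q2)
  wider <- tube; wider$perimeter <- tube$perimeter * 1.2
  expect_gt(as.numeric(reversed_reynolds_flow(wider)), as.numeric(q))
})

test_that("preset airways reproduce the published low flow rates", {
  expect_equal(as.numeric(reversed_reynolds_flow(fx$pano_st)) * 60000, 37,
               tolerance = 0.1)
  expect_equal(as.numeric(reversed_reynolds_flow(fx$euo_st)) * 60000, 48,
               tolerance = 0.1)
})

test_that("duct resistance follows Hagen-Poiseuille and parallel rules", {
  expect_equal(resistance_serial(1.8e-5, 0.1, 0.005), 7333.86,
               tolerance = 1e-4)
  r0 <- resistance_serial(1.8e-5, 0.1, 0.004)
  expect_equal(resistance_serial(1.8e-5, 0.1, 0.002), 16 * r0)
  expect_equal(resistance_serial(1.8e-5, 0.2, 0.004), 2 * r0)
  expect_equal(resistance_parallel(r0), r0)
  expect_equal(resistance_parallel(rep(r0, 5)), r0 / 5)
  # fourteen half-caliber parallel channels roughly match one serial pipe
  r_half <- resistance_serial(1.8e-5, 0.1, 0.002)
  ratio <- resistance_parallel(rep(r_half, 14)) / r0
  expect_equal(ratio, 16 / 14, tolerance = 1e-9)
  mixed <- c(r0, 3 * r0, 10 * r0)
  expect_lte(resistance_parallel(mixed), min(mixed))
  expect_error(resistance_parallel(numeric(0)), "at least one")
  expect_error(resistance_serial(1.8e-5, 0.1, 0), "positive")
})

test_that("regime reports summarise the airway consistently", {
  rep_low <- regime_report(fx$pano_st, q = 37 / 60000, f = 1.5 / 60)
  expect_true(all(rep_low$stations$regime == "laminar" |
                    rep_low$stations$regime == "transitional"))
  # the narrow vestibule breathes quasi-steadily; even the widest chamber
  # stays far from the unsteady regime
  vest_wo <- rep_low$stations$Wo[rep_low$stations$region == "vestibule"]
  expect_true(all(vest_wo < 1))
  expect_lt(rep_low$summary$max_Wo, 10)
  expect_equal(rep_low$summary$reversed_reynolds_Q * 60000, 37,
               tolerance = 0.1)
  # olfactory recess and trachea are excluded from the scanned path
  expect_false(any(rep_low$stations$region %in%
                     c("olfactory_recess", "tracheal_extension")))
})
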