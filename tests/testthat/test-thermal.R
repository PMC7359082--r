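test_that("focal field matches the 70% widths and transmission derating", {
  f <- build_focal_field(2.1, transmission = 1, dims_70pct = c(8.4, 4.5),
                         grid_spacing = 0.2)
  expect_equal(f$peak_Pa, 2.1e6)
  expect_equal(max(f$p_Pa), 2.1e6)
  # 70%-of-peak contour width along each axis within one cell
  pk <- f$peak_index
  for (d in 1:2) {
    prof <- if (d == 1) f$p_Pa[, pk[2]] else f$p_Pa[pk[1], ]
    width <- sum(prof >= 0.7 * max(prof)) * 0.2
    expect_lt(abs(width - c(8.4, 4.5)[d]), 0.2 + 1e-9)
  }
  f2 <- build_focal_field(2.1, transmission = 0.473)
  expect_equal(f2$peak_Pa, 0.473 * 2.1e6)
  expect_error(build_focal_field(2.1, transmission = 0), "transmission")
  expect_error(build_focal_field(2.1, transmission = 1.2), "transmission")
})

test_that("heat deposition follows Q = alpha p^2 / (rho c)", {
  tis <- tissue_properties(density = 1000, sound_speed = 1540)
  f <- build_focal_field(1, transmission = 1, dims_70pct = c(4, 4),
                         grid_spacing = 0.5)
  Q <- heat_deposition(f, tis, f0 = 486e3)
  alpha <- 5 * 0.486  # Np/m at 486 kHz
  expect_equal(alpha, 2.43)
  expect_equal(max(Q), alpha * 1e12 / (1000 * 1540), tolerance = 1e-12)
  expect_equal(max(Q), 1.578e6, tolerance = 1e-3)
  zero <- f; zero$p_Pa[] <- 0
  expect_true(all(heat_deposition(zero, tis) == 0))
})

test_that("Pennes solver matches the adiabatic closed form exactly", {
  # k = 0, w = 0, uniform Q: delta T = Q * t_on_total / (rho c_p)
  tis <- tissue_properties(density = 1000, specific_heat = 3600,
                           thermal_conductivity = 0, perfusion_rate = 0)
  Q <- array(3.6e6, c(4, 4))
  res <- pennes_solve(Q, tis, heating_schedule = list(on = 0.010, period = 1,
                                                      total = 30),
                      timestep = 0.05)
  expect_equal(res$max_delta_T, 3.6e6 * 0.010 * 30 / 3.6e6, tolerance = 1e-3)
  # zero source stays at arterial temperature
  res0 <- pennes_solve(array(0, c(4, 4)), tis,
                       heating_schedule = list(on = 0.01, period = 1,
                                               total = 5))
  expect_equal(res0$max_delta_T, 0)
  expect_true(all(res0$T_final == tis$arterial_temp))
})

test_that("Pennes solver reaches the perfusion steady state", {
  # k = 0, w > 0, continuous heating: delta T_ss = Q / (w rho_b c_b)
  tis <- tissue_properties(thermal_conductivity = 0, perfusion_rate = 0.1)
  Q <- array(1e5, c(3, 3))
  tau <- tis$density * tis$specific_heat /
    (tis$perfusion_rate * tis$blood_density * tis$blood_specific_heat)
  res <- pennes_solve(Q, tis,
                      heating_schedule = list(on = 1, period = 1,
                                              total = ceiling(5 * tau)),
                      timestep = 0.02)
  ss <- 1e5 / (tis$perfusion_rate * tis$blood_density *
                 tis$blood_specific_heat)
  expect_equal(res$max_delta_T, ss, tolerance = 0.01)
})

test_that("unstable timesteps are rejected with the admissible bound", {
  tis <- tissue_properties()
  Q <- array(1e5, c(8, 8))
  expect_error(pennes_solve(Q, tis, list(on = 0.01, period = 1, total = 1),
                            timestep = 0.5, spacing = 0.2e-3), "stability|bound")
})

test_that("heating is monotone in transmission and converges under refinement", {
  tis <- tissue_properties()
  sch <- list(on = 0.010, period = 1, total = 10)
  dts <- vapply(c(0.5, 0.7, 0.9), function(tx) {
    f <- build_focal_field(2.1, tx, dims_70pct = c(4, 3), grid_spacing = 0.4)
    pennes_solve(heat_deposition(f, tis), tis, sch, timestep = 0.05,
                 spacing = 0.4e-3)$max_delta_T
  }, numeric(1))
  expect_true(all(diff(dts) > 0))

  # grid refinement: halving the spacing changes max delta T by < 2%
  ref <- vapply(c(0.4, 0.2), function(h) {
    f <- build_focal_field(2.1, 0.7, dims_70pct = c(4, 3), grid_spacing = h)
    pennes_solve(heat_deposition(f, tis), tis, sch, timestep = 0.01,
                 spacing = h * 1e-3)$max_delta_T
  }, numeric(1))
  expect_lt(abs(ref[2] - ref[1]) / ref[1], 0.02)
})

test_that("microbubble enhancement reproduces the printed range arithmetic", {
  expect_equal(mb_enhanced(0), 0)
  expect_equal(round(mb_enhanced(0.33), 2), 1.19)
  expect_equal(round(mb_enhanced(0.07), 2), 0.25)
  expect_equal(mb_enhanced(1, factor = 2), 2)
})

test_that("temperature range scales quadratically with transmission", {
  tis <- tissue_properties(thermal_conductivity = 0)
  sch <- list(on = 0.010, period = 1, total = 5)
  rng <- treatment_temperature_range(2.1, 0.485, 0.95, tis, sch,
                                     dims_70pct = c(4, 3),
                                     grid_spacing = 0.4, timestep = 0.05)
  expect_equal(unname(rng["hi"] / rng["lo"]), (0.95 / 0.485)^2,
               tolerance = 1e-6)
  eq <- treatment_temperature_range(2.1, 0.6, 0.6, tis, sch,
                                    dims_70pct = c(4, 3), grid_spacing = 0.4,
                                    timestep = 0.05)
  expect_equal(unname(eq["lo"]), unname(eq["hi"]))
  dbl <- treatment_temperature_range(4.2, 0.485, 0.95, tis, sch,
                                     dims_70pct = c(4, 3), grid_spacing = 0.4,
                                     timestep = 0.05)
  expect_equal(unname(dbl["lo"] / rng["lo"]), 4, tolerance = 1e-6)
  expect_error(treatment_temperature_range(2.1, 0.9, 0.5), "transmission_lo")
})
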