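test_that("ramp schedule matches endpoints, clamp and hold phase", {
  sch <- build_ramp_schedule()
  expect_equal(nrow(sch), 300)
  expect_equal(sch$pressure_MPa[1], 1.8)                  # pulse 0
  expect_equal(sch$pressure_MPa[101], 1.8 + 100 * 0.003)  # clamp at pulse 100
  expect_equal(sch$pressure_MPa[101], 2.1)
  expect_equal(sch$pressure_MPa[300], 2.1)                # pulse 299
  expect_equal(sch$phase[300], "HOLD")
  ramp <- sch$pressure_MPa[sch$phase == "RAMP"]
  expect_true(all(diff(ramp) >= 0))
  expect_true(all(diff(ramp) <= 0.003 + 1e-12))
  expect_true(all(sch$pressure_MPa >= 0 & sch$pressure_MPa <= 2.1))
  expect_error(build_ramp_schedule(p_start = 2.2), "p_start")
})

test_that("fixed schedule is constant and handles degenerate inputs", {
  sch <- build_fixed_schedule(2.0, 120, 1)
  expect_equal(nrow(sch), 120)
  expect_true(all(sch$pressure_MPa == 2.0))
  expect_true(all(sch$phase == "HOLD"))
  expect_true(all(build_fixed_schedule(0, 60, 1)$pressure_MPa == 0))
  expect_equal(nrow(build_fixed_schedule(2, 0, 1)), 0)
})

test_that("controller triggers on the 5-sigma rule and halves pressure", {
  # seeded baseline, then a +10 sd jump -> trigger at the jump pulse,
  # all later commanded pressures are half the trigger pressure
  set.seed(42)
  base <- rnorm(10)
  jump_val <- mean(base) + 10 * sd(base)
  sums <- c(base, rnorm(5), jump_val, rnorm(5))
  sched_p <- c(seq(1.8, by = 0.003, length.out = 15), 2.0,
               rep(2.05, 5))
  st <- controller_new()
  commanded <- numeric(length(sums))
  for (i in seq_along(sums)) {
    step <- controller_step(st, sums[i], sched_p[i], i - 1L)
    st <- step$state
    commanded[i] <- step$commanded_pressure
  }
  expect_equal(st$mode, "TRIGGERED")
  expect_equal(st$trigger_index, 15L)        # zero-based index of the jump
  expect_equal(st$trigger_pressure, 2.0)
  expect_equal(commanded[17:21], rep(1.0, 5))  # 50% drop after trigger
  expect_true(all(commanded <= sched_p))

  # constant band sums (sd = 0) never trigger under the strict inequality
  st2 <- controller_new()
  for (i in 0:29) st2 <- controller_step(st2, 1, 2.0, i)$state
  expect_equal(st2$mode, "MONITOR")

  expect_error(controller_step(controller_new(), 0, 1.8, 5), "out-of-order")
})

test_that("baseline MAD screen rescues detection after a baseline outlier", {
  set.seed(9)
  base <- rnorm(10, 100, 1)
  base[4] <- 500                      # signal disruption during baseline
  sums <- c(base, rnorm(10, 100, 1), 120)  # clear jump vs clean baseline
  run <- function(mad_flag) {
    st <- controller_new(baseline_outlier_mad = mad_flag)
    for (i in seq_along(sums)) {
      st <- controller_step(st, sums[i], 2.0, i - 1L)$state
    }
    st$mode
  }
  expect_equal(run(FALSE), "MONITOR")    # outlier-inflated sd masks the jump
  expect_equal(run(TRUE), "TRIGGERED")
})

test_that("closed-loop treatment triggers at the configured hard onset", {
  sch <- build_ramp_schedule()
  m <- emission_model(onset_pressure_sub = 1.9, onset_width = 0,
                      noise_sd = 0, second_harmonic_amp = 0,
                      ultraharmonic_amp = 0, seed = 3)
  res <- run_treatment(sch, emission_source(m, duration = 5e-4,
                                            sample_rate = 2.5e6))
  # first pulse with 1.8 + 0.003 i >= 1.9 is i = 34
  expect_true(res$triggered)
  expect_equal(res$trigger_index, 34L)
  expect_equal(res$trigger_pressure, 1.8 + 34 * 0.003)
  post <- res$applied_MPa[(res$trigger_index + 2):300]
  expect_true(all(post == 0.5 * res$trigger_pressure))  # absorbing
  expect_true(all(res$applied_MPa <= res$scheduled_MPa + 1e-12))
})

test_that("no-subharmonic and disabled-detector treatments run open loop", {
  sch <- build_ramp_schedule(total_duration = 60)
  m0 <- emission_model(subharmonic_amp = 0, second_harmonic_amp = 0,
                       ultraharmonic_amp = 0, noise_sd = 0, seed = 1)
  res <- run_treatment(sch, emission_source(m0, duration = 5e-4,
                                            sample_rate = 2.5e6))
  expect_false(res$triggered)
  expect_equal(res$applied_MPa, sch$pressure_MPa)

  m1 <- emission_model(onset_pressure_sub = 1.82, onset_width = 0,
                       noise_sd = 0, seed = 1)
  res2 <- run_treatment(sch, emission_source(m1, duration = 5e-4,
                                             sample_rate = 2.5e6),
                        detector_config = list(enabled = FALSE))
  expect_equal(res2$applied_MPa, sch$pressure_MPa)

  short <- simulate_treatment_emissions(m0, build_ramp_schedule(
    total_duration = 30), duration = 5e-4, sample_rate = 2.5e6)
  expect_error(run_treatment(sch, short), "exhausted")
})
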