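# Exposure schedules and the subharmonic-triggered pressure controller.
#
# Treatment convention: 10 ms pulse trains at 1 Hz PRF for 5 min; pressures
# ramp from 1.8 to 2.1 MPa (non-derated) in 3 kPa per-pulse increments over
# the first 2 min, then hold at the maximum. A detected change in the
# subharmonic triggers a 50% pressure drop held for the remainder.

#' Ramped exposure schedule
#'
#' Per-pulse commanded pressure `min(p_start + i * increment, p_max)` for
#' pulses inside the ramp window; clamped (or post-window) pulses hold at
#' `p_max`. With the defaults the clamp is reached exactly at pulse 100,
#' inside the 120 s window.
#'
#' @param p_start,p_max Ramp endpoints in MPa (defaults 1.8, 2.1).
#' @param increment Per-pulse pressure step in MPa (default 0.003).
#' @param ramp_window Ramp duration in s (default 120).
#' @param total_duration Treatment duration in s (default 300).
#' @param prf Pulse repetition frequency in Hz (default 1).
#' @param pulse_duration Pulse-train length in s (default 0.010).
#'
#' @return An `exposure_schedule`: data frame with zero-based `pulse_index`,
#'   `time_s`, `pressure_MPa` and `phase` (RAMP/HOLD), plus attributes.
#' @export
build_ramp_schedule <- function(p_start = 1.8, p_max = 2.1, increment = 0.003,
                                ramp_window = 120, total_duration = 300,
                                prf = 1, pulse_duration = 0.010) {
  if (p_start > p_max) stop("build_ramp_schedule: p_start exceeds p_max")
  if (increment <= 0) stop("build_ramp_schedule: increment must be positive")
  n <- round(total_duration * prf)
  i <- seq_len(n) - 1L
  t <- i / prf
  p <- ifelse(t < ramp_window, pmin(p_start + i * increment, p_max), p_max)
  phase <- ifelse(t < ramp_window & p < p_max, "RAMP", "HOLD")
  new_exposure_schedule(i, t, p, phase, prf, pulse_duration, total_duration,
                        increment = increment, p_max = p_max)
}

#' Fixed-pressure exposure schedule
#'
#' @param pressure Constant commanded pressure in MPa.
#' @param total_duration Treatment duration in s.
#' @param prf Pulse repetition frequency in Hz.
#' @param pulse_duration Pulse-train length in s.
#' @return An `exposure_schedule` with all pulses labeled HOLD.
#' @export
build_fixed_schedule <- function(pressure = 2.0, total_duration = 300, prf = 1,
                                 pulse_duration = 0.010) {
  if (pressure < 0) stop("build_fixed_schedule: pressure must be >= 0")
  n <- round(total_duration * prf)
  i <- seq_len(n) - 1L
  new_exposure_schedule(i, i / prf, rep(pressure, n), rep("HOLD", n),
                        prf, pulse_duration, total_duration,
                        increment = 0, p_max = pressure)
}

new_exposure_schedule <- function(i, t, p, phase, prf, pulse_duration,
                                  total_duration, increment, p_max) {
  df <- data.frame(pulse_index = as.integer(i), time_s = t,
                   pressure_MPa = p, phase = phase,
                   stringsAsFactors = FALSE)
  structure(df, class = c("exposure_schedule", "data.frame"),
            prf = prf, pulse_duration = pulse_duration,
            total_duration = total_duration, increment = increment,
            p_max = p_max)
}

#' Feedback controller state
#'
#' State machine of the acoustic-emissions pressure controller: accumulate a
#' band-sum baseline over the first `n_baseline` pulses, then monitor; a
#' band sum strictly above `mean + k_sd * sd` of the baseline triggers a
#' permanent drop to `drop_fraction` of the trigger-pulse pressure. Baseline
#' pulses are never eligible to trigger. If the baseline sd is exactly zero
#' a floor of `1e-12 * |mean|` is substituted so constant signals do not
#' hair-trigger. An optional median-absolute-deviation screen discards
#' baseline outliers (e.g. a transient signal disruption during baseline
#' acquisition) before the statistics are computed.
#'
#' @param n_baseline Baseline pulses (default 10).
#' @param k_sd Threshold multiplier (default 5).
#' @param drop_fraction Post-trigger pressure fraction (default 0.5).
#' @param baseline_outlier_mad Reject baseline sums more than
#'   `3 * 1.4826 * MAD` from the baseline median (default FALSE).
#'
#' @return An object of class `controller_state`, mode `BASELINE_ACCUM`.
#' @export
controller_new <- function(n_baseline = 10, k_sd = 5, drop_fraction = 0.5,
                           baseline_outlier_mad = FALSE) {
  structure(list(mode = "BASELINE_ACCUM",
                 baseline_sums = numeric(0),
                 baseline_mean = NA_real_, baseline_sd = NA_real_,
                 n_baseline = as.integer(n_baseline), k_sd = k_sd,
                 drop_fraction = drop_fraction,
                 baseline_outlier_mad = baseline_outlier_mad,
                 trigger_index = NA_integer_, trigger_pressure = NA_real_,
                 next_index = 0L),
            class = "controller_state")
}

#' Advance the controller by one pulse
#'
#' Consumes the band sum measured for pulse `pulse_index` (delivered at the
#' returned commanded pressure) and updates the state. The commanded
#' pressure equals the scheduled pressure until the pulse after a trigger,
#' then `drop_fraction * trigger_pressure` for every later pulse; TRIGGERED
#' is absorbing.
#'
#' @param state A `controller_state`.
#' @param band_sum Band sum measured at this pulse (may be NA during
#'   baseline accumulation only if detection is not wanted).
#' @param scheduled_pressure Scheduled pressure for this pulse in MPa.
#' @param pulse_index Zero-based pulse index; must arrive in order.
#'
#' @return List with `state` (updated) and `commanded_pressure` (MPa).
#' @export
controller_step <- function(state, band_sum, scheduled_pressure, pulse_index) {
  stopifnot(inherits(state, "controller_state"))
  if (pulse_index != state$next_index) {
    stop("controller_step: out-of-order pulse index (expected ",
         state$next_index, ", got ", pulse_index, ")")
  }
  commanded <- if (state$mode == "TRIGGERED") {
    state$drop_fraction * state$trigger_pressure
  } else {
    scheduled_pressure
  }

  if (state$mode == "BASELINE_ACCUM") {
    state$baseline_sums <- c(state$baseline_sums, band_sum)
    if (length(state$baseline_sums) >= state$n_baseline) {
      sums <- state$baseline_sums
      if (isTRUE(state$baseline_outlier_mad)) {
        med <- stats::median(sums)
        madv <- stats::mad(sums)
        keep <- abs(sums - med) <= 3 * madv
        if (sum(keep) >= 3) sums <- sums[keep]
      }
      state$baseline_mean <- mean(sums)
      state$baseline_sd <- stats::sd(sums)
      state$mode <- "MONITOR"
    }
  } else if (state$mode == "MONITOR") {
    sdev <- state$baseline_sd
    if (sdev == 0) sdev <- 1e-12 * abs(state$baseline_mean)
    if (is.finite(band_sum) &&
        band_sum > state$baseline_mean + state$k_sd * sdev) {
      state$mode <- "TRIGGERED"
      state$trigger_index <- as.integer(pulse_index)
      state$trigger_pressure <- scheduled_pressure
    }
  }
  state$next_index <- state$next_index + 1L
  list(state = state, commanded_pressure = commanded)
}

#' Closed-loop treatment simulation
#'
#' Runs a full treatment: for each scheduled pulse the controller issues a
#' commanded pressure, the emission source produces a received record at
#' that pressure, the record is reduced to a band sum, and the controller
#' ingests the sum. Band sums are computed after optional baseline
#' subtraction: the subtraction baseline is the mean of the first
#' `n_baseline` records, pressure-scaled by default so drive-proportional
#' leakage cancels during the ramp. Baseline-pulse band sums are computed
#' leave-one-out (each baseline record minus the mean of the others) so that
#' under pure noise the baseline and monitor sums share one distribution.
#'
#' @param schedule An `exposure_schedule`.
#' @param emission_source Function `(pressure_MPa, pulse_index) ->
#'   sonication_record`, or a list of precomputed records (one per pulse; a
#'   shorter list is a truncation error). The list form bypasses pressure
#'   feedback in record synthesis and is meant for replaying acquired data.
#' @param detector_config List; recognized fields `band`
#'   (default "subharmonic"), `n_baseline` (10), `k_sd` (5), `enabled`
#'   (TRUE), `subtract` ("time", "freq" or "none"; default "time"),
#'   `pressure_scaling` (TRUE), `window` ("hann"), `drop_fraction` (0.5),
#'   `baseline_outlier_mad` (FALSE).
#'
#' @return List with `trace` (a `detection_trace`), `applied_MPa`,
#'   `scheduled_MPa`, `triggered`, `trigger_index`, `trigger_pressure`,
#'   and `controller` (final state).
#' @export
run_treatment <- function(schedule, emission_source,
                          detector_config = list()) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  cfg <- utils::modifyList(
    list(band = "subharmonic", n_baseline = 10, k_sd = 5, enabled = TRUE,
         subtract = "time", pressure_scaling = TRUE, window = "hann",
         drop_fraction = 0.5, baseline_outlier_mad = FALSE),
    detector_config)
  n <- nrow(schedule)
  from_list <- is.list(emission_source) && !is.function(emission_source)
  if (from_list && length(emission_source) < n) {
    stop("run_treatment: emission source exhausted before schedule end")
  }
  get_record <- function(pressure, i) {
    if (from_list) emission_source[[i + 1L]] else emission_source(pressure, i)
  }
  # numerical floor: band sums below 1e-9 of the raw baseline records'
  # total spectral magnitude are machine-precision residues of an exact
  # subtraction, not signal, and are treated as zero
  num_floor <- 0
  band_sum_of <- function(rec, baseline_rec = NULL) {
    if (!is.null(baseline_rec) && cfg$subtract == "time") {
      rec <- subtract_baseline_time(rec, baseline_rec, cfg$pressure_scaling)
    }
    spec <- compute_spectrum(rec, window = cfg$window)
    if (!is.null(baseline_rec) && cfg$subtract == "freq") {
      bspec <- compute_spectrum(baseline_rec, window = cfg$window)
      spec <- subtract_baseline_freq(spec, bspec)
    }
    s <- unname(spec$band_sums[[cfg$band]])
    if (s < num_floor) 0 else s
  }
  mean_record <- function(recs) {
    m <- rowMeans(vapply(recs, `[[`, numeric(length(recs[[1]]$samples)),
                         "samples"))
    out <- recs[[1]]
    out$samples <- m
    out$commanded_pressure <-
      mean(vapply(recs, `[[`, numeric(1), "commanded_pressure"))
    out
  }

  ctrl <- controller_new(cfg$n_baseline, cfg$k_sd, cfg$drop_fraction,
                         cfg$baseline_outlier_mad)
  applied <- numeric(n)
  sums <- rep(NA_real_, n)
  base_recs <- vector("list", cfg$n_baseline)
  baseline_rec <- NULL

  for (i in seq_len(n)) {
    idx <- i - 1L
    scheduled <- schedule$pressure_MPa[i]
    commanded <- if (cfg$enabled && ctrl$mode == "TRIGGERED") {
      ctrl$drop_fraction * ctrl$trigger_pressure
    } else {
      scheduled
    }
    rec <- get_record(commanded, idx)
    rec$commanded_pressure <- if (from_list && is.finite(rec$commanded_pressure))
      rec$commanded_pressure else commanded
    rec$pulse_index <- idx
    applied[i] <- commanded

    if (i <= cfg$n_baseline) {
      base_recs[[i]] <- rec
      if (i == cfg$n_baseline) {
        num_floor <- 1e-9 * mean(vapply(base_recs, function(r)
          sum(compute_spectrum(r, window = cfg$window)$magnitudes),
          numeric(1)))
        # baseline complete: leave-one-out sums for the baseline pulses
        for (j in seq_len(cfg$n_baseline)) {
          loo <- if (cfg$subtract == "none" || cfg$n_baseline < 2) NULL else
            mean_record(base_recs[-j])
          sums[j] <- band_sum_of(base_recs[[j]], loo)
        }
        baseline_rec <- mean_record(base_recs)
        if (cfg$enabled) {
          for (j in seq_len(cfg$n_baseline)) {
            st <- controller_step(ctrl, sums[j], schedule$pressure_MPa[j],
                                  j - 1L)
            ctrl <- st$state
          }
        }
      }
    } else {
      sums[i] <- band_sum_of(rec, if (cfg$subtract == "none") NULL else
        baseline_rec)
      if (cfg$enabled) {
        st <- controller_step(ctrl, sums[i], scheduled, idx)
        ctrl <- st$state
      }
    }
  }

  trace <- detect_change(sums, n_baseline = cfg$n_baseline, k_sd = cfg$k_sd,
                         pressures = schedule$pressure_MPa)
  list(trace = trace,
       applied_MPa = applied,
       scheduled_MPa = schedule$pressure_MPa,
       triggered = cfg$enabled && ctrl$mode == "TRIGGERED",
       trigger_index = ctrl$trigger_index,
       trigger_pressure = ctrl$trigger_pressure,
       controller = ctrl)
}

#' Serialize a treatment run to a per-pulse data frame
#'
#' @param schedule The `exposure_schedule` used.
#' @param result A `run_treatment` result.
#' @return Data frame with pulse_index, time_s, scheduled_MPa, applied_MPa,
#'   phase, band_sum and triggered columns, suitable for CSV export.
#' @export
treatment_as_data_frame <- function(schedule, result) {
  data.frame(pulse_index = schedule$pulse_index,
             time_s = schedule$time_s,
             scheduled_MPa = schedule$pressure_MPa,
             applied_MPa = result$applied_MPa,
             phase = schedule$phase,
             band_sum = result$trace$band_sums,
             triggered = !is.na(result$trigger_index) &
               schedule$pulse_index >= result$trigger_index)
}
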