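#' Acoustic medium
#'
#' Minimal description of the propagation medium needed for plane-wave
#' intensity computations.
#'
#' @param density Mass density in kg/m^3.
#' @param sound_speed Longitudinal sound speed in m/s.
#'
#' @return An object of class `acoustic_medium`.
#' @export
#' @examples
#' water <- acoustic_medium(998, 1483)
acoustic_medium <- function(density = 998, sound_speed = 1483) {
  if (density <= 0 || sound_speed <= 0) {
    stop("acoustic_medium: density and sound_speed must be strictly positive")
  }
  structure(list(density = density, sound_speed = sound_speed),
            class = "acoustic_medium")
}

# internal constructor; samples are unit-peak, physical pressure is applied
# downstream by the exposure schedule
new_pulse_train <- function(samples, sample_rate, center_freq, channel,
                            bursts, train_duration, continuous = FALSE) {
  structure(list(samples = samples,
                 sample_rate = sample_rate,
                 center_freq = center_freq,
                 channel = channel,
                 bursts = bursts,
                 train_duration = train_duration,
                 continuous = continuous),
            class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf(
    "<pulse_train> channel %s: %d samples @ %.3g MHz, f0 = %.0f kHz, %d burst(s), duty %.4f\n",
    x$channel, length(x$samples), x$sample_rate / 1e6, x$center_freq / 1e3,
    nrow(x$bursts), train_duty(x)))
  invisible(x)
}

#' Within-train duty cycle of a pulse train
#'
#' Fraction of samples inside annotated bursts.
#'
#' @param train A `pulse_train`.
#' @return Duty cycle in \[0, 1\].
#' @export
train_duty <- function(train) {
  stopifnot(inherits(train, "pulse_train"))
  if (train$continuous) return(1)
  on <- sum(train$bursts$n_samples)
  on / length(train$samples)
}

#' Continuous sinusoidal burst
#'
#' Builds the 10 ms sinusoidal exposure used alongside SBPK pulse trains:
#' a single continuous burst of `duration * f0` cycles at unit peak
#' amplitude. The burst is its own pulse-inversion partner (flagged
#' continuous, not paired).
#'
#' @param f0 Center frequency in Hz (default 486 kHz).
#' @param duration Burst duration in seconds.
#' @param sample_rate Sampling rate in Hz; must be at least `10 * f0`.
#'
#' @return A `pulse_train` with one burst annotation.
#' @export
#' @examples
#' tr <- make_sine_burst(486e3, 0.010, 48.6e6)
#' length(tr$samples)   # 486000
#' tr$bursts$n_cycles   # 4860
make_sine_burst <- function(f0 = 486e3, duration = 0.010, sample_rate = 50e6) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("make_sine_burst: duration must be positive")
  }
  if (sample_rate < 10 * f0) {
    stop("make_sine_burst: sample_rate must be at least 10 * f0 (undersampled)")
  }
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  samples <- sin(2 * pi * f0 * t)
  bursts <- data.frame(start = 1L,
                       n_cycles = f0 * duration,
                       n_samples = n,
                       phase_key = 0,
                       channel_phase = 0,
                       partner = 1L)
  new_pulse_train(samples, sample_rate, f0, "A", bursts, duration,
                  continuous = TRUE)
}

#' Two-channel SBPK pulse-train pair
#'
#' Generates a short-burst phase-keying (SBPK) transmit pair, one train per
#' transducer of the dual-aperture configuration. Each channel carries
#' `n_burst_pairs` pulse-inversion pairs of `burst_cycles`-cycle tone bursts;
#' within a pair the two bursts differ in phase by pi so that their aligned
#' sum cancels. Burst start times are jittered inside equal non-overlapping
#' slots by a seeded uniform draw. Channel B repeats the channel-A timing but
#' adds a per-pair phase key so that superposition at the focus yields
#' varying resultant magnitudes.
#'
#' @param f0 Center frequency in Hz.
#' @param train_duration Train length in seconds (default 10 ms).
#' @param sample_rate Sampling rate in Hz (default 50 MHz for clean
#'   pulse-inversion cancellation).
#' @param burst_cycles Cycles per short burst (default 5).
#' @param n_burst_pairs Pulse-inversion pairs per channel (default 16; the
#'   default within-train duty keeps the temporal-average intensity of the
#'   full exposure schedule below 0.05 W/cm^2 at the maximum drive pressure).
#' @param inter_channel_phase_scheme `"quadrature"` draws channel-B pair
#'   phases from \{0, pi/2, pi, 3pi/2\}; `"none"` keeps both channels in phase.
#' @param seed Integer seed; identical seeds give bitwise-identical trains.
#'
#' @return A list with elements `A` and `B`, each a `pulse_train`.
#' @export
make_sbpk_pair <- function(f0 = 486e3, train_duration = 0.010,
                           sample_rate = 50e6, burst_cycles = 5,
                           n_burst_pairs = 16,
                           inter_channel_phase_scheme = c("quadrature", "none"),
                           seed = 1L) {
  inter_channel_phase_scheme <- match.arg(inter_channel_phase_scheme)
  n_bursts <- 2L * n_burst_pairs
  on_time <- n_bursts * burst_cycles / f0
  if (on_time > train_duration) {
    stop("make_sbpk_pair: requested on-time (", signif(on_time, 4),
         " s) exceeds train duration (", train_duration, " s)")
  }
  n <- round(train_duration * sample_rate)
  burst_samples <- round(burst_cycles / f0 * sample_rate)
  slot <- n %/% n_bursts
  if (burst_samples > slot) {
    stop("make_sbpk_pair: bursts do not fit in non-overlapping slots")
  }

  set.seed(seed)
  jitter <- floor(stats::runif(n_bursts) * (slot - burst_samples + 1))
  starts <- (seq_len(n_bursts) - 1L) * slot + jitter + 1L
  pair_id <- rep(seq_len(n_burst_pairs), each = 2L)
  phase_key <- rep(c(0, pi), times = n_burst_pairs)
  partner <- as.integer(ifelse(seq_len(n_bursts) %% 2L == 1L,
                               seq_len(n_bursts) + 1L,
                               seq_len(n_bursts) - 1L))
  chanB_pair_phase <- switch(inter_channel_phase_scheme,
    quadrature = sample(c(0, pi / 2, pi, 3 * pi / 2), n_burst_pairs,
                        replace = TRUE),
    none = rep(0, n_burst_pairs))

  synth <- function(channel_phase_per_burst, channel) {
    samples <- numeric(n)
    for (b in seq_len(n_bursts)) {
      idx <- starts[b]:(starts[b] + burst_samples - 1L)
      tt <- (seq_len(burst_samples) - 1) / sample_rate
      samples[idx] <- sin(2 * pi * f0 * tt + phase_key[b] +
                            channel_phase_per_burst[b])
    }
    bursts <- data.frame(start = starts,
                         n_cycles = burst_cycles,
                         n_samples = burst_samples,
                         phase_key = phase_key,
                         channel_phase = channel_phase_per_burst,
                         partner = partner)
    new_pulse_train(samples, sample_rate, f0, channel, bursts, train_duration)
  }

  list(A = synth(rep(0, n_bursts), "A"),
       B = synth(rep(chanB_pair_phase, each = 2L), "B"))
}

#' Pulse-inversion combination of two received records
#'
#' Sample-wise sum of a positive- and a negative-polarity record. For a
#' linear (odd-symmetric) echo the fundamental and odd harmonics cancel
#' while even-harmonic (nonlinear microbubble) content is retained.
#'
#' @param record_pos,record_neg Equal-length numeric vectors, aligned to the
#'   burst start and sharing a sample rate.
#' @return Numeric vector, the sample-wise sum.
#' @export
pulse_inversion_combine <- function(record_pos, record_neg) {
  if (length(record_pos) != length(record_neg)) {
    stop("pulse_inversion_combine: records must have equal length (alignment)")
  }
  record_pos + record_neg
}

#' Spatial-peak temporal-average intensity of an exposure
#'
#' Plane-wave convention:
#' `I_spta = p^2 / (2 rho c) * duty_within * (train_duration * prf)`,
#' i.e. the free-field peak intensity derated by the within-train duty of the
#' pulse train and the macro duty of the pulse repetition.
#'
#' @param train A `pulse_train`.
#' @param peak_pressure Peak (non-derated) pressure in Pa.
#' @param prf Pulse repetition frequency in Hz; `prf * train_duration` must
#'   not exceed 1.
#' @param medium An `acoustic_medium` (default degassed water).
#'
#' @return Intensity in W/cm^2.
#' @export
#' @examples
#' tr <- make_sine_burst(486e3, 0.010, 10e6)
#' compute_ispta(tr, 2.1e6, prf = 1)  # ~1.49 W/cm^2
compute_ispta <- function(train, peak_pressure, prf = 1,
                          medium = acoustic_medium()) {
  stopifnot(inherits(train, "pulse_train"), inherits(medium, "acoustic_medium"))
  if (peak_pressure < 0) stop("compute_ispta: peak_pressure must be >= 0")
  if (prf * train$train_duration > 1 + 1e-12) {
    stop("compute_ispta: prf * train_duration must not exceed 1")
  }
  i_peak <- peak_pressure^2 / (2 * medium$density * medium$sound_speed) # W/m^2
  i_peak * train_duty(train) * (train$train_duration * prf) / 1e4
}
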