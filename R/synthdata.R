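# Seeded synthetic-data generators: received acoustic-emission records with
# pressure-gated microbubble components, contrast-MRI image pairs, and
# water-path vs bone-path benchtop field-scan pairs. Generators are
# phenomenological stand-ins for the acquired data; they reproduce the
# statistical structure the analysis assumes, not bubble physics.

#' Phenomenological microbubble emission model
#'
#' Per-pulse received signal model: fundamental leakage proportional to the
#' commanded pressure, plus subharmonic (f0/2), 2nd-harmonic (2 f0) and
#' 1st-ultraharmonic (3 f0/2) tones that switch on smoothly above their
#' onset pressures once microbubbles have arrived, plus white Gaussian
#' noise, all filtered by the narrowband receiver. Component onset is a
#' logistic ramp of width `onset_width` (10-90% transition) in commanded
#' pressure; a width of 0 gives a hard threshold.
#'
#' Default amplitudes are calibrated so that, with the default record
#' parameters, the fully-developed subharmonic band sum sits about 20
#' noise standard deviations above the noise-only band-sum mean: the
#' 5-sigma detection threshold is then crossed near the logistic midpoint,
#' mirroring detections that occur mid-ramp close to the onset pressure.
#'
#' @param fundamental_leak_amp Fundamental leakage amplitude per MPa of
#'   commanded pressure (default 1).
#' @param subharmonic_amp,second_harmonic_amp,ultraharmonic_amp Component
#'   amplitudes at full development (defaults 0.014, 0.007, 0.003).
#' @param onset_pressure_sub,onset_pressure_h2,onset_pressure_uh Onset
#'   pressures in MPa (defaults 1.95, 1.95, 2.0).
#' @param onset_width Logistic transition width in MPa (default 0.010).
#' @param growth Amplitude growth above onset: `"none"` (default),
#'   `"linear"` or `"quadratic"` in `pressure / onset`.
#' @param noise_sd White-noise standard deviation (default 0.01).
#' @param mb_arrival_pulse First pulse index with microbubbles present
#'   (default 0; infusion begins before sonication).
#' @param receiver A `receiver_model`, or NULL to skip receiver filtering.
#' @param seed Integer; records are reproducible per (seed, pulse_index).
#'
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(fundamental_leak_amp = 1,
                           subharmonic_amp = 0.014,
                           onset_pressure_sub = 1.95,
                           second_harmonic_amp = 0.007,
                           onset_pressure_h2 = 1.95,
                           ultraharmonic_amp = 0.003,
                           onset_pressure_uh = 2.0,
                           onset_width = 0.010,
                           growth = c("none", "linear", "quadratic"),
                           noise_sd = 0.01,
                           mb_arrival_pulse = 0L,
                           receiver = receiver_model(),
                           seed = 1L) {
  growth <- match.arg(growth)
  amps <- c(fundamental_leak_amp, subharmonic_amp, second_harmonic_amp,
            ultraharmonic_amp, noise_sd)
  if (any(amps < 0)) stop("emission_model: amplitudes must be >= 0")
  structure(list(fundamental_leak_amp = fundamental_leak_amp,
                 subharmonic_amp = subharmonic_amp,
                 onset_pressure_sub = onset_pressure_sub,
                 second_harmonic_amp = second_harmonic_amp,
                 onset_pressure_h2 = onset_pressure_h2,
                 ultraharmonic_amp = ultraharmonic_amp,
                 onset_pressure_uh = onset_pressure_uh,
                 onset_width = onset_width, growth = growth,
                 noise_sd = noise_sd,
                 mb_arrival_pulse = as.integer(mb_arrival_pulse),
                 receiver = receiver, seed = as.integer(seed)),
            class = "emission_model")
}

onset_gate <- function(pressure, onset, width) {
  if (width <= 0) return(as.numeric(pressure >= onset))
  1 / (1 + exp(-4 * (pressure - onset) / width))
}

#' Simulate one received emission record
#'
#' @param model An `emission_model`.
#' @param commanded_pressure Commanded non-derated pressure in MPa.
#' @param pulse_index Zero-based pulse index.
#' @param duration Acquisition window length in s (default 1 ms).
#' @param sample_rate Sampling rate in Hz (default 5 MHz; must exceed
#'   2.5x the 2nd harmonic).
#' @param f0 Transmit center frequency in Hz.
#' @return A `sonication_record`.
#' @export
simulate_emission_record <- function(model, commanded_pressure,
                                     pulse_index = 0L, duration = 1e-3,
                                     sample_rate = 5e6, f0 = 486e3) {
  stopifnot(inherits(model, "emission_model"))
  if (sample_rate <= 2.5 * (2 * f0)) {
    stop("simulate_emission_record: sample_rate must exceed 2.5 * (2 f0)")
  }
  set.seed((model$seed %% 10007L) * 100003L + as.integer(pulse_index))
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  p <- commanded_pressure
  x <- model$fundamental_leak_amp * p * sin(2 * pi * f0 * t)
  if (pulse_index >= model$mb_arrival_pulse) {
    gfac <- switch(model$growth, none = function(on) 1,
                   linear = function(on) p / on,
                   quadratic = function(on) (p / on)^2)
    comp <- function(amp, onset, freq) {
      g <- onset_gate(p, onset, model$onset_width)
      if (amp <= 0 || g < 1e-12) return(0)
      amp * g * gfac(onset) * sin(2 * pi * freq * t + stats::runif(1, 0, 2 * pi))
    }
    x <- x +
      comp(model$subharmonic_amp, model$onset_pressure_sub, f0 / 2) +
      comp(model$second_harmonic_amp, model$onset_pressure_h2, 2 * f0) +
      comp(model$ultraharmonic_amp, model$onset_pressure_uh, 3 * f0 / 2)
  }
  if (model$noise_sd > 0) x <- x + stats::rnorm(n, 0, model$noise_sd)
  rec <- sonication_record(x, sample_rate, pulse_index, p,
                           is_baseline = FALSE, f0 = f0)
  if (!is.null(model$receiver)) rec <- apply_receiver(rec, model$receiver)
  rec
}

#' Simulate emissions for a whole exposure schedule
#'
#' One record per scheduled pulse at its commanded pressure; the result is
#' usable as the `emission_source` of [run_treatment()] (open loop) or the
#' model can be wrapped as a function for closed-loop control.
#'
#' @param model An `emission_model`.
#' @param schedule An `exposure_schedule`.
#' @param ... Passed to [simulate_emission_record()].
#' @return List of `sonication_record`s.
#' @export
simulate_treatment_emissions <- function(model, schedule, ...) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  lapply(seq_len(nrow(schedule)), function(i) {
    simulate_emission_record(model, schedule$pressure_MPa[i],
                             schedule$pulse_index[i], ...)
  })
}

#' Wrap an emission model as a closed-loop emission source
#'
#' @param model An `emission_model`.
#' @param ... Passed to [simulate_emission_record()].
#' @return Function `(pressure_MPa, pulse_index) -> sonication_record`.
#' @export
emission_source <- function(model, ...) {
  function(pressure, pulse_index) {
    simulate_emission_record(model, pressure, pulse_index, ...)
  }
}

#' Synthetic baseline / contrast-enhanced MRI image pair
#'
#' Gaussian-noise images with the post image elevated by
#' `enhancement_pct` percent of the baseline mean over a 3x3 region.
#'
#' @param baseline_mean,baseline_sd Image mean and noise sd.
#' @param enhancement_pct Enhancement of the ROI in percent of the baseline
#'   mean (default 31.8, the mean enhancement observed at confirmed
#'   openings).
#' @param image_shape Rows, cols (default 64 x 64).
#' @param roi_center Row, col of the enhanced 3x3 region center.
#' @param seed Integer seed.
#' @return List with matrices `pre` and `post` and the configuration.
#' @export
make_synthetic_mri_pair <- function(baseline_mean = 100, baseline_sd = 5,
                                    enhancement_pct = 31.8,
                                    image_shape = c(64, 64),
                                    roi_center = c(32, 32), seed = 1L) {
  set.seed(seed)
  pre <- matrix(stats::rnorm(prod(image_shape), baseline_mean, baseline_sd),
                image_shape[1], image_shape[2])
  post <- matrix(stats::rnorm(prod(image_shape), baseline_mean, baseline_sd),
                 image_shape[1], image_shape[2])
  r <- (roi_center[1] - 1):(roi_center[1] + 1)
  c <- (roi_center[2] - 1):(roi_center[2] + 1)
  post[r, c] <- post[r, c] + enhancement_pct / 100 * baseline_mean
  list(pre = pre, post = post, roi_center = roi_center,
       enhancement_pct = enhancement_pct, baseline_mean = baseline_mean,
       baseline_sd = baseline_sd)
}

#' Synthetic water-path / bone-path field-scan pair
#'
#' Water scan: 2-D Gaussian beam profile with configured 70%-of-peak
#' widths. Bone scan: transmission-scaled copy of the profile displaced by
#' `shift_mm` along the first axis, plus optional Gaussian noise.
#'
#' @param transmission Pressure transmission fraction (default 0.473, the
#'   observed mean transmission to the target).
#' @param shift_mm Focal shift in mm (default 2.7, the observed mean).
#' @param dims_70pct 70% full widths of the beam in mm (default
#'   `c(8.4, 4.5)`).
#' @param spacing Grid spacing in mm (default 0.25).
#' @param noise_sd Additive noise sd relative to the water peak (= 1).
#' @param seed Integer seed.
#' @param extent_mm Grid half-extent in mm (default 12).
#' @param fov Analysis field of view in mm (default 6).
#' @return A `field_scan_pair`: list with `water`, `bone`, `spacing`, `fov`.
#' @export
make_synthetic_field_scans <- function(transmission = 0.473, shift_mm = 2.7,
                                       dims_70pct = c(8.4, 4.5),
                                       spacing = 0.25, noise_sd = 0,
                                       seed = 1L, extent_mm = 12, fov = 6) {
  set.seed(seed)
  sigma <- (dims_70pct / 2) / sqrt(2 * log(1 / 0.7))
  ax <- seq(-extent_mm, extent_mm, by = spacing)
  gauss2 <- function(center1) {
    outer(exp(-(ax - center1)^2 / (2 * sigma[1]^2)),
          exp(-ax^2 / (2 * sigma[2]^2)))
  }
  water <- gauss2(0)
  bone <- transmission * gauss2(shift_mm)
  if (noise_sd > 0) {
    bone <- bone + matrix(stats::rnorm(length(bone), 0, noise_sd),
                          nrow(bone), ncol(bone))
  }
  structure(list(water = water, bone = bone, spacing = spacing, fov = fov,
                 transmission = transmission, shift_mm = shift_mm),
            class = "field_scan_pair")
}

#' Noise-only band-sum series for a schedule
#'
#' Fast batch generator of per-pulse subharmonic band sums under a
#' component-free emission model (noise only), for Monte-Carlo studies of
#' the false-trigger rate. Matches [compute_spectrum()] band conventions;
#' the batch path evaluates the whole treatment with one matrix FFT.
#'
#' @param n_pulses Pulses per treatment.
#' @param noise_sd White-noise sd.
#' @param duration,sample_rate Record parameters (defaults 0.5 ms, 2.5 MHz).
#' @param f0 Transmit center frequency in Hz.
#' @param band Band name (default "subharmonic").
#' @param window FFT window.
#' @param seed Integer seed.
#' @return Numeric vector of `n_pulses` band sums.
#' @export
simulate_noise_band_sums <- function(n_pulses, noise_sd = 0.01,
                                     duration = 5e-4, sample_rate = 2.5e6,
                                     f0 = 486e3, band = "subharmonic",
                                     window = "hann", seed = 1L) {
  set.seed(seed)
  n <- round(duration * sample_rate)
  m <- matrix(stats::rnorm(n * n_pulses, 0, noise_sd), n, n_pulses)
  band_sum_matrix(m, sample_rate, f0, band, window)
}
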