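---
title: "Methods: simulating and analyzing transvertebral FUS blood-spinal-cord-barrier opening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing transvertebral FUS blood-spinal-cord-barrier opening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinefus)
```

# The problem

Focused ultrasound (FUS) combined with circulating microbubbles can open
the blood-spinal-cord barrier (BSCB) transiently and non-invasively,
which would allow drugs to reach spinal-cord tissue. Delivering FUS
through the intact vertebral column is hard: bone attenuates and aberrates
the beam, and reflections inside the spinal canal promote standing waves.
A dual-aperture, crossed-beam configuration transmitting short-burst
phase-keying (SBPK) pulse trains at a sub-megahertz center frequency
(f0 = 486 kHz here) addresses both problems. Treatment is monitored by
passive cavitation detection: microbubble emissions at the subharmonic
(f0/2 = 243 kHz), first ultraharmonic (3 f0/2 = 729 kHz) and second
harmonic (2 f0 = 972 kHz) signal stable cavitation, and a detected
subharmonic change triggers a protective pressure drop.

This package implements that computational machinery end to end at desk
scale: transmit waveform synthesis, exposure scheduling and feedback
control, emissions spectral analysis, a Pennes bioheat thermal safety
model, outcome metrics, and seeded synthetic-data generators that stand in
for animal and bench data so that every stage is testable offline.

# Transmit waveforms

`make_sine_burst()` builds the continuous 10 ms sinusoidal burst;
`make_sbpk_pair()` builds the two-channel SBPK pair. Waveforms are
unit-peak; physical pressure enters only through the exposure schedule,
which keeps waveform shape independent of drive level.

The SBPK microstructure is parametric because only its morphology is
constrained (brief inverted pulse pairs whose focal superposition gives
varying resultant magnitudes). Defaults, all config-exposed:

* `burst_cycles = 5` - a short burst at 486 kHz (about 10 us);
* `n_burst_pairs = 16` pulse-inversion (PI) pairs per channel, placed by
  seeded uniform jitter inside equal non-overlapping slots;
* channel-B phase keys drawn from {0, pi/2, pi, 3*pi/2} per pair
  ("quadrature" scheme);
* `sample_rate = 50` MHz (about 100 samples per cycle) so PI pairs cancel
  to machine precision.

The pair count is the one deliberate calibration: the within-train duty it
implies (about 3.3%) keeps the spatial-peak temporal-average intensity of
the full schedule at the 2.1 MPa ramp maximum just below the 0.05 W/cm^2
safety ceiling for sparsely distributed SBPK exposures.
`compute_ispta()` uses the plane-wave convention
`I_spta = p^2/(2 rho c) * duty_within * (train_duration * prf)`.

# Exposure schedules and the feedback controller

`build_ramp_schedule()` encodes the ramped protocol: 10 ms pulse trains at
1 Hz PRF for 5 min, pressures ramped from 1.8 MPa to 2.1 MPa (non-derated)
in 3 kPa per-pulse increments over the first 2 min, then held at maximum.
At 1 Hz a 3 kPa step reaches 2.1 MPa at pulse 100, before the 120 s window
closes; the schedule clamps there and holds, which honors both printed
endpoints. Whether the experimental system clamped or skipped increments is
not documented; clamping is the package's choice.

The controller (`controller_new()` / `controller_step()`) is a three-state
machine: accumulate the band sums of the first `n_baseline = 10` pulses,
then monitor; a band sum strictly above `mean + k_sd * sd` (sample sd,
`k_sd = 5`) triggers a permanent drop to 50% of the trigger-pulse pressure.
Baseline pulses are never trigger-eligible. Degenerate-input safety: if the
baseline sd is exactly zero, a floor of `1e-12 * |mean|` is substituted. An
optional median-absolute-deviation screen (off by default) discards
baseline outliers such as a transient signal disruption, the known
failure mode of a baseline-referenced threshold.

`run_treatment()` closes the loop: commanded pressure -> synthetic record
-> band sum -> controller. Two numerical choices matter here:

* **Leave-one-out baseline residuals.** The detection trace subtracts the
  mean baseline record from each pulse. For the baseline pulses themselves
  the mean of the *other* nine records is used. Under pure noise this makes
  baseline and monitor band sums share one distribution (variance
  `sigma^2 (1 + 1/n)` both); subtracting the full mean would give baseline
  residuals the smaller variance `sigma^2 (1 - 1/n)` and bias the
  threshold low.
* **Numerical floor.** When baseline subtraction is exact (e.g. noiseless,
  drive-proportional leakage), the residual band sums are machine-epsilon
  rounding noise. Band sums below `1e-9` of the raw baseline records'
  total spectral magnitude are treated as zero so that epsilon-scale
  residues cannot out-vote an epsilon-scale threshold.

# Emissions analysis

`compute_spectrum()` returns a one-sided, window-gain-corrected magnitude
spectrum (a unit on-bin tone has magnitude 1) and sums 40 kHz bands
centered on 243, 729 and 972 kHz. Conventions fixed for reproducibility
where the source procedure is silent: Hann window by default (rectangular
available), inclusive lower / exclusive upper band edges, magnitude (not
power) spectra, sample sd with n-1 denominator for the baseline statistic.

The receiver is modeled by `receiver_model()` as a zero-phase Butterworth
band-pass (order 4, fractional bandwidth 20%) centered at 250 kHz; the
physical element's bandwidth is uncharacterized, so it is parametric.
Zero-phase filtering preserves pulse alignment, which time-domain baseline
subtraction relies on. Because signal and noise in a band are filtered
identically, in-band signal-to-noise - and hence detection behavior - is
insensitive to the exact bandwidth.

Two baseline-subtraction variants are implemented. The time-domain method
(`subtract_baseline_time()`, with pressure scaling so drive-proportional
content cancels during the ramp) is the method of record. The
frequency-domain magnitude subtraction (`subtract_baseline_freq()`,
`max(record - baseline, 0)` bin-wise) is retained for comparison: by the
triangle inequality it can never report more of a phase-shifted new
component than the time-domain residual does, which is the mechanism by
which a magnitude-subtraction detector under-detects.

# Detection statistics at treatment length

The detector declares a change at the first monitor pulse whose band sum
exceeds `mean + 5 sd` of ten baseline sums. With only ten baseline
samples the threshold is itself noisy (t-like with 9 df), and a 5-min
treatment offers 290 eligible pulses. The package's Monte-Carlo tests
compute a per-treatment false-trigger probability of about 0.10 for
noise-only 300-pulse treatments at `k_sd = 5` (and near 1 at `k_sd = 2`).
This is a property of the statistic at these operating conditions, not an
implementation artifact: it is insensitive to the number of FFT bins
summed per band, and shortening treatments or enlarging the baseline -
which would change the study conditions - are the only ways to push it
materially lower. The directional claim (2 sd is strictly more
false-positive-prone than 5 sd) is robust.

# Synthetic emissions

`emission_model()` generates per-pulse records: fundamental leakage
proportional to commanded pressure, nonlinear components gated by a
logistic onset in pressure (10-90% transition width 10 kPa, configurable;
width 0 gives a hard threshold), white Gaussian noise, and the receiver
filter. Records are bit-reproducible per `(seed, pulse_index)`. Component
amplitude growth above onset is configurable (`none`, `linear`,
`quadratic` in pressure/onset) because the true growth law is unknown.

Defaults are set by one a-priori design rule: with `noise_sd = 0.01` and
the default acquisition window, the noise-only subharmonic band-sum sd is
0.00136 and a unit in-band tone contributes 2.0, so
`subharmonic_amp = 0.014` places the fully-developed subharmonic about 20
noise-sd above the noise mean. The 5-sigma threshold then sits near the
logistic midpoint and detection lands within one 3 kPa increment of the
onset pressure - the regime in which detections were observed mid-ramp
(1.9-2.1 MPa). Onset defaults are 1.95 MPa (subharmonic and 2nd harmonic)
and 2.0 MPa (ultraharmonic), inside that range, with the 2nd harmonic at
half and the ultraharmonic at about a fifth of the subharmonic amplitude,
mirroring the reported detection frequency ordering (always / most cases /
some cases). The acquisition window default is 1 ms at 5 MHz (1 kHz bin
spacing, 40 bins per summation band); closed-loop studies in the test
suite use 0.5 ms at 2.5 MHz, which halves cost without changing detection
behavior.

What the generator does *not* emulate: bubble dynamics (no
Rayleigh-Plesset physics), broadband inertial-cavitation emissions,
temporally correlated noise or gain drift, motion, and receiver
nonidealities beyond a band-pass. Passing tests therefore demonstrate that
the analysis machinery is correct under the stated statistical structure,
not that the controller is field-ready.

# Thermal model

The propagation of SBPK exposures through CT-derived laminae is out of
scope (it requires CT volumes and an elastic wave solver); the focal field
is instead the parametric Gaussian ellipsoid of `build_focal_field()`,
with 70%-of-peak widths set to the measured focal dimensions
(8.4 x 4.5 x 4.7 mm) and peak pressure equal to drive pressure times a
through-bone transmission factor. Heat deposition is the plane-wave
relation `Q = alpha p^2/(rho c)` with `alpha = 5 Np/m/MHz * f[MHz]`
(spinal-cord absorption taken equal to brain).

`pennes_solve()` integrates the Pennes bioheat equation with explicit
forward Euler and a central-difference Laplacian (1-3 D, 0.2 mm default
spacing, Dirichlet far-field boundary at arterial temperature). The
stability bound `dt <= dx^2 rho c_p / (2 D k)` is checked and reported.
The pulsed source (10 ms on every 1 s for 5 min) is handled by computing
each step's on-fraction analytically, so deposited energy is exact for
any stable step; the adiabatic limit then matches
`dT = Q t_on/(rho c_p)` to rounding. Tissue defaults: k = 0.528 W/(m K),
c_p = 3600 J/(kg K), rho = 1000 kg/m^3, perfusion off (config-exposed;
blood at 1050 kg/m^3, 3617 J/(kg K) when enabled).

At 2.1 MPa drive over the observed in-view transmission range
(48.5-95.0%), the pipeline's maximum temperature rises are of order
tenths of a degree, and `mb_enhanced()` applies the expected ~3.6x
microbubble enhancement. Because the Gaussian field only approximates the
aberrated in-canal field, the no-bubble range should be read as an
order-of-magnitude safety result. Because the bioheat equation is linear
in Q, the hi/lo ratio is exactly `(0.95/0.485)^2` for a fixed field
geometry whatever the conduction; a larger observed ratio would imply
different field geometries at the two transmissions.

# Outcome metrics

* `assess_enhancement()`: opening iff the 3x3 target-window mean is at
  least 2 baseline sd above the baseline-window mean (inclusive boundary,
  per "at least"; equality with the baseline mean itself is not opening).
  `find_enhancement_center()` centers the window on the maximum of the
  3x3 box mean of post - pre, restricted to a user ROI when given -
  a single-voxel argmax would park the window on a noise spike or a
  region corner and understate enhancement.
* `aggregate_outcomes()`: per-location tallies over the packaged outcome
  table (EBD-positive / ramped, subharmonic-positive / viable, MRI
  confirmations per pig, subharmonic detections without confirmed opening,
  detection failures, macroscopic damage). "Opening not confirmed" means
  neither EBD nor MRI positive.
* `transmission_metrics()`: through-bone transmission at the water-focus
  coordinate, maximum transmission within the 6 x 6 mm field of view, and
  the focal shift (Euclidean peak displacement). Both transmission
  readings are reported because "transmission to the target" could mean
  either; scan-peak ties break to the first occurrence in row-major order.
* `ct_top_fraction_density()`: mean and sd of the top 5% (ceiling rule) of
  CT density samples, the cut that isolates bone from residual soft
  tissue.
* `summarize_histology()`: maximum grade across sectioning levels.

# Problem sizes and runtime choices

The test suite runs full 300-pulse treatments for closed-loop checks
(0.5 ms records at 2.5 MHz), 100 seeded replicates for onset-recovery
statistics, 1000 replicates (batch FFT path, `simulate_noise_band_sums()`)
for false-trigger rates, and small grids (a few mm at 0.4 mm spacing,
5-30 s heating) for thermal closed-form comparisons, with one full-length
adiabatic run; the analysis scripts run the full 5-min thermal simulation
on the 0.2 mm grid. These sizes keep the whole suite near a minute on one
core while leaving every statistical conclusion at its stated replicate
count.

# Known limitations

* The focal field is separable-Gaussian; no aberration, standing waves,
  shear conversion or bone heating. Absolute temperature rises inherit
  this approximation.
* The emission generator is phenomenological; onset pressures and
  amplitudes are inputs, so parameter-recovery results validate the
  detector, not bubble physics.
* The controller model is synchronous and latency-free.
* The outcome table ships as transcribed; aggregation reproduces its
  tallies but performs no statistical inference on them.
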