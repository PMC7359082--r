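# Plain-text serialization: sample CSVs with JSON sidecars for waveforms
# and records, CSV export for spectra and treatment traces.

#' Export a pulse train as CSV samples plus a JSON sidecar
#'
#' @param train A `pulse_train`.
#' @param path Sample CSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_pulse_train <- function(train, path) {
  stopifnot(inherits(train, "pulse_train"))
  utils::write.csv(data.frame(sample = train$samples), path, row.names = FALSE)
  meta <- list(sample_rate = train$sample_rate, f0 = train$center_freq,
               channel = train$channel, train_duration = train$train_duration,
               continuous = train$continuous, bursts = train$bursts)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a pulse train written by [write_pulse_train()]
#'
#' @param path Sample CSV path with a `<path>.json` sidecar.
#' @return A `pulse_train`.
#' @export
read_pulse_train <- function(path) {
  samples <- utils::read.csv(path)$sample
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_pulse_train(samples, meta$sample_rate, meta$f0, meta$channel,
                  as.data.frame(meta$bursts), meta$train_duration,
                  isTRUE(meta$continuous))
}

#' Export a spectrum as CSV (freq_Hz, magnitude)
#'
#' @param spec A `spectral_summary`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectral_summary"))
  utils::write.csv(data.frame(freq_Hz = spec$freqs,
                              magnitude = spec$magnitudes),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a treatment run as a per-pulse CSV
#'
#' @param schedule The `exposure_schedule` used.
#' @param result A [run_treatment()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_treatment_csv <- function(schedule, result, path) {
  utils::write.csv(treatment_as_data_frame(schedule, result), path,
                   row.names = FALSE)
  invisible(path)
}
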