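#' Uniformly sampled single-channel signal
#'
#' The common carrier for raw heart-sound traces, Hilbert envelopes and
#' arterial-pressure waveforms: a numeric sample vector plus its sampling
#' rate, a unit label and the time offset of the first sample. Generators
#' attach ground-truth event times under `meta`.
#'
#' @param samples Numeric vector of finite samples, length >= 2.
#' @param fs Sampling rate in Hz (> 0).
#' @param unit Unit label for the samples (e.g. `"au"`, `"mmHg"`).
#' @param start_time_s Time of the first sample in seconds.
#' @param meta Optional named list of side metadata (true event times,
#'   generator parameters, processing provenance).
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, fs, unit = "au", start_time_s = 0, meta = list()) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop_invalid("signal_record needs at least 2 samples")
  if (!all(is.finite(samples))) stop_invalid("signal_record samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_invalid("fs must be a single positive number")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), unit = as.character(unit),
         start_time_s = as.numeric(start_time_s), meta = meta),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d samples @ %g Hz (%.3f s), unit=%s, t0=%g s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              x$unit, x$start_time_s))
  invisible(x)
}

#' @export
length.signal_record <- function(x) length(x$samples)

#' Sample times of a signal record
#'
#' @param record A [signal_record()].
#' @return Numeric vector of sample times in seconds.
#' @export
record_times <- function(record) {
  stopifnot(inherits(record, "signal_record"))
  record$start_time_s + (seq_along(record$samples) - 1) / record$fs
}

#' Duration of a signal record in seconds
#'
#' @param record A [signal_record()].
#' @return Duration `length(samples) / fs` in seconds.
#' @export
record_duration <- function(record) {
  stopifnot(inherits(record, "signal_record"))
  length(record$samples) / record$fs
}
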