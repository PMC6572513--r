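#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, the denoising step
#' applied to the raw esophageal heart-sound trace before envelope
#' extraction. The default band of 25-120 Hz covers the dominant S1/S2
#' energy while removing baseline drift and high-frequency noise.
#'
#' @param record A [signal_record()].
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order Butterworth design order (default 4; zero-phase filtering
#'   doubles the effective roll-off).
#' @return A filtered [signal_record()] of the same length and sampling
#'   rate.
#' @export
bandpass <- function(record, lo = 25, hi = 120, order = 4) {
  stopifnot(inherits(record, "signal_record"))
  fs <- record$fs
  if (!(lo > 0 && lo < hi && hi < fs / 2)) {
    stop_invalid("band edges must satisfy 0 < lo < hi < fs/2; got (",
                 lo, ", ", hi, ") at fs=", fs)
  }
  bt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bt, record$samples)
  signal_record(y, fs, unit = record$unit, start_time_s = record$start_time_s,
                meta = c(record$meta, list(band_hz = c(lo, hi))))
}

#' Hilbert envelope of a signal
#'
#' Magnitude of the analytic signal, `sqrt(x^2 + H[x]^2)` where `H[x]` is
#' the Hilbert transform of `x`: the instantaneous-amplitude trace on which
#' S1 and S2 peaks are measured. Computed by the FFT analytic-signal
#' method (zeroing negative frequencies and doubling positive ones).
#'
#' @param record A [signal_record()] with at least 8 finite samples.
#' @return A non-negative [signal_record()] of the same length and
#'   sampling rate, unit-labelled as an envelope.
#' @export
hilbert_envelope <- function(record) {
  stopifnot(inherits(record, "signal_record"))
  x <- record$samples
  if (length(x) < 8L) stop_invalid("need at least 8 samples for the envelope")
  if (!all(is.finite(x))) stop_invalid("samples must be finite")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
  signal_record(env, record$fs, unit = paste0(record$unit, " (envelope)"),
                start_time_s = record$start_time_s, meta = record$meta)
}

# strict local maxima of x; the first sample of a flat plateau counts
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) idx <- c(idx, i)   # plateau start
      i <- j + 1L
    } else i <- i + 1L
  }
  idx
}

#' Detect heart-sound peaks on an envelope
#'
#' Finds local maxima of the smoothed envelope that exceed
#' `threshold_frac` times the window's 98th-percentile envelope value and
#' are separated by at least `min_separation_s`. When two candidates fall
#' inside one separation window the larger is kept; at equal height the
#' earlier one wins. Peak amplitudes are read from the raw (unsmoothed)
#' envelope near the detected location, so smoothing steers detection
#' without attenuating the measured amplitude.
#'
#' @param envelope A non-negative [signal_record()], typically from
#'   [hilbert_envelope()].
#' @param min_separation_s Minimum peak separation in seconds.
#' @param threshold_frac Detection threshold as a fraction of the
#'   98th-percentile envelope value, in (0, 1).
#' @param smooth_ms Moving-average width applied before peak picking
#'   (default 25 ms).
#' @return A data frame with columns `time_s` and `amplitude`, sorted by
#'   time; zero rows for an all-zero envelope.
#' @export
detect_sound_peaks <- function(envelope, min_separation_s = 0.1,
                               threshold_frac = 0.25, smooth_ms = 25) {
  stopifnot(inherits(envelope, "signal_record"))
  x <- envelope$samples
  if (any(x < -1e-9)) stop_invalid("envelope must be non-negative")
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop_invalid("threshold_frac must lie in (0, 1)")
  }
  fs <- envelope$fs
  empty <- data.frame(time_s = numeric(0), amplitude = numeric(0))
  if (all(x == 0)) return(empty)
  sm <- moving_average(x, round(smooth_ms / 1000 * fs))
  thr <- threshold_frac * stats::quantile(sm, 0.98, names = FALSE)
  cand <- local_maxima(sm)
  cand <- cand[sm[cand] >= thr]
  if (length(cand) == 0L) return(empty)
  # greedy selection by descending height, earlier-first on ties
  ord <- cand[order(-sm[cand], cand)]
  min_gap <- min_separation_s * fs
  keep <- logical(0)
  sel <- integer(0)
  for (i in ord) {
    if (all(abs(sel - i) >= min_gap)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  # amplitude from the raw envelope within +/- half the smoothing width
  half <- max(1L, round(smooth_ms / 1000 * fs / 2))
  amp <- vapply(sel, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    max(x[lo:hi])
  }, numeric(1))
  data.frame(time_s = envelope$start_time_s + (sel - 1L) / fs, amplitude = amp)
}

#' Label detected peaks as S1 or S2
#'
#' Classifies envelope peaks using the cardiac-timing rule that systole
#' (S1 to S2) is shorter than diastole (S2 to the next S1). The RR
#' interval is estimated from sums of adjacent inter-peak gaps (or taken
#' from `heart_rate_hint`); peaks preceded by a diastolic gap and followed
#' by a systolic gap anchor the S1 lattice, missed S1s between anchors are
#' recovered by matching peaks to the predicted lattice times, and each
#' S1's S2 is the next peak at roughly the systolic gap. Peaks that fit no
#' beat are counted in `unpaired_peaks` and excluded.
#'
#' @param peaks Data frame from [detect_sound_peaks()] (>= 4 peaks).
#' @param heart_rate_hint Optional heart rate (bpm) used instead of the
#'   internal RR estimate.
#' @return An object of class `labeled_beats`: a list with `beats` (data
#'   frame `s1_time_s`, `s1_env_amp`, `s2_time_s`, `s2_env_amp`, with `NA`
#'   for an absent S2) and `unpaired_peaks` (count).
#' @export
label_s1_s2 <- function(peaks, heart_rate_hint = NULL) {
  if (nrow(peaks) < 4L) stop_invalid("need at least 4 peaks to label beats")
  tm <- peaks$time_s
  gaps <- diff(tm)
  rr <- if (!is.null(heart_rate_hint)) 60 / heart_rate_hint else {
    stats::median(gaps[-length(gaps)] + gaps[-1L])
  }
  short <- gaps[gaps < 0.5 * rr]
  long <- gaps[gaps >= 0.5 * rr]
  if (length(short) == 0L || length(long) == 0L) {
    stop_domain("esopcg_ambiguous_rhythm",
                "ambiguous rhythm: systolic and diastolic gaps are indistinguishable")
  }
  sys_hat <- stats::median(short)
  dia_hat <- stats::median(long)
  if ((dia_hat - sys_hat) < 0.1 * dia_hat) {
    stop_domain("esopcg_ambiguous_rhythm",
                "ambiguous rhythm: systole/diastole ratio within 10%")
  }
  n <- length(tm)
  is_short <- c(gaps < 0.5 * rr, FALSE)          # gap after peak i
  prev_long <- c(TRUE, gaps >= 0.5 * rr)         # gap before peak i (first: open)
  anchors <- which(is_short & prev_long)
  if (length(anchors) == 0L) {
    stop_domain("esopcg_ambiguous_rhythm", "no S1 anchors found")
  }
  # fill missed S1s between anchors spaced ~k*RR (k >= 2)
  s1_idx <- integer(0)
  tol <- 0.2 * rr
  for (a in seq_along(anchors)) {
    s1_idx <- c(s1_idx, anchors[a])
    if (a == length(anchors)) break
    span <- tm[anchors[a + 1L]] - tm[anchors[a]]
    k <- round(span / rr)
    if (k >= 2L) {
      for (m in seq_len(k - 1L)) {
        pred <- tm[anchors[a]] + m * span / k
        free <- setdiff(seq_len(n), s1_idx)
        j <- free[which.min(abs(tm[free] - pred))]
        if (length(j) == 1L && abs(tm[j] - pred) <= tol) s1_idx <- c(s1_idx, j)
      }
    }
  }
  s1_idx <- sort(unique(s1_idx))
  used <- s1_idx
  beats <- data.frame(s1_time_s = tm[s1_idx], s1_env_amp = peaks$amplitude[s1_idx],
                      s2_time_s = NA_real_, s2_env_amp = NA_real_)
  for (b in seq_along(s1_idx)) {
    i <- s1_idx[b]
    nxt <- i + 1L
    if (nxt <= n && !(nxt %in% s1_idx)) {
      g <- tm[nxt] - tm[i]
      if (abs(g - sys_hat) <= 0.35 * sys_hat) {
        beats$s2_time_s[b] <- tm[nxt]
        beats$s2_env_amp[b] <- peaks$amplitude[nxt]
        used <- c(used, nxt)
      }
    }
  }
  structure(list(beats = beats, unpaired_peaks = n - length(unique(used))),
            class = "labeled_beats")
}

#' @export
print.labeled_beats <- function(x, ...) {
  cat(sprintf("<labeled_beats> %d beats (%d with S2), %d unpaired peaks\n",
              nrow(x$beats), sum(!is.na(x$beats$s2_time_s)), x$unpaired_peaks))
  invisible(x)
}

#' Windowed FFT total power
#'
#' Total spectral power of a window as a dB quantity:
#' `10*log10(sum_k |FFT(w * x)|^2 / (N * sum(w^2)) / power_ref)`. The
#' normalization makes the rectangular-window case equal the time-domain
#' mean square exactly (Parseval), and the Hamming window (the default, as
#' used for heart-sound spectra) a windowed estimate of the same quantity.
#'
#' @param record A [signal_record()].
#' @param window `"hamming"` or `"rectangular"`.
#' @param power_ref Reference power (squared signal units); default 1e-3,
#'   a dBm-style convention.
#' @return List with `power_db`, the linear `power`, and the
#'   normalization metadata.
#' @export
spectral_power <- function(record, window = c("hamming", "rectangular"),
                           power_ref = 1e-3) {
  stopifnot(inherits(record, "signal_record"))
  window <- match.arg(window)
  x <- record$samples
  n <- length(x)
  w <- if (window == "hamming") signal::hamming(n) else rep(1, n)
  spec <- Mod(stats::fft(w * x))^2
  p <- sum(spec) / (n * sum(w^2))
  list(power_db = 10 * log10(p / power_ref), power = p,
       window = window, power_ref = power_ref,
       normalization = "sum|FFT(w*x)|^2 / (N * sum(w^2))")
}

#' Phonocardiographic metrics for one window
#'
#' The per-window summary analyzed clinically: mean S1 and S2 amplitudes
#' on the dB scale (`20*log10` of the mean per-beat envelope peak relative
#' to `db_ref`), heart rate from the median S1-to-S1 interval, and the
#' Hamming-window FFT total power of the filtered signal.
#'
#' @param record The (band-passed) [signal_record()] the beats were
#'   detected on.
#' @param labeled A [label_s1_s2()] result with at least 4 paired beats.
#' @param db_ref Reference amplitude for the dB scale (default 1 signal
#'   unit; absolute dB values depend on amplifier gain, so only relative
#'   changes are comparable across setups).
#' @param power_ref Reference power for the total-power dB scale.
#' @return A one-row data frame with columns `s1_amp_db`, `s2_amp_db`,
#'   `heart_rate_bpm`, `total_power_db`, `n_beats`, plus attributes
#'   recording the references and power normalization.
#' @export
pcg_metrics <- function(record, labeled, db_ref = 1, power_ref = 1e-3) {
  stopifnot(inherits(record, "signal_record"), inherits(labeled, "labeled_beats"))
  beats <- labeled$beats
  paired <- beats[!is.na(beats$s2_time_s), ]
  if (nrow(paired) < 4L) {
    stop_domain("esopcg_insufficient_beats",
                "need at least 4 paired beats, got ", nrow(paired))
  }
  s1_db <- 20 * log10(mean(paired$s1_env_amp) / db_ref)
  s2_db <- 20 * log10(mean(paired$s2_env_amp) / db_ref)
  hr <- 60 / stats::median(diff(beats$s1_time_s))
  pw <- spectral_power(record, window = "hamming", power_ref = power_ref)
  out <- data.frame(s1_amp_db = s1_db, s2_amp_db = s2_db,
                    heart_rate_bpm = hr, total_power_db = pw$power_db,
                    n_beats = nrow(paired))
  attr(out, "db_ref") <- db_ref
  attr(out, "power_ref") <- power_ref
  attr(out, "power_normalization") <- pw$normalization
  out
}

#' Full sound-window analysis chain
#'
#' Convenience wrapper running the processing chain on one heart-sound
#' window: band-pass, Hilbert envelope, peak detection, S1/S2 labeling and
#' [pcg_metrics()].
#'
#' @param record A raw sound [signal_record()].
#' @param band Band-pass edges in Hz.
#' @param db_ref,power_ref References for the dB scales.
#' @param min_separation_s,threshold_frac Peak-detection settings.
#' @param heart_rate_hint Optional heart-rate hint for labeling.
#' @return List with `metrics` (the [pcg_metrics()] row), `labeled`,
#'   `envelope` and `filtered`.
#' @export
analyze_sound_window <- function(record, band = c(25, 120), db_ref = 1,
                                 power_ref = 1e-3, min_separation_s = 0.1,
                                 threshold_frac = 0.25,
                                 heart_rate_hint = NULL) {
  filtered <- bandpass(record, band[1], band[2])
  env <- hilbert_envelope(filtered)
  peaks <- detect_sound_peaks(env, min_separation_s = min_separation_s,
                              threshold_frac = threshold_frac)
  labeled <- label_s1_s2(peaks, heart_rate_hint = heart_rate_hint)
  metrics <- pcg_metrics(filtered, labeled, db_ref = db_ref,
                         power_ref = power_ref)
  list(metrics = metrics, labeled = labeled, envelope = env,
       filtered = filtered)
}
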