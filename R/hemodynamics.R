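#' Per-beat arterial pressures for one window
#'
#' Delimits beats on the pressure channel as minimum-to-minimum cycles
#' (minima located with the same peak detector used for heart sounds, on
#' the negated trace, minimum separation 0.3 s) and reports the means
#' across beats of the per-beat maxima (SBP), minima (DBP) and time
#' averages (MAP).
#'
#' @param pressure A [signal_record()] in mmHg, at least 4 beats, sampled
#'   at >= 100 Hz.
#' @param min_separation_s Minimum beat separation for the minima
#'   detector.
#' @return A one-row data frame with `sbp_mmhg`, `dbp_mmhg`, `map_mmhg`
#'   and `n_beats`.
#' @export
beat_pressures <- function(pressure, min_separation_s = 0.3) {
  stopifnot(inherits(pressure, "signal_record"))
  if (pressure$fs < 100) stop_invalid("pressure channel must be sampled at >= 100 Hz")
  x <- pressure$samples
  rng <- diff(range(x))
  if (rng < 1) {
    stop_domain("esopcg_no_beats", "flatline pressure input: no beats detectable")
  }
  neg <- signal_record(max(x) - x, pressure$fs, unit = pressure$unit)
  troughs <- detect_sound_peaks(neg, min_separation_s = min_separation_s,
                                threshold_frac = 0.25, smooth_ms = 10)
  if (nrow(troughs) < 5L) {
    stop_domain("esopcg_no_beats", "fewer than 4 beats found on the pressure channel")
  }
  idx <- round((troughs$time_s - pressure$start_time_s) * pressure$fs) + 1L
  sbp <- dbp <- mp <- numeric(length(idx) - 1L)
  for (b in seq_len(length(idx) - 1L)) {
    seg <- x[idx[b]:(idx[b + 1L] - 1L)]
    sbp[b] <- max(seg); dbp[b] <- min(seg); mp[b] <- mean(seg)
  }
  data.frame(sbp_mmhg = mean(sbp), dbp_mmhg = mean(dbp),
             map_mmhg = mean(mp), n_beats = length(sbp))
}

#' Maximal arterial pressure upstroke slope (dP/dtmax)
#'
#' Per-beat maximum of the first difference of the (lightly smoothed)
#' pressure trace times the sampling rate, averaged across beats. Beats
#' are delimited as in [beat_pressures()]; if no beat structure is found
#' the maximum over the whole window is returned (covers analytic test
#' signals such as ramps and sinusoids).
#'
#' @param pressure A [signal_record()] in mmHg at >= 100 Hz.
#' @param smooth_ms Moving-average width applied before differencing
#'   (default 4 ms: wide enough to damp sample noise, narrow enough to
#'   leave the upstroke peak slope unattenuated at clinical rise times).
#' @return Mean per-beat dP/dtmax in mmHg/s.
#' @export
dpdt_max <- function(pressure, smooth_ms = 4) {
  stopifnot(inherits(pressure, "signal_record"))
  fs <- pressure$fs
  if (fs < 100) stop_invalid("pressure channel must be sampled at >= 100 Hz")
  if (length(pressure$samples) < fs * 0.3) {
    stop_domain("esopcg_insufficient_data", "window shorter than one beat")
  }
  sm <- moving_average(pressure$samples, round(smooth_ms / 1000 * fs))
  d <- diff(sm) * fs
  beats <- tryCatch(beat_segments(pressure), error = function(e) NULL)
  if (is.null(beats)) return(max(d))
  mean(vapply(beats, function(rg) max(d[rg[1]:min(rg[2], length(d))]), numeric(1)))
}

# beat delimitation shared by dpdt_max: sample-index ranges between minima
beat_segments <- function(pressure, min_separation_s = 0.3) {
  x <- pressure$samples
  if (diff(range(x)) < 1) stop_domain("esopcg_no_beats", "flatline input")
  neg <- signal_record(max(x) - x, pressure$fs, unit = pressure$unit)
  troughs <- detect_sound_peaks(neg, min_separation_s = min_separation_s,
                                threshold_frac = 0.25, smooth_ms = 10)
  if (nrow(troughs) < 3L) stop_domain("esopcg_no_beats", "too few beats")
  idx <- round((troughs$time_s - pressure$start_time_s) * pressure$fs) + 1L
  lapply(seq_len(length(idx) - 1L), function(b) c(idx[b], idx[b + 1L] - 1L))
}

#' Systemic vascular resistance
#'
#' The standard clinical identity `SVR = 80 * (MAP - CVP) / CO` in
#' dyne s/cm^5. CVP has no default: it must be supplied explicitly to
#' avoid a silently biased resistance.
#'
#' @param map_mmhg Mean arterial pressure (mmHg), `> cvp_mmhg`.
#' @param cvp_mmhg Central venous pressure (mmHg).
#' @param co_l_min Cardiac output (L/min, > 0).
#' @return SVR in dyne s/cm^5.
#' @export
svr <- function(map_mmhg, cvp_mmhg, co_l_min) {
  if (any(co_l_min <= 0)) stop_invalid("cardiac output must be > 0")
  if (any(map_mmhg < cvp_mmhg)) stop_invalid("MAP must be >= CVP")
  80 * (map_mmhg - cvp_mmhg) / co_l_min
}

#' Percentage change between paired values
#'
#' `(after - before) / before * 100`, the scale on which all before/after
#' comparisons are reported.
#'
#' @param before,after Numeric vectors (recycled); `before` must be
#'   nonzero.
#' @return Percentage change(s).
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) {
    stop_domain("esopcg_undefined_baseline",
                "percentage change undefined for a zero baseline")
  }
  (after - before) / before * 100
}
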