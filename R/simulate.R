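#' Cardiac-cycle parameters for the heart-sound simulator
#'
#' Describes one steady state of the phonocardiographic forward model: beat
#' timing, the two Gaussian-windowed sinusoid wavelets standing in for the
#' S1 and S2 heart sounds, RR-interval jitter and additive noise. Defaults
#' correspond to a typical intraoperative baseline: heart rate near 90 bpm,
#' S1 envelope peak at about 28 dB re 1 signal unit and S2 near 24 dB, S1
#' carrier 50 Hz with 20 ms half-width, S2 carrier 60 Hz with 15 ms
#' half-width, systole occupying 35% of the RR interval.
#'
#' @param heart_rate_bpm Heart rate, beats/min, in \[30, 200\].
#' @param s1_amp,s2_amp Linear envelope peak amplitudes (> 0, signal units).
#' @param s1_freq_hz,s2_freq_hz Wavelet carrier frequencies (Hz).
#' @param s1_width_s,s2_width_s Gaussian wavelet half-widths (s); each must
#'   be smaller than the systolic duration.
#' @param systole_fraction Fraction of the RR interval between S1 onset and
#'   S2 onset, in (0.2, 0.5).
#' @param rr_jitter_cv Coefficient of variation of RR intervals (>= 0).
#' @param noise_sd Additive white Gaussian noise SD (signal units, >= 0).
#' @return A list of class `cycle_params`.
#' @export
cycle_params <- function(heart_rate_bpm = 90,
                         s1_amp = 10^(28.1 / 20),
                         s2_amp = 10^(24.1 / 20),
                         s1_freq_hz = 50, s2_freq_hz = 60,
                         s1_width_s = 0.020, s2_width_s = 0.015,
                         systole_fraction = 0.35,
                         rr_jitter_cv = 0, noise_sd = 0) {
  if (heart_rate_bpm < 30 || heart_rate_bpm > 200) {
    stop_invalid("heart_rate_bpm must lie in [30, 200], got ", heart_rate_bpm)
  }
  if (s1_amp <= 0 || s2_amp <= 0) stop_invalid("S1/S2 amplitudes must be > 0")
  if (systole_fraction <= 0.2 || systole_fraction >= 0.5) {
    stop_invalid("systole_fraction must lie in (0.2, 0.5)")
  }
  systole_s <- systole_fraction * 60 / heart_rate_bpm
  if (s1_width_s >= systole_s || s2_width_s >= systole_s) {
    stop_invalid("wavelet half-widths must be smaller than the systolic duration (",
                 signif(systole_s, 3), " s)")
  }
  if (rr_jitter_cv < 0 || noise_sd < 0) {
    stop_invalid("rr_jitter_cv and noise_sd must be >= 0")
  }
  structure(list(heart_rate_bpm = heart_rate_bpm, s1_amp = s1_amp,
                 s2_amp = s2_amp, s1_freq_hz = s1_freq_hz,
                 s2_freq_hz = s2_freq_hz, s1_width_s = s1_width_s,
                 s2_width_s = s2_width_s, systole_fraction = systole_fraction,
                 rr_jitter_cv = rr_jitter_cv, noise_sd = noise_sd),
            class = "cycle_params")
}

#' Hemodynamic parameters for the arterial-waveform simulator
#'
#' One steady state of the arterial pulse template plus the covariates that
#' enter the vascular-resistance identity. Defaults approximate a
#' vasodilated intraoperative baseline (BP near 110/59 mmHg, CVP 10 mmHg,
#' cardiac output 7.5 L/min, giving an SVR around 700 dyne s/cm^5).
#'
#' @param sbp_mmhg,dbp_mmhg Systolic and diastolic pressure (mmHg),
#'   `sbp > dbp > 0`.
#' @param upstroke_time_s Foot-to-peak rise time (s), in (0.05, 0.3);
#'   controls dP/dtmax.
#' @param cvp_mmhg Central venous pressure (mmHg).
#' @param co_l_min Cardiac output (L/min, > 0).
#' @return A list of class `hemo_params`.
#' @export
hemo_params <- function(sbp_mmhg = 109.6, dbp_mmhg = 58.9,
                        upstroke_time_s = 0.15,
                        cvp_mmhg = 10, co_l_min = 7.5) {
  if (!(sbp_mmhg > dbp_mmhg && dbp_mmhg > 0)) {
    stop_invalid("require sbp > dbp > 0, got sbp=", sbp_mmhg, ", dbp=", dbp_mmhg)
  }
  if (upstroke_time_s <= 0.05 || upstroke_time_s >= 0.3) {
    stop_invalid("upstroke_time_s must lie in (0.05, 0.3)")
  }
  if (co_l_min <= 0) stop_invalid("co_l_min must be > 0")
  structure(list(sbp_mmhg = sbp_mmhg, dbp_mmhg = dbp_mmhg,
                 upstroke_time_s = upstroke_time_s, cvp_mmhg = cvp_mmhg,
                 co_l_min = co_l_min),
            class = "hemo_params")
}

#' Ground-truth drug effect for the episode simulator
#'
#' Parameterizes what a bolus of a cardiovascular drug does in the forward
#' model. Heart-sound gains are expressed as percentage changes of the
#' dB-scale amplitudes (the scale on which clinical percentage changes of
#' phonocardiographic amplitude are reported); heart rate and pressures
#' shift additively; SVR and dP/dtmax changes are realized through the
#' cardiac-output and upstroke-time parameters respectively; TDI S' is a
#' provided covariate whose change is drawn to match `tdis_delta_pct`.
#'
#' @param s1_db_gain_pct,s2_db_gain_pct Percentage change applied to the
#'   dB-scale S1/S2 envelope amplitudes.
#' @param hr_delta_bpm Additive heart-rate change (bpm).
#' @param sbp_delta_mmhg,dbp_delta_mmhg Additive pressure changes (mmHg).
#' @param svr_delta_pct Percentage change in systemic vascular resistance.
#' @param tdis_delta_pct,dpdt_delta_pct Ground-truth percentage changes of
#'   the contractility covariates.
#' @param covariate_r2 Population squared correlation between sound-change
#'   and covariate-change across episodes, in \[0, 1\].
#' @return A list of class `drug_effect`.
#' @export
drug_effect <- function(s1_db_gain_pct = 0, s2_db_gain_pct = 0,
                        hr_delta_bpm = 0, sbp_delta_mmhg = 0,
                        dbp_delta_mmhg = 0, svr_delta_pct = 0,
                        tdis_delta_pct = 0, dpdt_delta_pct = 0,
                        covariate_r2 = 0) {
  if (covariate_r2 < 0 || covariate_r2 > 1) {
    stop_invalid("covariate_r2 must lie in [0, 1]")
  }
  structure(list(s1_db_gain_pct = s1_db_gain_pct,
                 s2_db_gain_pct = s2_db_gain_pct,
                 hr_delta_bpm = hr_delta_bpm,
                 sbp_delta_mmhg = sbp_delta_mmhg,
                 dbp_delta_mmhg = dbp_delta_mmhg,
                 svr_delta_pct = svr_delta_pct,
                 tdis_delta_pct = tdis_delta_pct,
                 dpdt_delta_pct = dpdt_delta_pct,
                 covariate_r2 = covariate_r2),
            class = "drug_effect")
}

# add a Gaussian-windowed cosine wavelet centered at t0 into sig (in place
# semantics via return); only touches samples within +/- 5 half-widths
add_wavelet <- function(sig, t0, amp, freq, width, fs) {
  n <- length(sig)
  i_lo <- max(1L, floor((t0 - 5 * width) * fs) + 1L)
  i_hi <- min(n, ceiling((t0 + 5 * width) * fs) + 1L)
  if (i_lo > i_hi) return(sig)
  t <- (seq.int(i_lo, i_hi) - 1L) / fs - t0
  sig[i_lo:i_hi] <- sig[i_lo:i_hi] +
    amp * exp(-t^2 / (2 * width^2)) * cos(2 * pi * freq * t)
  sig
}

#' Generate a synthetic esophageal phonocardiogram
#'
#' Sums, over complete cardiac cycles, two Gaussian-windowed cosine
#' wavelets per beat — S1 shortly after cycle onset and S2 at onset plus
#' `systole_fraction * RR` — and adds white Gaussian noise. Beat onsets sit
#' at multiples of the RR interval (jittered if `rr_jitter_cv > 0`) and a
#' beat is emitted only when its full cycle fits inside `duration_s`, so at
#' zero jitter the S1 count equals `floor(duration_s / RR)`. True S1/S2
#' wavelet center times are returned in `meta` for ground-truth checks.
#'
#' @param params A [cycle_params()].
#' @param duration_s Record duration in seconds (must hold >= 2 beats).
#' @param fs Sampling rate (Hz), at least 4x the larger carrier frequency.
#' @param seed Optional integer seed; fixing it makes the record
#'   bit-reproducible.
#' @return A [signal_record()] with `meta$s1_times`, `meta$s2_times`,
#'   `meta$rr_s` and `meta$params`.
#' @export
generate_heart_sound <- function(params, duration_s, fs = 1000, seed = NULL) {
  stopifnot(inherits(params, "cycle_params"))
  if (duration_s <= 0 || fs <= 0) stop_invalid("duration_s and fs must be > 0")
  f_max <- max(params$s1_freq_hz, params$s2_freq_hz)
  if (fs < 4 * f_max) {
    stop_invalid("fs must be at least 4x the highest wavelet carrier (",
                 4 * f_max, " Hz)")
  }
  rr0 <- 60 / params$heart_rate_bpm
  if (duration_s < 2 * rr0) stop_invalid("duration_s must hold at least 2 beats")
  if (max(params$s1_width_s, params$s2_width_s) >= rr0) {
    stop_invalid("wavelet half-width must be smaller than the beat interval")
  }
  with_seed(seed, {
    # beat onsets: cumulative jittered RR, full cycles only
    onsets <- numeric(0); rr_s <- numeric(0)
    t0 <- 0
    repeat {
      rr <- if (params$rr_jitter_cv > 0) {
        rr0 * max(0.2, 1 + params$rr_jitter_cv * stats::rnorm(1))
      } else rr0
      if (t0 + rr > duration_s + 1e-9) break
      onsets <- c(onsets, t0); rr_s <- c(rr_s, rr)
      t0 <- t0 + rr
    }
    n <- round(duration_s * fs)
    sig <- numeric(n)
    s1_times <- onsets + 2.5 * params$s1_width_s
    s2_times <- s1_times + params$systole_fraction * rr_s
    for (k in seq_along(onsets)) {
      sig <- add_wavelet(sig, s1_times[k], params$s1_amp,
                         params$s1_freq_hz, params$s1_width_s, fs)
      sig <- add_wavelet(sig, s2_times[k], params$s2_amp,
                         params$s2_freq_hz, params$s2_width_s, fs)
    }
    if (params$noise_sd > 0) sig <- sig + stats::rnorm(n, sd = params$noise_sd)
    signal_record(sig, fs, unit = "au",
                  meta = list(s1_times = s1_times, s2_times = s2_times,
                              rr_s = rr_s, params = params))
  })
}

# arterial pulse template constants: exponential diastolic decay constant
# (fraction of diastole), dicrotic bump amplitude (fraction of pulse
# pressure), bump width (s) and position (fraction of diastole after peak)
.art_tau_frac <- 1 / 3
.art_dicrotic_amp <- 0.03
.art_dicrotic_width <- 0.02
.art_dicrotic_pos <- 0.25

# evaluate one beat of the pressure template at phase times t in [0, T)
arterial_beat <- function(t, hemo, period) {
  tu <- hemo$upstroke_time_s
  td <- period - tu
  pp <- hemo$sbp_mmhg - hemo$dbp_mmhg
  tau <- .art_tau_frac * td
  e_end <- exp(-td / tau)
  p <- numeric(length(t))
  rise <- t < tu
  p[rise] <- (1 - cos(pi * t[rise] / tu)) / 2
  s <- t[!rise] - tu
  p[!rise] <- (exp(-s / tau) - e_end) / (1 - e_end) +
    .art_dicrotic_amp *
      exp(-(s - .art_dicrotic_pos * td)^2 / (2 * .art_dicrotic_width^2))
  hemo$dbp_mmhg + pp * p
}

#' Generate a synthetic arterial pressure waveform
#'
#' Periodic pulse template: a half-cosine upstroke from DBP to SBP over
#' `upstroke_time_s`, then an exponential diastolic decay (normalized to
#' reach DBP exactly at cycle end) carrying a small Gaussian dicrotic
#' inflection. Per-beat maxima equal SBP and minima DBP by construction,
#' and the template mean over an integer number of beats is available in
#' closed form via [arterial_template_map()].
#'
#' @param hemo A [hemo_params()].
#' @param heart_rate_bpm Heart rate (bpm).
#' @param duration_s Record duration (s).
#' @param fs Sampling rate (Hz).
#' @param seed Optional seed (used only when `noise_sd > 0`).
#' @param noise_sd Additive Gaussian noise SD (mmHg); default noiseless.
#' @return A [signal_record()] in mmHg with the template parameters in
#'   `meta`.
#' @export
generate_arterial_waveform <- function(hemo, heart_rate_bpm, duration_s,
                                       fs = 1000, seed = NULL, noise_sd = 0) {
  stopifnot(inherits(hemo, "hemo_params"))
  if (duration_s <= 0 || fs <= 0) stop_invalid("duration_s and fs must be > 0")
  period <- 60 / heart_rate_bpm
  if (hemo$upstroke_time_s >= period) {
    stop_invalid("upstroke_time_s must be shorter than the beat period")
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  phase <- t %% period
  p <- arterial_beat(phase, hemo, period)
  with_seed(seed, {
    if (noise_sd > 0) p <- p + stats::rnorm(n, sd = noise_sd)
    signal_record(p, fs, unit = "mmHg",
                  meta = list(hemo = hemo, heart_rate_bpm = heart_rate_bpm))
  })
}

#' Closed-form mean of the arterial pulse template
#'
#' Time average of one beat of the template used by
#' [generate_arterial_waveform()]; the simulator's ground-truth mean
#' arterial pressure.
#'
#' @param hemo A [hemo_params()].
#' @param heart_rate_bpm Heart rate (bpm).
#' @return Mean arterial pressure (mmHg).
#' @export
arterial_template_map <- function(hemo, heart_rate_bpm) {
  stopifnot(inherits(hemo, "hemo_params"))
  period <- 60 / heart_rate_bpm
  tu <- hemo$upstroke_time_s
  td <- period - tu
  pp <- hemo$sbp_mmhg - hemo$dbp_mmhg
  tau <- .art_tau_frac * td
  e_end <- exp(-td / tau)
  i_rise <- tu / 2
  i_decay <- (tau * (1 - e_end) - td * e_end) / (1 - e_end)
  i_bump <- .art_dicrotic_amp * .art_dicrotic_width * sqrt(2 * pi)
  hemo$dbp_mmhg + pp * (i_rise + i_decay + i_bump) / period
}

#' Ground-truth dP/dtmax of the arterial template
#'
#' Peak slope of the half-cosine upstroke,
#' `pi * (SBP - DBP) / (2 * upstroke_time_s)`.
#'
#' @param hemo A [hemo_params()].
#' @return dP/dtmax in mmHg/s.
#' @export
arterial_template_dpdt <- function(hemo) {
  stopifnot(inherits(hemo, "hemo_params"))
  pi * (hemo$sbp_mmhg - hemo$dbp_mmhg) / (2 * hemo$upstroke_time_s)
}

#' Apply a drug effect to a pre-drug parameter state
#'
#' Produces the post-drug cycle and hemodynamic parameters. S1/S2 envelope
#' amplitudes change on the dB scale: the post dB amplitude is
#' `(1 + gain_pct/100)` times the pre dB amplitude (relative to `db_ref`),
#' matching how clinical percentage changes of phonocardiographic
#' amplitude are computed. Heart rate and pressures shift additively. The
#' dP/dtmax change is realized by rescaling the upstroke time (accounting
#' for any pulse-pressure change), and the SVR change by adjusting cardiac
#' output so that `80 * (MAP - CVP) / CO` moves by exactly
#' `svr_delta_pct` percent, with MAP taken from the template closed form.
#'
#' @param cycle Pre-drug [cycle_params()].
#' @param hemo Pre-drug [hemo_params()].
#' @param effect A [drug_effect()].
#' @param db_ref Reference amplitude for the dB scale (default 1).
#' @return List with elements `cycle` and `hemo` (post-drug states).
#' @export
apply_drug_effect <- function(cycle, hemo, effect, db_ref = 1) {
  stopifnot(inherits(cycle, "cycle_params"), inherits(hemo, "hemo_params"),
            inherits(effect, "drug_effect"))
  gain_db <- function(amp, pct, label) {
    if (pct == 0) return(amp)
    if (1 + pct / 100 <= 0) {
      stop_invalid(label, " dB gain of ", pct, "% drives the amplitude through zero")
    }
    db <- 20 * log10(amp / db_ref)
    if (db <= 0) {
      stop_invalid(label, " pre-drug amplitude is at or below db_ref; a ",
                   "percentage dB gain is undefined")
    }
    db_ref * 10^(db * (1 + pct / 100) / 20)
  }
  s1 <- gain_db(cycle$s1_amp, effect$s1_db_gain_pct, "S1")
  s2 <- gain_db(cycle$s2_amp, effect$s2_db_gain_pct, "S2")
  hr <- cycle$heart_rate_bpm + effect$hr_delta_bpm
  cycle_post <- cycle_params(heart_rate_bpm = hr, s1_amp = s1, s2_amp = s2,
                             s1_freq_hz = cycle$s1_freq_hz,
                             s2_freq_hz = cycle$s2_freq_hz,
                             s1_width_s = cycle$s1_width_s,
                             s2_width_s = cycle$s2_width_s,
                             systole_fraction = cycle$systole_fraction,
                             rr_jitter_cv = cycle$rr_jitter_cv,
                             noise_sd = cycle$noise_sd)
  sbp <- hemo$sbp_mmhg + effect$sbp_delta_mmhg
  dbp <- hemo$dbp_mmhg + effect$dbp_delta_mmhg
  pp_ratio <- (sbp - dbp) / (hemo$sbp_mmhg - hemo$dbp_mmhg)
  tu <- hemo$upstroke_time_s * pp_ratio / (1 + effect$dpdt_delta_pct / 100)
  hemo_post <- hemo_params(sbp_mmhg = sbp, dbp_mmhg = dbp,
                           upstroke_time_s = tu, cvp_mmhg = hemo$cvp_mmhg,
                           co_l_min = hemo$co_l_min)
  # adjust CO so SVR = 80*(MAP - CVP)/CO moves by exactly svr_delta_pct
  svr_pre <- svr(arterial_template_map(hemo, cycle$heart_rate_bpm),
                 hemo$cvp_mmhg, hemo$co_l_min)
  svr_target <- svr_pre * (1 + effect$svr_delta_pct / 100)
  map_post <- arterial_template_map(hemo_post, hr)
  hemo_post$co_l_min <- 80 * (map_post - hemo_post$cvp_mmhg) / svr_target
  list(cycle = cycle_post, hemo = hemo_post)
}

#' Generate a paired pre/post drug episode
#'
#' Builds one complete synthetic episode: 20-s (by default) pre- and
#' post-drug heart-sound and arterial-pressure windows, the ground-truth
#' parameter states, and the per-window hemodynamic covariates (TDI S',
#' template dP/dtmax, CVP, CO). Covariate post values are set so their
#' percentage changes equal the effect's ground truth exactly.
#'
#' @param cycle Pre-drug [cycle_params()].
#' @param hemo Pre-drug [hemo_params()].
#' @param effect A [drug_effect()].
#' @param seed Integer seed; sub-seeds `seed..seed+3` drive the four
#'   generated records.
#' @param fs Sampling rate (Hz), default 1000.
#' @param window_s Window length (s), default 20.
#' @param tdis_cm_s Pre-drug TDI S' covariate value (cm/s).
#' @param event_time_s Nominal drug timestamp within the notional full
#'   record (the windows are cut 2 min either side of it).
#' @param db_ref Reference amplitude for the dB gain arithmetic.
#' @return An object of class `pcg_episode` with fields `pre_sound`,
#'   `post_sound`, `pre_pressure`, `post_pressure`, `event_time_s`,
#'   `truth` and `covariates`.
#' @export
generate_episode <- function(cycle = cycle_params(), hemo = hemo_params(),
                             effect = drug_effect(), seed = NULL,
                             fs = 1000, window_s = 20, tdis_cm_s = 9.7,
                             event_time_s = 300, db_ref = 1) {
  post <- apply_drug_effect(cycle, hemo, effect, db_ref = db_ref)
  seeds <- if (is.null(seed)) rep(list(NULL), 4) else as.list(seed + 0:3)
  pre_sound <- generate_heart_sound(cycle, window_s, fs, seed = seeds[[1]])
  post_sound <- generate_heart_sound(post$cycle, window_s, fs, seed = seeds[[2]])
  pre_pressure <- generate_arterial_waveform(hemo, cycle$heart_rate_bpm,
                                             window_s, fs, seed = seeds[[3]])
  post_pressure <- generate_arterial_waveform(post$hemo,
                                              post$cycle$heart_rate_bpm,
                                              window_s, fs, seed = seeds[[4]])
  covariates <- data.frame(
    window = c("pre", "post"),
    tdis_cm_s = c(tdis_cm_s, tdis_cm_s * (1 + effect$tdis_delta_pct / 100)),
    dpdt_mmhg_s = c(arterial_template_dpdt(hemo),
                    arterial_template_dpdt(post$hemo)),
    cvp_mmhg = c(hemo$cvp_mmhg, post$hemo$cvp_mmhg),
    co_l_min = c(hemo$co_l_min, post$hemo$co_l_min),
    stringsAsFactors = FALSE
  )
  structure(list(pre_sound = pre_sound, post_sound = post_sound,
                 pre_pressure = pre_pressure, post_pressure = post_pressure,
                 event_time_s = event_time_s,
                 truth = list(effect = effect,
                              pre = list(cycle = cycle, hemo = hemo),
                              post = post),
                 covariates = covariates),
            class = "pcg_episode")
}

#' @export
print.pcg_episode <- function(x, ...) {
  cat(sprintf("<pcg_episode> %g-s pre/post windows @ %g Hz; S1 gain %+g%%, S2 gain %+g%%\n",
              record_duration(x$pre_sound), x$pre_sound$fs,
              x$truth$effect$s1_db_gain_pct, x$truth$effect$s2_db_gain_pct))
  invisible(x)
}

#' Sample correlated sound-change / covariate-change pairs
#'
#' Draws `n` episodes' worth of (sound percentage change, covariate
#' percentage change) pairs from a bivariate Gaussian whose means are the
#' effect's ground-truth percentage changes and whose population squared
#' correlation equals `effect$covariate_r2` (positive correlation root).
#' Construction: `x = mx + sx*z1`, `y = my + sy*(r*z1 + sqrt(1-r^2)*z2)`
#' with independent standard normal `z1`, `z2`, so the degenerate
#' `covariate_r2 = 1` case is exactly linear.
#'
#' @param effect A [drug_effect()].
#' @param n Number of pairs (>= 3).
#' @param seed Optional integer seed.
#' @param covariate Which covariate mean to use: `"tdis"` or `"dpdt"`.
#' @param sd_sound,sd_covariate Marginal SDs of the two percentage-change
#'   series (defaults 5 and 8, the scale of the between-episode spread seen
#'   clinically).
#' @return A data frame with columns `sound_pct_change` and
#'   `covariate_pct_change`.
#' @export
sample_covariate_pairs <- function(effect, n, seed = NULL,
                                   covariate = c("tdis", "dpdt"),
                                   sd_sound = 5, sd_covariate = 8) {
  stopifnot(inherits(effect, "drug_effect"))
  covariate <- match.arg(covariate)
  if (n < 3) stop_invalid("n must be >= 3")
  r2 <- effect$covariate_r2
  if (r2 < 0 || r2 > 1) stop_invalid("covariate_r2 must lie in [0, 1]")
  r <- sqrt(r2)
  mx <- effect$s1_db_gain_pct
  my <- if (covariate == "tdis") effect$tdis_delta_pct else effect$dpdt_delta_pct
  with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    data.frame(sound_pct_change = mx + sd_sound * z1,
               covariate_pct_change = my + sd_covariate * (r * z1 + sqrt(1 - r2) * z2))
  })
}

#' Preset drug-effect study conditions
#'
#' Baseline states and effect sizes for the four vasoactive drugs as
#' observed clinically with an esophageal phonocardiogram during liver
#' transplantation: ephedrine (positive inotrope; S1 dB up 12.7%, dP/dt up
#' 45.7%), esmolol (negative inotrope; S1 down 15.3%), phenylephrine
#' (vasoconstrictor; S2 up 5.5%, SVR up 13.3%) and nicardipine
#' (vasodilator; S2 down 14.2%, SVR down 43.5%). Baselines use the
#' corresponding group means (S1/S2 dB amplitudes, heart rate, blood
#' pressure); the nicardipine baseline, for which no group statistics were
#' reported, uses its representative tracing (166/86 mmHg) with typical
#' amplitudes.
#'
#' @param drug One of `"ephedrine"`, `"esmolol"`, `"phenylephrine"`,
#'   `"nicardipine"`.
#' @return List with `cycle` ([cycle_params()]), `hemo` ([hemo_params()]),
#'   `effect` ([drug_effect()]) and `n` (the typical group size).
#' @export
drug_preset <- function(drug = c("ephedrine", "esmolol", "phenylephrine",
                                 "nicardipine")) {
  drug <- match.arg(drug)
  switch(drug,
    ephedrine = list(
      cycle = cycle_params(heart_rate_bpm = 92.9, s1_amp = 10^(28.1 / 20),
                           s2_amp = 10^(24.1 / 20)),
      hemo = hemo_params(sbp_mmhg = 109.6, dbp_mmhg = 58.9),
      effect = drug_effect(s1_db_gain_pct = 12.7, s2_db_gain_pct = 9.1,
                           hr_delta_bpm = -0.3, sbp_delta_mmhg = 29.7,
                           dbp_delta_mmhg = 15.6, svr_delta_pct = 30.9,
                           tdis_delta_pct = 18.0, dpdt_delta_pct = 45.7,
                           covariate_r2 = 0.612),
      n = 9L),
    esmolol = list(
      cycle = cycle_params(heart_rate_bpm = 99.0, s1_amp = 10^(33.2 / 20),
                           s2_amp = 10^(25.5 / 20)),
      hemo = hemo_params(sbp_mmhg = 136.1, dbp_mmhg = 71.1),
      effect = drug_effect(s1_db_gain_pct = -15.3, s2_db_gain_pct = 3.5,
                           hr_delta_bpm = 0.3, sbp_delta_mmhg = -11.7,
                           dbp_delta_mmhg = -3.5, svr_delta_pct = -3.7,
                           tdis_delta_pct = -20.5, dpdt_delta_pct = -23.6,
                           covariate_r2 = 0.612),
      n = 11L),
    phenylephrine = list(
      cycle = cycle_params(heart_rate_bpm = 108.3, s1_amp = 10^(29.1 / 20),
                           s2_amp = 10^(21.9 / 20)),
      hemo = hemo_params(sbp_mmhg = 93.7, dbp_mmhg = 52.8),
      effect = drug_effect(s1_db_gain_pct = 0, s2_db_gain_pct = 5.5,
                           hr_delta_bpm = 0.5, sbp_delta_mmhg = 17.8,
                           dbp_delta_mmhg = 10.3, svr_delta_pct = 13.3,
                           tdis_delta_pct = -5.6, dpdt_delta_pct = 26.5,
                           covariate_r2 = 0.285),
      n = 7L),
    nicardipine = list(
      cycle = cycle_params(heart_rate_bpm = 85, s1_amp = 10^(29 / 20),
                           s2_amp = 10^(25 / 20)),
      hemo = hemo_params(sbp_mmhg = 166, dbp_mmhg = 86),
      effect = drug_effect(s1_db_gain_pct = 0, s2_db_gain_pct = -14.2,
                           hr_delta_bpm = 0, sbp_delta_mmhg = -61,
                           dbp_delta_mmhg = -38, svr_delta_pct = -43.5,
                           tdis_delta_pct = 0, dpdt_delta_pct = 0,
                           covariate_r2 = 0),
      n = 2L)
  )
}

#' Simulate a batch of episodes for one drug group
#'
#' Generates `n` noiseless episodes under a drug's preset effect, with
#' mild between-episode variation of the baseline (heart rate SD 4 bpm,
#' S1/S2 amplitude SD 1 dB, pressure level SD 4 mmHg, upstroke time SD
#' 10 ms) so group statistics are non-degenerate while each episode's
#' ground truth stays exact.
#'
#' @param drug Passed to [drug_preset()].
#' @param n Number of episodes (default: the preset's group size).
#' @param seed Integer seed controlling both the baseline variation and
#'   the per-episode generator seeds.
#' @param ... Passed on to [generate_episode()].
#' @return List with `episodes` (list of `pcg_episode`) and `drug`.
#' @export
simulate_drug_batch <- function(drug, n = NULL, seed = 1, ...) {
  preset <- drug_preset(drug)
  if (is.null(n)) n <- preset$n
  with_seed(seed, {
    hr_dev <- stats::rnorm(n, sd = 4)
    s1_dev <- stats::rnorm(n, sd = 1)    # dB
    s2_dev <- stats::rnorm(n, sd = 1)
    bp_dev <- stats::rnorm(n, sd = 4)
    tu_dev <- stats::rnorm(n, sd = 0.01)
    ep_seeds <- sample.int(2^20, n) * 100
    episodes <- lapply(seq_len(n), function(i) {
      cyc <- preset$cycle
      cyc <- cycle_params(heart_rate_bpm = cyc$heart_rate_bpm + hr_dev[i],
                          s1_amp = cyc$s1_amp * 10^(s1_dev[i] / 20),
                          s2_amp = cyc$s2_amp * 10^(s2_dev[i] / 20),
                          s1_freq_hz = cyc$s1_freq_hz,
                          s2_freq_hz = cyc$s2_freq_hz,
                          s1_width_s = cyc$s1_width_s,
                          s2_width_s = cyc$s2_width_s,
                          systole_fraction = cyc$systole_fraction,
                          rr_jitter_cv = cyc$rr_jitter_cv,
                          noise_sd = cyc$noise_sd)
      hm <- preset$hemo
      hm <- hemo_params(sbp_mmhg = hm$sbp_mmhg + bp_dev[i],
                        dbp_mmhg = hm$dbp_mmhg + bp_dev[i],
                        upstroke_time_s = hm$upstroke_time_s + tu_dev[i],
                        cvp_mmhg = hm$cvp_mmhg, co_l_min = hm$co_l_min)
      generate_episode(cyc, hm, preset$effect, seed = ep_seeds[i], ...)
    })
    list(episodes = episodes, drug = drug)
  })
}
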