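make_tone <- function(f, fs = 1000, dur = 5, amp = 1) {
  signal_record(amp * sin(2 * pi * f * (0:(dur * fs - 1)) / fs), fs)
}

central <- function(x, frac = 0.9) {
  n <- length(x)
  drop <- floor(n * (1 - frac) / 2)
  x[(drop + 1):(n - drop)]
}

test_that("band-pass keeps in-band tones and removes drift", {
  tone50 <- make_tone(50)
  out <- bandpass(tone50, 25, 120)
  expect_lt(max(abs(central(out$samples) - central(tone50$samples))), 0.01)
  drift <- make_tone(1)
  expect_lt(max(abs(central(bandpass(drift, 25, 120)$samples))), 0.01)
  zero <- signal_record(rep(0, 1000), 1000)
  expect_equal(bandpass(zero, 25, 120)$samples, rep(0, 1000))
  expect_error(bandpass(tone50, 120, 25), class = "esopcg_invalid_argument")
  expect_error(bandpass(tone50, 25, 600), class = "esopcg_invalid_argument")
})

test_that("Hilbert envelope recovers tone amplitude and tracks slow modulation", {
  tone <- make_tone(50, amp = 2)
  env <- hilbert_envelope(tone)
  expect_true(all(abs(central(env$samples) - 2) < 0.02))
  # slowly varying non-negative modulation is tracked within 2% centrally
  fs <- 1000; t <- (0:(5 * fs - 1)) / fs
  a_t <- 1 + 0.5 * sin(2 * pi * 1 * t)
  mod <- signal_record(a_t * sin(2 * pi * 50 * t), fs)
  env_m <- hilbert_envelope(mod)$samples
  expect_true(all(abs(central(env_m) - central(a_t)) < 0.02 * max(a_t)))
  zero <- signal_record(rep(0, 64), 1000)
  expect_equal(hilbert_envelope(zero)$samples, rep(0, 64))
  bad <- signal_record(rep(1, 64), 1000); bad$samples[3] <- NaN
  expect_error(hilbert_envelope(bad), class = "esopcg_invalid_argument")
})

test_that("envelope dominates the signal pointwise", {
  rec <- generate_heart_sound(cycle_params(), 10)
  env <- hilbert_envelope(rec)
  expect_true(all(env$samples >= 0))
  expect_true(all(env$samples - abs(rec$samples) > -1e-9))
})

test_that("peak detection counts wavelets and applies the separation rule", {
  rec <- generate_heart_sound(cycle_params(heart_rate_bpm = 73), 20)
  env <- hilbert_envelope(bandpass(rec, 25, 120))
  peaks <- detect_sound_peaks(env)
  expect_identical(nrow(peaks), 48L)   # 24 S1 + 24 S2 by construction
  # constant envelope: no local maxima, no peaks
  flat <- signal_record(rep(2, 2000), 1000)
  expect_identical(nrow(detect_sound_peaks(flat)), 0L)
  # two wavelets 50 ms apart under a 0.2-s separation: keep the larger
  fs <- 1000; sig <- numeric(2000)
  t <- (0:1999) / fs
  sig <- 1.0 * exp(-(t - 0.50)^2 / (2 * 0.01^2)) +
         0.6 * exp(-(t - 0.55)^2 / (2 * 0.01^2))
  pk <- detect_sound_peaks(signal_record(sig, fs), min_separation_s = 0.2)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$time_s, 0.50, tolerance = 0.01)
  # equal heights within one separation window: the earlier peak wins
  sig2 <- exp(-(t - 0.50)^2 / (2 * 0.01^2)) + exp(-(t - 0.55)^2 / (2 * 0.01^2))
  pk2 <- detect_sound_peaks(signal_record(sig2, fs), min_separation_s = 0.2)
  expect_identical(nrow(pk2), 1L)
  expect_lt(pk2$time_s, 0.525)
})

test_that("S1/S2 labeling matches simulator ground truth on noiseless windows", {
  for (hr in c(50, 90, 120)) {
    for (sf in c(0.3, 0.4)) {
      rec <- generate_heart_sound(
        cycle_params(heart_rate_bpm = hr, systole_fraction = sf), 20)
      res <- analyze_sound_window(rec)
      truth <- rec$meta
      got <- res$labeled$beats
      expect_identical(nrow(got), length(truth$s1_times),
                       info = paste("HR", hr, "sf", sf))
      expect_true(all(abs(got$s1_time_s - truth$s1_times) < 0.02))
      expect_true(all(abs(got$s2_time_s - truth$s2_times) < 0.02))
      expect_identical(res$labeled$unpaired_peaks, 0L)
    }
  }
})

test_that("a spurious mid-diastolic peak is left unpaired without losing beats", {
  rec <- generate_heart_sound(cycle_params(heart_rate_bpm = 73), 20)
  env <- hilbert_envelope(bandpass(rec, 25, 120))
  peaks <- detect_sound_peaks(env)
  # inject a fake peak halfway through one diastole
  fake_t <- rec$meta$s2_times[10] + 0.5 * (rec$meta$s1_times[11] - rec$meta$s2_times[10])
  peaks <- rbind(peaks, data.frame(time_s = fake_t, amplitude = 5))
  peaks <- peaks[order(peaks$time_s), ]
  lab <- label_s1_s2(peaks)
  expect_identical(lab$unpaired_peaks, 1L)
  expect_identical(nrow(lab$beats), length(rec$meta$s1_times))
  expect_true(all(abs(lab$beats$s1_time_s - rec$meta$s1_times) < 0.02))
})

test_that("labeling rejects rhythms without a systole/diastole contrast", {
  # equal gaps: alternation is undecidable
  peaks <- data.frame(time_s = seq(0, 4, by = 0.4), amplitude = 1)
  expect_error(label_s1_s2(peaks), class = "esopcg_ambiguous_rhythm")
  expect_error(label_s1_s2(peaks[1:3, ]), class = "esopcg_invalid_argument")
})

test_that("labeling stays reliable at 20 dB SNR", {
  agree <- 0L; total <- 0L
  for (s in 1:5) {
    clean <- generate_heart_sound(cycle_params(heart_rate_bpm = 90), 20)
    noisy_params <- cycle_params(heart_rate_bpm = 90,
                                 noise_sd = noise_sd_for_snr(clean, 20))
    rec <- generate_heart_sound(noisy_params, 20, seed = 100 + s)
    res <- tryCatch(analyze_sound_window(rec), error = function(e) NULL)
    truth <- rec$meta$s1_times
    total <- total + length(truth)
    if (!is.null(res)) {
      agree <- agree + sum(vapply(truth, function(tt) {
        any(abs(res$labeled$beats$s1_time_s - tt) < 0.03)
      }, logical(1)))
    }
  }
  expect_gte(agree / total, 0.95)
})

test_that("amplitude and heart-rate metrics follow their defining arithmetic", {
  rec <- generate_heart_sound(cycle_params(), 20)
  filt <- bandpass(rec, 25, 120)
  lab <- make_labeled(s1_times = cumsum(rep(60 / 73, 10)),
                      s1_amps = rep(10, 10),
                      s2_times = cumsum(rep(60 / 73, 10)) + 0.25,
                      s2_amps = rep(5, 10))
  m <- pcg_metrics(filt, lab)
  expect_equal(m$s1_amp_db, 20)          # 20*log10(10/1)
  expect_equal(m$heart_rate_bpm, 73)
  # fewer than 4 paired beats is an error
  lab2 <- make_labeled(c(1, 2, 3), rep(1, 3), c(1.3, 2.3, 3.3), rep(1, 3))
  expect_error(pcg_metrics(filt, lab2), class = "esopcg_insufficient_beats")
})

test_that("dB metrics are exactly gain-equivariant", {
  rec <- generate_heart_sound(cycle_params(), 20)
  g <- 2
  scaled <- signal_record(g * rec$samples, rec$fs, meta = rec$meta)
  m1 <- analyze_sound_window(rec)$metrics
  m2 <- analyze_sound_window(scaled)$metrics
  expect_equal(m2$s1_amp_db - m1$s1_amp_db, 20 * log10(g), tolerance = 1e-9)
  expect_equal(m2$s2_amp_db - m1$s2_amp_db, 20 * log10(g), tolerance = 1e-9)
  expect_equal(m2$total_power_db - m1$total_power_db, 10 * log10(g^2),
               tolerance = 1e-9)
})

test_that("rectangular-window total power satisfies Parseval", {
  set.seed(5)
  x <- signal_record(rnorm(4096), 1000)
  p <- spectral_power(x, window = "rectangular", power_ref = 1)
  expect_equal(p$power, mean(x$samples^2), tolerance = 1e-6)
  # the Hamming estimate stays within a fraction of a dB of it for noise
  ph <- spectral_power(x, window = "hamming", power_ref = 1)
  expect_lt(abs(ph$power_db - p$power_db), 1)
})
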