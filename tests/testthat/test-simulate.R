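test_that("beat count matches independent enumeration of onsets at zero jitter", {
  # oracle: beats at k*RR with the full cycle required to fit
  enumerate_beats <- function(hr, duration) {
    rr <- 60 / hr
    k <- 0L; t0 <- 0
    while (t0 + rr <= duration + 1e-9) { k <- k + 1L; t0 <- t0 + rr }
    k
  }
  for (hr in c(50, 73, 92.9, 120)) {
    rec <- generate_heart_sound(cycle_params(heart_rate_bpm = hr), 20)
    expect_equal(length(rec$meta$s1_times), enumerate_beats(hr, 20),
                 info = paste("HR", hr))
    expect_equal(length(rec$meta$s2_times), length(rec$meta$s1_times))
  }
  # the derived case: 73 bpm over 20 s gives floor(20 / (60/73)) = 24 beats
  rec73 <- generate_heart_sound(cycle_params(heart_rate_bpm = 73), 20)
  expect_identical(length(rec73$meta$s1_times), 24L)
})

test_that("noiseless construction places unit-amplitude S1 wavelets at their centers", {
  p <- cycle_params(heart_rate_bpm = 60, s1_amp = 1, s2_amp = 0.5)
  rec <- generate_heart_sound(p, 2, fs = 1000)
  expect_identical(length(rec$meta$s1_times), 2L)
  expect_identical(length(rec$meta$s2_times), 2L)
  at_centers <- rec$samples[round(rec$meta$s1_times * rec$fs) + 1L]
  expect_equal(at_centers, c(1, 1), tolerance = 1e-6)
  expect_lte(max(abs(rec$samples)), 1 + 1e-6)
})

test_that("generators are bit-deterministic under a fixed seed", {
  p <- cycle_params(rr_jitter_cv = 0.05, noise_sd = 0.3)
  expect_identical(generate_heart_sound(p, 10, seed = 7)$samples,
                   generate_heart_sound(p, 10, seed = 7)$samples)
  hm <- hemo_params()
  expect_identical(generate_arterial_waveform(hm, 90, 10, seed = 7, noise_sd = 1)$samples,
                   generate_arterial_waveform(hm, 90, 10, seed = 7, noise_sd = 1)$samples)
  e1 <- generate_episode(seed = 11)
  e2 <- generate_episode(seed = 11)
  expect_identical(e1$pre_sound$samples, e2$pre_sound$samples)
  expect_identical(e1$post_pressure$samples, e2$post_pressure$samples)
})

test_that("noiseless RMS is strictly increasing in the S1 amplitude", {
  rms <- vapply(c(0.5, 1, 2, 4), function(a) {
    sqrt(mean(generate_heart_sound(cycle_params(s1_amp = a), 10)$samples^2))
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("arterial template hits configured SBP/DBP and stays in range", {
  hm <- hemo_params(sbp_mmhg = 127, dbp_mmhg = 88, upstroke_time_s = 0.12)
  w <- generate_arterial_waveform(hm, 108, 20)
  expect_equal(max(w$samples), 127, tolerance = 0.5)
  expect_equal(min(w$samples), 88, tolerance = 0.5)
  # single full beat, noiseless: everywhere within [dbp, sbp]
  one <- generate_arterial_waveform(hm, 60, 1)
  expect_true(all(one$samples >= 88 - 1e-6 & one$samples <= 127 + 1e-6))
})

test_that("halving the upstroke time doubles dP/dtmax at fixed pulse pressure", {
  hm1 <- hemo_params(upstroke_time_s = 0.2)
  hm2 <- hemo_params(upstroke_time_s = 0.1)
  # closed form is exact
  expect_equal(arterial_template_dpdt(hm2) / arterial_template_dpdt(hm1), 2)
  # measured from the sampled waveform within 5%
  d1 <- dpdt_max(generate_arterial_waveform(hm1, 80, 15))
  d2 <- dpdt_max(generate_arterial_waveform(hm2, 80, 15))
  expect_equal(d2 / d1, 2, tolerance = 0.05)
})

test_that("drug-effect arithmetic acts on the dB scale", {
  cyc <- cycle_params()
  hm <- hemo_params()
  # identity: all-zero effect leaves every parameter untouched
  post0 <- apply_drug_effect(cyc, hm, drug_effect())
  expect_equal(unclass(post0$cycle), unclass(cyc))
  expect_equal(unclass(post0$hemo), unclass(hm))
  # +12.8% on 28.1 dB lands at 31.7 dB
  pre <- cycle_params(s1_amp = 10^(28.1 / 20))
  post <- apply_drug_effect(pre, hm, drug_effect(s1_db_gain_pct = 12.8))
  expect_equal(20 * log10(post$cycle$s1_amp), 31.7, tolerance = 0.05)
  # -15.3% on 33.2 dB lands at 28.1 dB
  pre2 <- cycle_params(s1_amp = 10^(33.2 / 20))
  post2 <- apply_drug_effect(pre2, hm, drug_effect(s1_db_gain_pct = -15.3))
  expect_equal(20 * log10(post2$cycle$s1_amp), 28.1, tolerance = 0.1)
  # a gain through zero or an undefined baseline is rejected
  expect_error(apply_drug_effect(pre, hm, drug_effect(s1_db_gain_pct = -120)),
               class = "esopcg_invalid_argument")
  expect_error(apply_drug_effect(cycle_params(s1_amp = 0.5), hm,
                                 drug_effect(s1_db_gain_pct = 10)),
               class = "esopcg_invalid_argument")
})

test_that("a null effect gives a null episode and covariates carry the truth", {
  ep <- generate_episode(effect = drug_effect(), seed = 3)
  expect_identical(ep$pre_sound$meta$params, ep$post_sound$meta$params)
  cov <- ep$covariates
  expect_equal(cov$tdis_cm_s[1], cov$tdis_cm_s[2])
  expect_equal(cov$dpdt_mmhg_s[1], cov$dpdt_mmhg_s[2])
  # non-null: covariate percentage changes equal the configured ground truth
  eff <- drug_effect(tdis_delta_pct = 18, dpdt_delta_pct = 45.7,
                     svr_delta_pct = 30.9)
  ep2 <- generate_episode(effect = eff, seed = 3)
  expect_equal(percent_change(ep2$covariates$tdis_cm_s[1],
                              ep2$covariates$tdis_cm_s[2]), 18)
  expect_equal(percent_change(ep2$covariates$dpdt_mmhg_s[1],
                              ep2$covariates$dpdt_mmhg_s[2]), 45.7)
})

test_that("covariate pair sampler honors its population correlation", {
  eff1 <- drug_effect(s1_db_gain_pct = 12.7, tdis_delta_pct = 18,
                      covariate_r2 = 1)
  d1 <- sample_covariate_pairs(eff1, 50, seed = 1)
  expect_equal(correlate_changes(d1$sound_pct_change,
                                 d1$covariate_pct_change)$r2, 1,
               tolerance = 1e-9)
  eff0 <- drug_effect(covariate_r2 = 0)
  d0 <- sample_covariate_pairs(eff0, 1e5, seed = 1)
  expect_lt(correlate_changes(d0$sound_pct_change,
                              d0$covariate_pct_change)$r2, 0.01)
  bad <- drug_effect(); bad$covariate_r2 <- 1.5
  expect_error(sample_covariate_pairs(bad, 10, seed = 1),
               class = "esopcg_invalid_argument")
  expect_error(sample_covariate_pairs(eff0, 2, seed = 1),
               class = "esopcg_invalid_argument")
})

test_that("parameter constructors enforce physiologic invariants", {
  expect_error(cycle_params(heart_rate_bpm = 250), class = "esopcg_invalid_argument")
  expect_error(cycle_params(systole_fraction = 0.6), class = "esopcg_invalid_argument")
  expect_error(cycle_params(s1_width_s = 0.5), class = "esopcg_invalid_argument")
  expect_error(hemo_params(sbp_mmhg = 80, dbp_mmhg = 90),
               class = "esopcg_invalid_argument")
  expect_error(hemo_params(co_l_min = 0), class = "esopcg_invalid_argument")
  expect_error(drug_effect(covariate_r2 = 2), class = "esopcg_invalid_argument")
  expect_error(generate_heart_sound(cycle_params(), -1),
               class = "esopcg_invalid_argument")
  expect_error(generate_heart_sound(cycle_params(heart_rate_bpm = 40), 1),
               class = "esopcg_invalid_argument")
  expect_error(generate_arterial_waveform(hemo_params(), 90, 0),
               class = "esopcg_invalid_argument")
})
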