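# shared fixtures built in code

# per-episode percentage change of one metric column from analyze_episode()
# output rows
episode_pct_change <- function(metrics, var) {
  pre <- metrics[metrics$window == "pre", var]
  post <- metrics[metrics$window == "post", var]
  percent_change(pre, post)
}

# analyze every episode of a simulate_drug_batch() result and return the
# per-episode percentage changes of one metric
batch_pct_changes <- function(batch, var) {
  vapply(seq_along(batch$episodes), function(i) {
    m <- analyze_episode(batch$episodes[[i]], episode_id = i)
    episode_pct_change(m, var)
  }, numeric(1))
}

# hand-built labeled_beats object for direct pcg_metrics tests
make_labeled <- function(s1_times, s1_amps, s2_times, s2_amps) {
  structure(list(beats = data.frame(s1_time_s = s1_times,
                                    s1_env_amp = s1_amps,
                                    s2_time_s = s2_times,
                                    s2_env_amp = s2_amps),
                 unpaired_peaks = 0L),
            class = "labeled_beats")
}

# noise SD giving a target SNR (dB) relative to a noiseless record
noise_sd_for_snr <- function(record, snr_db) {
  sqrt(mean(record$samples^2)) / 10^(snr_db / 20)
}
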