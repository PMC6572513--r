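test_that("identical pairs are flagged degenerate with p = 1", {
  x <- c(5, 6, 7, 8)
  res <- paired_compare(x, x)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_equal(res$pct_change_median, 0)
  expect_identical(res$test_used, "degenerate")
  expect_error(paired_compare(1:4, 1:5), class = "esopcg_invalid_argument")
})

test_that("the selected-test procedure has power at the clinical effect scale", {
  # shift of 3.6 on a baseline of 28.1 +/- 3.7 with n = 9 pairs
  set.seed(42)
  hits <- 0L; reps <- 200L
  for (r in seq_len(reps)) {
    before <- rnorm(9, 28.1, 3.7)
    after <- before + 3.6 + rnorm(9, 0, 2)
    if (paired_compare(before, after)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.8)
})

test_that("signed-rank and paired-t point in the same direction on symmetric effects", {
  set.seed(9)
  for (r in 1:20) {
    before <- rnorm(15, 50, 5)
    after <- before + sample(c(-3, 3), 1) + rnorm(15, 0, 1)
    d <- after - before
    tt <- t.test(after, before, paired = TRUE)
    wt <- wilcox.test(after, before, paired = TRUE, exact = FALSE)
    expect_identical(sign(median(d)), sign(mean(d)))
    # both tests reject on the same side for a clear symmetric shift
    expect_lt(max(tt$p.value, wt$p.value), 0.05)
  }
})

test_that("correlation of changes is exact, consistent, and affine-invariant", {
  x <- c(1, 2, 3, 5, 8)
  res <- correlate_changes(x, 2 * x + 1)
  expect_equal(res$r2, 1)
  set.seed(3)
  xi <- rnorm(1e5); yi <- rnorm(1e5)
  expect_lt(correlate_changes(xi, yi)$r2, 0.001)
  # affine rescaling of either series leaves r2 unchanged
  a <- rnorm(100); b <- 0.4 * a + rnorm(100)
  r0 <- correlate_changes(a, b)$r2
  expect_equal(correlate_changes(3 * a - 7, b)$r2, r0, tolerance = 1e-12)
  expect_equal(correlate_changes(a, -0.5 * b + 2)$r2, r0, tolerance = 1e-12)
  expect_error(correlate_changes(rep(1, 10), rnorm(10)),
               class = "esopcg_undefined_correlation")
  expect_error(correlate_changes(1:2, 1:2), class = "esopcg_invalid_argument")
})

test_that("drug-group summary recovers a configured S1 gain", {
  batch <- simulate_drug_batch("ephedrine", n = 5, seed = 21)
  metrics <- do.call(rbind, lapply(seq_along(batch$episodes), function(i) {
    analyze_episode(batch$episodes[[i]], episode_id = i)
  }))
  summ <- summarize_drug_group(metrics, drug = "ephedrine")
  s1 <- summ[summ$variable == "s1_amp_db", ]
  expect_equal(s1$pct_change_median, 12.7, tolerance = 0.5)
  expect_lt(s1$p_value, 0.05)
  # identical pre/post pairs: every percentage change is zero
  dup <- metrics
  dup[dup$window == "post", !(names(dup) %in% c("episode", "window"))] <-
    dup[dup$window == "pre", !(names(dup) %in% c("episode", "window"))]
  summ0 <- summarize_drug_group(dup, drug = "null")
  expect_true(all(summ0$pct_change_median == 0))
})

test_that("an S2-only effect leaves the S1 comparison non-significant", {
  set.seed(77)
  nonsig <- 0L; groups <- 10L
  for (g in seq_len(groups)) {
    eps <- lapply(1:7, function(i) {
      cyc <- cycle_params(heart_rate_bpm = 100 + rnorm(1, 0, 4),
                          s1_amp = 10^((29.1 + rnorm(1, 0, 1)) / 20),
                          s2_amp = 10^((21.9 + rnorm(1, 0, 1)) / 20),
                          noise_sd = 0.5)
      generate_episode(cyc, hemo_params(93.7, 52.8),
                       drug_effect(s2_db_gain_pct = 5.5),
                       seed = g * 1000 + i)
    })
    metrics <- do.call(rbind, lapply(seq_along(eps), function(i) {
      analyze_episode(eps[[i]], episode_id = i)
    }))
    summ <- summarize_drug_group(metrics, drug = "phenylephrine")
    if (summ$p_value[summ$variable == "s1_amp_db"] > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig / groups, 0.9)
})

test_that("variables missing from some episodes are compared pairwise or reported absent", {
  batch <- simulate_drug_batch("esmolol", n = 3, seed = 5)
  metrics <- do.call(rbind, lapply(seq_along(batch$episodes), function(i) {
    analyze_episode(batch$episodes[[i]], episode_id = i)
  }))
  metrics$tdis_cm_s <- NA_real_
  summ <- summarize_drug_group(metrics, drug = "esmolol")
  tdis <- summ[summ$variable == "tdis_cm_s", ]
  expect_identical(tdis$test_used, "absent")
  expect_true(is.na(tdis$p_value))
  expect_false(any(is.na(summ$p_value[summ$variable == "s1_amp_db"])))
})
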