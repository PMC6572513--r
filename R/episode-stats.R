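#' Paired before/after comparison with normality-gated test choice
#'
#' The statistical procedure applied per variable: a Shapiro-Wilk test on
#' the paired differences decides between the paired t test (normality not
#' rejected at `alpha_normality`) and the Wilcoxon signed-rank test.
#' Descriptives follow the clinical reporting layout: mean and SD before
#' and after, and the median and interquartile range (25th; 75th
#' percentiles, linear interpolation) of the per-pair percentage changes.
#'
#' @param before,after Paired numeric vectors of equal length >= 2.
#' @param alpha_normality Significance level of the normality gate
#'   (default 0.05).
#' @param variable Optional variable name carried into the result.
#' @return A one-row data frame of class `paired_comparison` with columns
#'   `variable`, `n`, `mean_before`, `sd_before`, `mean_after`,
#'   `sd_after`, `test_used` (`"paired-t"`, `"signed-rank"` or
#'   `"degenerate"`), `p_value`, `pct_change_median`, `pct_change_q25`,
#'   `pct_change_q75`, `degenerate` (flag). With all differences equal to
#'   zero the data are degenerate and `p_value = 1` by convention; with
#'   `n = 2` the normality gate cannot run and the paired t test is used.
#' @export
paired_compare <- function(before, after, alpha_normality = 0.05,
                           variable = NA_character_) {
  if (length(before) != length(after)) {
    stop_invalid("before and after must have equal length")
  }
  n <- length(before)
  if (n < 2L) stop_invalid("need at least 2 pairs")
  d <- after - before
  pct <- percent_change(before, after)
  q <- stats::quantile(pct, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    test_used <- "degenerate"
    p <- 1
  } else if (n < 3L) {
    test_used <- "paired-t"
    p <- stats::t.test(after, before, paired = TRUE)$p.value
  } else {
    normal <- stats::shapiro.test(d)$p.value >= alpha_normality
    if (normal) {
      test_used <- "paired-t"
      p <- stats::t.test(after, before, paired = TRUE)$p.value
    } else {
      test_used <- "signed-rank"
      p <- stats::wilcox.test(after, before, paired = TRUE, exact = FALSE)$p.value
    }
  }
  out <- data.frame(variable = variable, n = n,
                    mean_before = mean(before), sd_before = stats::sd(before),
                    mean_after = mean(after), sd_after = stats::sd(after),
                    test_used = test_used, p_value = p,
                    pct_change_median = q[2], pct_change_q25 = q[1],
                    pct_change_q75 = q[3], degenerate = degenerate,
                    stringsAsFactors = FALSE)
  class(out) <- c("paired_comparison", class(out))
  out
}

#' Squared Pearson correlation between percentage-change series
#'
#' Pearson correlation of two paired series (typically percentage changes
#' of a heart-sound amplitude and of a hemodynamic covariate), reported as
#' r-squared with the two-sided p value from the exact t transform of r on
#' n - 2 degrees of freedom.
#'
#' @param x_pct,y_pct Paired finite numeric vectors of equal length >= 3.
#' @return List with `r2`, `p_value` and `n`.
#' @export
correlate_changes <- function(x_pct, y_pct) {
  if (length(x_pct) != length(y_pct)) stop_invalid("series must have equal length")
  if (length(x_pct) < 3L) stop_invalid("need at least 3 pairs")
  if (!all(is.finite(x_pct)) || !all(is.finite(y_pct))) {
    stop_invalid("series must be finite")
  }
  if (stats::sd(x_pct) == 0 || stats::sd(y_pct) == 0) {
    stop_domain("esopcg_undefined_correlation",
                "correlation undefined: a series has zero variance")
  }
  ct <- stats::cor.test(x_pct, y_pct, method = "pearson")
  list(r2 = unname(ct$estimate)^2, p_value = ct$p.value, n = length(x_pct))
}

#' Summarize a drug group's paired episode metrics
#'
#' Builds the drug-group summary table: one paired before/after comparison
#' per variable (pressures, heart rate, SVR, TDI S', dP/dt, S1/S2
#' amplitudes, total power) across a group's episodes. A variable missing
#' (NA) in some episodes is compared over the complete pairs only and
#' reported as absent if fewer than 2 remain.
#'
#' @param episode_metrics A data frame with one row per episode window,
#'   columns `episode`, `window` (`"pre"`/`"post"`) and the metric
#'   columns; the shape produced by [analyze_episode()] /
#'   [run_pipeline()].
#' @param drug Group label carried into the output.
#' @param variables Metric columns to compare (default: all present among
#'   the standard set).
#' @param alpha_normality Normality-gate level for [paired_compare()].
#' @return A data frame of [paired_compare()] rows, one per variable, with
#'   a `drug` column.
#' @export
summarize_drug_group <- function(episode_metrics, drug = NA_character_,
                                 variables = NULL, alpha_normality = 0.05) {
  std <- c("sbp_mmhg", "dbp_mmhg", "map_mmhg", "heart_rate_bpm",
           "svr_dyne_s_cm5", "tdis_cm_s", "dpdt_mmhg_s",
           "s1_amp_db", "s2_amp_db", "total_power_db")
  if (is.null(variables)) variables <- intersect(std, names(episode_metrics))
  pre <- episode_metrics[episode_metrics$window == "pre", ]
  post <- episode_metrics[episode_metrics$window == "post", ]
  pre <- pre[order(pre$episode), ]
  post <- post[order(post$episode), ]
  if (nrow(pre) < 2L || !identical(pre$episode, post$episode)) {
    stop_invalid("need >= 2 episodes with matching pre and post rows")
  }
  rows <- lapply(variables, function(v) {
    b <- pre[[v]]; a <- post[[v]]
    ok <- is.finite(b) & is.finite(a)
    if (sum(ok) < 2L) {
      out <- data.frame(variable = v, n = sum(ok), mean_before = NA_real_,
                        sd_before = NA_real_, mean_after = NA_real_,
                        sd_after = NA_real_, test_used = "absent",
                        p_value = NA_real_, pct_change_median = NA_real_,
                        pct_change_q25 = NA_real_, pct_change_q75 = NA_real_,
                        degenerate = NA, stringsAsFactors = FALSE)
      return(out)
    }
    paired_compare(b[ok], a[ok], alpha_normality = alpha_normality,
                   variable = v)
  })
  out <- do.call(rbind, rows)
  out$drug <- drug
  rownames(out) <- NULL
  out
}

#' Format a drug-group summary as a Markdown table
#'
#' Renders [summarize_drug_group()] output in the clinical reporting
#' layout: `mean ± sd` before and after, the test p value and the
#' `median (q25; q75)` percentage change per variable.
#'
#' @param summary_df Output of [summarize_drug_group()].
#' @param digits Significant digits.
#' @return Character vector of Markdown lines.
#' @export
format_summary_markdown <- function(summary_df, digits = 3) {
  f <- function(x) ifelse(is.na(x), "-", signif(x, digits))
  lines <- c(
    sprintf("| Variable | n | Before | After | Test | p | %% change median (IQR) |"),
    "|---|---|---|---|---|---|---|"
  )
  for (i in seq_len(nrow(summary_df))) {
    r <- summary_df[i, ]
    lines <- c(lines, sprintf(
      "| %s | %d | %s ± %s | %s ± %s | %s | %s | %s (%s; %s) |",
      r$variable, r$n, f(r$mean_before), f(r$sd_before), f(r$mean_after),
      f(r$sd_after), r$test_used, f(r$p_value), f(r$pct_change_median),
      f(r$pct_change_q25), f(r$pct_change_q75)))
  }
  lines
}
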