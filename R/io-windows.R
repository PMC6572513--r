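#' Write a signal record as a mono WAV file
#'
#' Minimal RIFF/WAVE writer: IEEE float64 (default, lossless for analysis
#' traces), IEEE float32, or 16-bit PCM. One channel at the record's
#' sampling rate.
#'
#' @param record A [signal_record()].
#' @param path Output path.
#' @param bits 64 or 32 (IEEE float) or 16 (PCM; samples must lie in
#'   \[-1, 1\]).
#' @return `path`, invisibly.
#' @export
write_wav <- function(record, path, bits = 64) {
  stopifnot(inherits(record, "signal_record"), bits %in% c(16L, 32L, 64L))
  x <- record$samples
  fs <- as.integer(round(record$fs))
  con <- file(path, "wb")
  on.exit(close(con))
  fmt <- if (bits >= 32) 3L else 1L
  bytes_per <- bits / 8L
  data_size <- length(x) * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 64) {
    writeBin(x, con, size = 8, endian = "little")
  } else if (bits == 32) {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    if (any(abs(x) > 1)) stop_invalid("16-bit PCM requires samples in [-1, 1]")
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_wav <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) {
    stop_domain("esopcg_format_error", "not a WAV file (too short): ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) {
    stop_domain("esopcg_format_error", "missing RIFF header: ", path)
  }
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) {
    stop_domain("esopcg_format_error", "missing WAVE tag: ", path)
  }
  fmt <- NULL; fs <- NULL; bits <- NULL; channels <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) {
      stop_domain("esopcg_format_error", "no data chunk in WAV file: ", path)
    }
    len <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      channels <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (len > 16) readBin(con, raw(), n = len - 16)
    } else if (id == "data") {
      if (is.null(fmt)) {
        stop_domain("esopcg_format_error", "data chunk before fmt chunk: ", path)
      }
      if (channels != 1L) {
        stop_domain("esopcg_format_error", "only mono WAV supported, got ",
                    channels, " channels: ", path)
      }
      if (fmt == 3L && bits == 64L) {
        x <- readBin(con, numeric(), n = len / 8, size = 8, endian = "little")
      } else if (fmt == 3L && bits == 32L) {
        x <- readBin(con, numeric(), n = len / 4, size = 4, endian = "little")
      } else if (fmt == 1L && bits == 16L) {
        x <- readBin(con, integer(), n = len / 2, size = 2,
                     endian = "little", signed = TRUE) / 32767
      } else {
        stop_domain("esopcg_format_error", "unsupported WAV encoding (format ",
                    fmt, ", ", bits, " bit): ", path)
      }
      return(list(samples = x, fs = fs))
    } else {
      readBin(con, raw(), n = len + len %% 2)
    }
  }
}

#' Write a signal record as a two-column CSV
#'
#' Columns `time_s` and a value column (named after `value_col`), the
#' interchange format for pressure traces.
#'
#' @param record A [signal_record()].
#' @param path Output path.
#' @param value_col Name of the value column (default `"pressure_mmhg"`).
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path, value_col = "pressure_mmhg") {
  stopifnot(inherits(record, "signal_record"))
  df <- data.frame(time_s = record_times(record), value = record$samples)
  names(df)[2] <- value_col
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a signal record from WAV or CSV
#'
#' WAV files (mono PCM16 or float32) carry their sampling rate in the
#' header; CSV files must have a strictly increasing, uniformly spaced
#' `time_s` first column and one value column, from which the sampling
#' rate is inferred. Malformed inputs raise a format error naming the
#' file and offending field.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"wav"` or `"csv"`.
#' @param unit Unit label for the returned record.
#' @return A [signal_record()].
#' @export
read_record <- function(path, format = c("auto", "wav", "csv"), unit = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_domain("esopcg_format_error", "file does not exist: ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, wav = "wav", csv = "csv",
                     stop_domain("esopcg_format_error",
                                 "unknown format for extension '.", ext, "': ", path))
  }
  if (format == "wav") {
    w <- read_wav(path)
    return(signal_record(w$samples, w$fs, unit = if (is.null(unit)) "au" else unit))
  }
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop_domain("esopcg_format_error",
                                                 "unparseable CSV: ", path))
  if (nrow(df) < 2L || ncol(df) < 2L) {
    stop_domain("esopcg_format_error",
                "CSV needs >= 2 rows and a time_s plus value column: ", path)
  }
  if (!"time_s" %in% names(df)) {
    stop_domain("esopcg_format_error", "missing 'time_s' column: ", path)
  }
  tm <- df$time_s
  dt <- diff(tm)
  if (any(dt <= 0)) {
    stop_domain("esopcg_format_error",
                "non-monotone 'time_s' column in ", path)
  }
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-9) {
    stop_domain("esopcg_format_error",
                "non-uniform sampling in 'time_s' column of ", path)
  }
  value_col <- setdiff(names(df), "time_s")[1]
  signal_record(df[[value_col]], fs = 1 / stats::median(dt),
                unit = if (is.null(unit)) value_col else unit,
                start_time_s = tm[1])
}

#' Describe a drug-administration event
#'
#' @param record_id Identifier of the parent record.
#' @param drug One of `"ephedrine"`, `"esmolol"`, `"phenylephrine"`,
#'   `"nicardipine"`, `"other"`.
#' @param event_time_s Drug timestamp within the record (s).
#' @param dose Free-text dose label.
#' @return A list of class `event_record`.
#' @export
event_record <- function(record_id, drug, event_time_s, dose = "") {
  drug <- match.arg(drug, c("ephedrine", "esmolol", "phenylephrine",
                            "nicardipine", "other"))
  structure(list(record_id = record_id, drug = drug,
                 event_time_s = event_time_s, dose = dose),
            class = "event_record")
}

#' Extract the paired pre/post analysis windows around an event
#'
#' Cuts the two fixed-length windows whose inner edges sit `offset_s`
#' before and after the drug event: pre spans
#' `[event - offset - length, event - offset)` and post
#' `[event + offset, event + offset + length)`, half-open in 0-based
#' samples, so each slice holds exactly `length_s * fs` samples.
#'
#' @param record The full-length [signal_record()].
#' @param event An [event_record()] (or any list with `event_time_s`).
#' @param offset_s Inner-edge distance from the event (default 120 s).
#' @param length_s Window length (default 20 s).
#' @return List with `pre` and `post` [signal_record()] slices, `anchors`
#'   (`event - offset`, `event + offset`) and `length_s`.
#' @export
extract_window_pair <- function(record, event, offset_s = 120, length_s = 20) {
  stopifnot(inherits(record, "signal_record"))
  ev <- event$event_time_s
  fs <- record$fs
  t0 <- record$start_time_s
  t_end <- t0 + length(record$samples) / fs
  pre_start <- ev - offset_s - length_s
  post_end <- ev + offset_s + length_s
  if (pre_start < t0 - 1e-9) {
    stop_domain("esopcg_out_of_range",
                "pre window starts ", signif(t0 - pre_start, 4),
                " s before the record")
  }
  if (post_end > t_end + 1e-9) {
    stop_domain("esopcg_out_of_range",
                "post window ends ", signif(post_end - t_end, 4),
                " s after the record")
  }
  n_len <- round(length_s * fs)
  slice <- function(start_s) {
    i0 <- round((start_s - t0) * fs)      # 0-based start sample
    signal_record(record$samples[(i0 + 1L):(i0 + n_len)], fs,
                  unit = record$unit, start_time_s = t0 + i0 / fs,
                  meta = record$meta)
  }
  list(pre = slice(pre_start), post = slice(ev + offset_s),
       anchors = c(ev - offset_s, ev + offset_s), length_s = length_s)
}

#' Write a simulated episode to disk
#'
#' Persists one [generate_episode()] result as paired WAV sound windows,
#' CSV pressure windows and a JSON sidecar holding the ground truth,
#' covariates and event time.
#'
#' @param episode A `pcg_episode`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_episode <- function(episode, dir, prefix = "episode") {
  stopifnot(inherits(episode, "pcg_episode"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    pre_sound = file.path(dir, paste0(prefix, "_pre.wav")),
    post_sound = file.path(dir, paste0(prefix, "_post.wav")),
    pre_pressure = file.path(dir, paste0(prefix, "_pre_pressure.csv")),
    post_pressure = file.path(dir, paste0(prefix, "_post_pressure.csv")),
    sidecar = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_wav(episode$pre_sound, paths["pre_sound"])
  write_wav(episode$post_sound, paths["post_sound"])
  write_record_csv(episode$pre_pressure, paths["pre_pressure"])
  write_record_csv(episode$post_pressure, paths["post_pressure"])
  truth <- list(event_time_s = episode$event_time_s,
                effect = unclass(episode$truth$effect),
                pre = lapply(episode$truth$pre, unclass),
                post = lapply(episode$truth$post, unclass),
                covariates = episode$covariates)
  jsonlite::write_json(truth, paths["sidecar"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Analyze one episode's pre and post windows
#'
#' Runs the full measurement chain on a `pcg_episode`: sound windows
#' through [analyze_sound_window()], pressure windows through
#' [beat_pressures()] and [dpdt_max()], and SVR from the measured MAP
#' with the episode's CVP/CO covariates.
#'
#' @param episode A `pcg_episode`.
#' @param band Band-pass edges (Hz).
#' @param db_ref,power_ref dB references for [pcg_metrics()].
#' @param episode_id Identifier placed in the `episode` column.
#' @return Data frame with two rows (`window = "pre"`/`"post"`) and the
#'   full metric set.
#' @export
analyze_episode <- function(episode, band = c(25, 120), db_ref = 1,
                            power_ref = 1e-3, episode_id = 1L) {
  stopifnot(inherits(episode, "pcg_episode"))
  one <- function(win) {
    snd <- analyze_sound_window(episode[[paste0(win, "_sound")]], band = band,
                                db_ref = db_ref, power_ref = power_ref)
    prs <- beat_pressures(episode[[paste0(win, "_pressure")]])
    dpdt <- dpdt_max(episode[[paste0(win, "_pressure")]])
    cov <- episode$covariates[episode$covariates$window == win, ]
    cbind(data.frame(episode = episode_id, window = win,
                     stringsAsFactors = FALSE),
          snd$metrics, prs,
          data.frame(dpdt_mmhg_s = dpdt,
                     svr_dyne_s_cm5 = svr(prs$map_mmhg, cov$cvp_mmhg,
                                          cov$co_l_min),
                     tdis_cm_s = cov$tdis_cm_s))
  }
  rbind(one("pre"), one("post"))
}

#' Run the full analysis pipeline over a batch of episodes
#'
#' Orchestrates the processing chain for each drug event — window pair,
#' band-pass, envelope, S1/S2 segmentation, phonocardiographic and
#' pressure metrics, SVR — then summarizes each drug group with paired
#' statistics. Episodes are supplied either in memory
#' (`config$episodes`, a list of `pcg_episode`, with `config$drugs`) or
#' on disk (`config$manifest`, `config$events`, `config$covariates`; see
#' Details). A stage failure is recorded per event and does not abort the
#' remaining events. The returned log records every parameter and the
#' seed, and contains no timestamps, so identical configs yield
#' byte-identical outputs.
#'
#' @param config A list. Common fields: `band` (default `c(25, 120)`),
#'   `offset_s` (120), `window_s` (20), `db_ref` (1), `power_ref`
#'   (1e-3), `seed` (NULL), `out_dir` (optional; writes `metrics.csv`,
#'   `summary.csv`, `summary.md`, `run_log.json`). In-memory mode:
#'   `episodes` + `drugs`. File mode: `manifest` (data frame
#'   `record_id`, `sound_path`, optional `pressure_path`), `events`
#'   (data frame `record_id`, `drug`, `event_time_s`, `dose`),
#'   `covariates` (data frame `record_id`, `window`, `tdis_cm_s`,
#'   `cvp_mmhg`, `co_l_min`).
#' @return List of class `pcg_pipeline_result` with `metrics`, `summary`,
#'   `errors` and `log`.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(
    list(band = c(25, 120), offset_s = 120, window_s = 20, db_ref = 1,
         power_ref = 1e-3, seed = NULL, out_dir = NULL),
    config
  )
  errors <- list()
  metrics <- list()
  drugs <- character(0)

  if (!is.null(cfg$episodes)) {
    eps <- cfg$episodes
    drug_vec <- cfg$drugs %||% rep("other", length(eps))
    for (i in seq_along(eps)) {
      res <- tryCatch(
        analyze_episode(eps[[i]], band = cfg$band, db_ref = cfg$db_ref,
                        power_ref = cfg$power_ref, episode_id = i),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[as.character(i)]] <- conditionMessage(res)
      } else {
        metrics[[length(metrics) + 1L]] <- res
        drugs <- c(drugs, rep(drug_vec[i], 2))
      }
    }
  } else if (!is.null(cfg$events)) {
    for (i in seq_len(nrow(cfg$events))) {
      ev <- cfg$events[i, ]
      res <- tryCatch({
        mrow <- cfg$manifest[cfg$manifest$record_id == ev$record_id, ]
        if (nrow(mrow) != 1L) stop_invalid("no manifest row for ", ev$record_id)
        sound <- read_record(mrow$sound_path)
        wp <- extract_window_pair(sound, ev, offset_s = cfg$offset_s,
                                  length_s = cfg$window_s)
        has_pressure <- "pressure_path" %in% names(mrow) &&
          !is.na(mrow$pressure_path) && nzchar(mrow$pressure_path)
        pp <- if (has_pressure) {
          extract_window_pair(read_record(mrow$pressure_path), ev,
                              offset_s = cfg$offset_s, length_s = cfg$window_s)
        } else NULL
        one <- function(win) {
          snd <- analyze_sound_window(wp[[win]], band = cfg$band,
                                      db_ref = cfg$db_ref,
                                      power_ref = cfg$power_ref)
          base <- cbind(data.frame(episode = i, window = win,
                                   stringsAsFactors = FALSE), snd$metrics)
          if (!is.null(pp)) {
            prs <- beat_pressures(pp[[win]])
            base <- cbind(base, prs,
                          data.frame(dpdt_mmhg_s = dpdt_max(pp[[win]])))
            cov <- cfg$covariates
            if (!is.null(cov)) {
              crow <- cov[cov$record_id == ev$record_id & cov$window == win, ]
              if (nrow(crow) == 1L) {
                base$svr_dyne_s_cm5 <- svr(prs$map_mmhg, crow$cvp_mmhg,
                                           crow$co_l_min)
                base$tdis_cm_s <- crow$tdis_cm_s
              }
            }
          }
          base
        }
        rbind(one("pre"), one("post"))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[as.character(ev$record_id)]] <- conditionMessage(res)
      } else {
        metrics[[length(metrics) + 1L]] <- res
        drugs <- c(drugs, rep(ev$drug, 2))
      }
    }
  } else {
    warning("run_pipeline: no episodes or events in config; empty report")
  }

  metrics_df <- if (length(metrics)) {
    all_names <- unique(unlist(lapply(metrics, names)))
    filled <- lapply(metrics, function(m) {
      m[setdiff(all_names, names(m))] <- NA
      m[all_names]
    })
    out <- do.call(rbind, filled)
    out$drug <- drugs
    out
  } else {
    data.frame(episode = integer(0), window = character(0),
               drug = character(0))
  }

  summary_df <- NULL
  if (nrow(metrics_df) > 0) {
    for (d in unique(metrics_df$drug)) {
      sub <- metrics_df[metrics_df$drug == d, ]
      if (length(unique(sub$episode)) >= 2L) {
        summary_df <- rbind(summary_df, summarize_drug_group(sub, drug = d))
      }
    }
  }

  log <- list(parameters = list(band = cfg$band, offset_s = cfg$offset_s,
                                window_s = cfg$window_s, db_ref = cfg$db_ref,
                                power_ref = cfg$power_ref),
              seed = cfg$seed,
              n_events = length(metrics) + length(errors),
              n_failed = length(errors))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics_df, file.path(cfg$out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(summary_df)) {
      utils::write.csv(summary_df, file.path(cfg$out_dir, "summary.csv"),
                       row.names = FALSE)
      writeLines(format_summary_markdown(summary_df),
                 file.path(cfg$out_dir, "summary.md"))
    }
    jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(metrics = metrics_df, summary = summary_df,
                 errors = errors, log = log),
            class = "pcg_pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pcg_pipeline_result <- function(x, ...) {
  cat(sprintf("<pcg_pipeline_result> %d windows analyzed, %d event(s) failed\n",
              nrow(x$metrics), length(x$errors)))
  if (!is.null(x$summary)) {
    cat("Summary rows:", nrow(x$summary), "\n")
  }
  invisible(x)
}
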