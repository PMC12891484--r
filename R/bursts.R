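#' Burst-detection configuration
#'
#' @param band `[low, high]` Hz envelope band. Reference defaults: mouse
#'   head-fixed LFP `c(2, 10)`, freely-moving `c(3, 8)`, human FXS
#'   `c(5, 10)`, TD `c(7, 12)`.
#' @param threshold_percentile envelope percentile defining a burst
#'   (default 90).
#' @param min_duration_ms a supra-threshold run must last strictly longer
#'   than this to count (default 3 ms).
#' @param metric `"amplitude"` (mouse) or `"log_squared_amplitude"` (human:
#'   envelope squared and log-transformed, i.e. power units).
#' @export
burst_config <- function(band = c(2, 10), threshold_percentile = 90,
                         min_duration_ms = 3,
                         metric = c("amplitude", "log_squared_amplitude")) {
  if (threshold_percentile <= 0 || threshold_percentile >= 100)
    stop_invalid("threshold_percentile must be in (0, 100)")
  if (min_duration_ms <= 0) stop_invalid("min_duration_ms must be > 0")
  list(band = band, threshold_percentile = threshold_percentile,
       min_duration_ms = min_duration_ms, metric = match.arg(metric))
}

#' Movement-bout configuration
#'
#' @param volt_threshold piezo voltage defining movement, mV (default 2).
#' @param buffer_ms sub-threshold gaps shorter than this inside a bout are
#'   bridged and counted as movement (default 750 ms).
#' @export
movement_config <- function(volt_threshold = 2, buffer_ms = 750) {
  if (volt_threshold <= 0 || buffer_ms <= 0)
    stop_invalid("movement thresholds must be > 0")
  list(volt_threshold = volt_threshold, buffer_ms = buffer_ms)
}

#' Detect analytic-envelope bursts
#'
#' Band-passes the recording, takes the Hilbert envelope (or its
#' log-squared, per `cfg$metric`), sets the threshold at the configured
#' percentile of the metric over the whole analysis window (percentiles use
#' linear interpolation between order statistics), and counts maximal
#' supra-threshold runs lasting strictly longer than the minimum duration.
#'
#' @param rec a [recording] with at least `analysis_length_s` of data.
#' @param cfg a [burst_config].
#' @param analysis_length_s length of the continuous analysis window,
#'   seconds (default 100; the percentile threshold is defined over exactly
#'   this window).
#' @param start_s window start, seconds; when the recording is longer than
#'   the window and `start_s` is `NULL` the start is drawn uniformly using
#'   `seed`.
#' @param seed RNG seed for the random start.
#' @return a `burst_stats` list: `count`, `durations_ms`, `threshold_value`,
#'   `intervals` (sample indices), `metric`, plus empty movement fields
#'   filled by [align_bursts_movement].
#' @export
burst_detect <- function(rec, cfg = burst_config(), analysis_length_s = 100,
                         start_s = NULL, seed = NULL) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sampling_rate
  need <- round(analysis_length_s * fs)
  n <- length(rec$samples)
  if (n < need)
    stop_invalid("recording (", n / fs, " s) shorter than the ",
                 analysis_length_s, " s analysis window")
  if (is.null(start_s)) {
    start <- if (n == need) 1L else
      with_seed(seed, sample.int(n - need + 1L, 1L))
  } else start <- round(start_s * fs) + 1L
  idx <- start + seq_len(need) - 1L
  if (idx[need] > n) stop_invalid("analysis window extends past the recording")
  x <- rec$samples[idx]

  env <- bandpass_analytic(x, fs, cfg$band)$amplitude
  metric <- if (cfg$metric == "log_squared_amplitude") log(env^2) else env
  thr <- quantile(metric, cfg$threshold_percentile / 100, type = 7,
                  names = FALSE)
  above <- metric > thr
  if (!any(above)) {
    warning("degenerate envelope: no samples above the percentile threshold")
    runs <- cbind(start = integer(), end = integer())
  } else runs <- true_runs(above)
  dur_ms <- (runs[, "end"] - runs[, "start"] + 1L) / fs * 1000
  keep <- dur_ms > cfg$min_duration_ms
  structure(list(count = sum(keep), durations_ms = dur_ms[keep],
                 threshold_value = thr,
                 intervals = runs[keep, , drop = FALSE],
                 metric = cfg$metric, window_start = start,
                 window_samples = need, sampling_rate = fs,
                 fraction_during_movement = NA_real_,
                 percent_time_moving = NA_real_),
            class = "burst_stats")
}

#' @export
print.burst_stats <- function(x, ...) {
  cat(sprintf("<burst_stats> %d bursts, median duration %.1f ms, threshold %.4g\n",
              x$count, if (x$count) median(x$durations_ms) else NA_real_,
              x$threshold_value))
  invisible(x)
}

#' Channel-averaged human burst metrics
#'
#' Runs [burst_detect] per channel with the log-squared-amplitude metric on
#' 90 s continuous windows, then averages count and mean duration across
#' channels.
#'
#' @param channels list of [recording] objects (occipital channels).
#' @param cfg a [burst_config]; the band is group-specific (5-10 Hz FXS,
#'   7-12 Hz TD).
#' @param analysis_length_s window length, seconds (default 90).
#' @param start_s,seed passed to [burst_detect].
#' @return list with `count` (channel mean), `mean_duration_ms` (channel
#'   mean), and `per_channel` results.
#' @export
human_burst_detect <- function(channels,
                               cfg = burst_config(band = c(5, 10),
                                                  metric = "log_squared_amplitude"),
                               analysis_length_s = 90, start_s = NULL,
                               seed = NULL) {
  if (inherits(channels, "recording")) channels <- list(channels)
  if (!length(channels)) stop_invalid("need at least one channel")
  per <- lapply(channels, burst_detect, cfg = cfg,
                analysis_length_s = analysis_length_s, start_s = start_s,
                seed = seed)
  list(count = mean(vapply(per, `[[`, 0, "count")),
       mean_duration_ms = mean(vapply(per, function(b)
         if (b$count) mean(b$durations_ms) else 0, 0)),
       per_channel = per)
}

#' Movement state from a rectified piezo trace
#'
#' Samples above the voltage threshold mark movement; sub-threshold gaps
#' shorter than the buffer between movement samples are bridged (counted as
#' movement). Percent time moving normalizes the binary state to the window
#' length times the sampling rate.
#'
#' @param piezo rectified piezo samples, mV.
#' @param sampling_rate Hz.
#' @param cfg a [movement_config].
#' @return list with `state` (0/1 per sample), `percent_time_moving`, and
#'   bout `intervals` (sample indices).
#' @export
movement_bouts <- function(piezo, sampling_rate, cfg = movement_config()) {
  above <- piezo > cfg$volt_threshold
  state <- above
  if (any(above)) {
    runs <- true_runs(!above)               # sub-threshold gaps
    buf <- cfg$buffer_ms / 1000 * sampling_rate
    n <- length(piezo)
    for (r in seq_len(nrow(runs))) {
      s <- runs[r, "start"]; e <- runs[r, "end"]
      interior <- s > 1L && e < n           # gap flanked by movement
      if (interior && (e - s + 1L) < buf) state[s:e] <- TRUE
    }
  }
  list(state = as.integer(state),
       percent_time_moving = 100 * sum(state) / length(piezo),
       intervals = true_runs(state))
}

#' Align bursts with the movement state
#'
#' A burst counts as occurring during movement when its onset sample has
#' movement state 1 (an overlap-fraction rule is available via `rule`).
#'
#' @param bursts a `burst_stats` from [burst_detect].
#' @param movement result of [movement_bouts] (or a bare 0/1 state vector
#'   over the same analysis window).
#' @param rule `"onset"` (default) or `"overlap"` (counted as movement when
#'   more than half the burst's samples are movement).
#' @return `bursts` with `fraction_during_movement` and
#'   `percent_time_moving` filled.
#' @export
align_bursts_movement <- function(bursts, movement, rule = c("onset", "overlap")) {
  stopifnot(inherits(bursts, "burst_stats"))
  rule <- match.arg(rule)
  state <- if (is.list(movement)) movement$state else movement
  if (length(state) != bursts$window_samples)
    stop_invalid("movement state length does not match the analysis window")
  iv <- bursts$intervals
  if (nrow(iv)) {
    during <- vapply(seq_len(nrow(iv)), function(r) {
      if (rule == "onset") state[iv[r, "start"]] == 1L
      else mean(state[iv[r, "start"]:iv[r, "end"]]) > 0.5
    }, TRUE)
    bursts$fraction_during_movement <- mean(during)
  } else bursts$fraction_during_movement <- NA_real_
  bursts$percent_time_moving <- 100 * sum(state) / length(state)
  bursts
}

#' Multitaper spectrogram
#'
#' Sliding-window multitaper PSD (no zero padding), times at window
#' centres.
#'
#' @param rec a [recording].
#' @param tapers number of Slepian tapers (default 2, with `TW = (K+1)/2`).
#' @param window_s window length, seconds (default 3).
#' @param step_s step between windows, seconds (default 0.75).
#' @param fmax optional upper frequency bound, Hz.
#' @return list with `power` (freq x time matrix, µV²/Hz), `freqs`, `times`.
#' @export
mt_spectrogram <- function(rec, tapers = 2L, window_s = 3, step_s = 0.75,
                           fmax = NULL) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sampling_rate
  n <- length(rec$samples)
  nw <- round(window_s * fs)
  if (n < nw) stop_invalid("recording shorter than one spectrogram window")
  ns <- round(step_s * fs)
  starts <- seq(1L, n - nw + 1L, by = ns)
  tp <- taper_params_tw((tapers + 1) / 2, window_s, K = tapers)
  frames <- lapply(starts, function(s) rec$samples[s + seq_len(nw) - 1L])
  es <- epoch_set(do.call(cbind, frames), window_s, fs)
  out <- multitaper_psd(es, tp, fmax = fmax)
  list(power = out$per_epoch, freqs = out$freqs,
       times = (starts - 1L + nw / 2) / fs)
}
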