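#' Epoch container
#'
#' Fixed-length, non-overlapping windows of one recording, stored column-wise
#' with a per-epoch inclusion flag. Epochs are flagged, never deleted, so
#' epoch counts and provenance survive to reports.
#'
#' @param epochs numeric matrix, one epoch per column.
#' @param segment_length epoch length in seconds.
#' @param sampling_rate Hz.
#' @param included logical vector, one flag per epoch.
#' @param source list of provenance metadata.
#' @export
epoch_set <- function(epochs, segment_length, sampling_rate,
                      included = rep(TRUE, ncol(epochs)), source = list()) {
  stopifnot(is.matrix(epochs), length(included) == ncol(epochs))
  structure(list(epochs = epochs, segment_length = segment_length,
                 sampling_rate = sampling_rate, included = included,
                 source = source, exclusion_report = NULL),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d x %g s epochs @ %g Hz (%d included)\n",
              ncol(x$epochs), x$segment_length, x$sampling_rate,
              sum(x$included)))
  invisible(x)
}

n_epochs <- function(es) ncol(es$epochs)

#' Remove the signal mean
#'
#' @param rec a [recording].
#' @return the recording with its mean subtracted (piezo untouched).
#' @export
detrend_mean <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  rec$samples <- rec$samples - mean(rec$samples)
  rec
}

#' Second-order IIR notch filter, zero-phase
#'
#' Removes a narrow line (e.g. 50/60 Hz mains) with a biquad notch applied
#' forward and backward. `bandwidth` is a fraction of the Nyquist frequency
#' (the convention of the common second-order IIR notch designs); the centre
#' is given in Hz.
#'
#' @param rec a [recording].
#' @param center_freq notch centre, Hz.
#' @param bandwidth -3 dB width as a fraction of Nyquist (e.g. 0.01).
#' @return filtered recording.
#' @export
notch_filter <- function(rec, center_freq, bandwidth = 0.01) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$sampling_rate / 2
  if (center_freq <= 0 || center_freq >= nyq)
    stop_invalid("notch centre ", center_freq, " Hz outside (0, ", nyq, ")")
  if (bandwidth <= 0) stop_invalid("notch bandwidth must be > 0")
  cf <- iir_notch_coef(center_freq / nyq, bandwidth)
  rec$samples <- iir_filtfilt(rec$samples, cf$b, cf$a)
  rec
}

#' Cut a recording into fixed-length epochs
#'
#' Non-overlapping windows in temporal order; a trailing remainder shorter
#' than `segment_length` is discarded.
#'
#' @param rec a [recording].
#' @param segment_length seconds per epoch (e.g. 5 for mouse, 2 for human).
#' @return an [epoch_set].
#' @export
segment <- function(rec, segment_length) {
  stopifnot(inherits(rec, "recording"))
  assert_scalar_num(segment_length, "segment_length", positive = TRUE)
  nspe <- round(segment_length * rec$sampling_rate)
  if (abs(nspe - segment_length * rec$sampling_rate) > 1e-6)
    stop_invalid("segment_length x sampling_rate must be integral")
  n <- length(rec$samples)
  k <- n %/% nspe
  if (k < 1L) stop_invalid("recording shorter than one segment")
  m <- matrix(rec$samples[seq_len(k * nspe)], nrow = nspe)
  epoch_set(m, segment_length, rec$sampling_rate,
            source = list(channel = rec$channel_label))
}

concatenate_epochs <- function(es, included_only = FALSE) {
  keep <- if (included_only) es$included else rep(TRUE, n_epochs(es))
  as.numeric(es$epochs[, keep, drop = FALSE])
}

robust_z <- function(x) {
  med <- median(x)
  s <- mad(x)
  if (s <= 0) s <- sd(x)
  if (!is.finite(s) || s <= 0) return(rep(0, length(x)))
  (x - med) / s
}

#' Flag movement/low-frequency artifact epochs
#'
#' An epoch is excluded only when BOTH its peak absolute amplitude and its
#' summed low-frequency (< `lf_cutoff`) spectral power are extreme relative
#' to the other epochs (robust z-scores above the thresholds). The
#' conjunction mirrors the rule that a contaminated epoch shows a large
#' movement artifact together with a huge spike in sub-1.5 Hz power.
#'
#' @param es an [epoch_set].
#' @param lf_cutoff low-frequency band upper edge, Hz (default 1.5).
#' @param amp_z robust z threshold on peak amplitude (default 4).
#' @param lf_z robust z threshold on low-frequency power (default 4).
#' @return the epoch set with `included` updated and an `exclusion_report`.
#' @export
exclude_artifact_epochs <- function(es, lf_cutoff = 1.5, amp_z = 4, lf_z = 4) {
  stopifnot(inherits(es, "epoch_set"))
  if (amp_z <= 0 || lf_z <= 0) stop_invalid("thresholds must be > 0")
  ne <- n_epochs(es)
  if (ne < 3L) {
    warning("fewer than 3 epochs: artifact z-scores unstable, exclusion skipped")
    es$exclusion_report <- data.frame(epoch = seq_len(ne), excluded = FALSE)
    return(es)
  }
  peak_amp <- apply(abs(es$epochs), 2L, max)
  nspe <- nrow(es$epochs)
  freqs <- (0:(nspe %/% 2)) / es$segment_length
  lf_bins <- which(freqs > 0 & freqs < lf_cutoff)
  lf_power <- apply(es$epochs, 2L, function(x) {
    X <- fft(x - mean(x))
    sum((Mod(X[lf_bins + 1L])^2) / nspe)
  })
  za <- robust_z(peak_amp)
  zl <- robust_z(lf_power)
  bad <- za > amp_z & zl > lf_z
  es$included <- es$included & !bad
  es$exclusion_report <- data.frame(epoch = seq_len(ne), amp_z = za,
                                    lf_z = zl, excluded = bad)
  es
}

#' Flag epochs exceeding an absolute amplitude limit
#'
#' @param es an [epoch_set].
#' @param limit rejection threshold in µV (default 120, the +/-120 µV rule).
#' @return the epoch set with offending epochs excluded.
#' @export
amplitude_reject <- function(es, limit = 120) {
  stopifnot(inherits(es, "epoch_set"))
  if (limit < 0) stop_invalid("limit must be >= 0")
  bad <- apply(abs(es$epochs), 2L, max) > limit
  es$included <- es$included & !bad
  es
}
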