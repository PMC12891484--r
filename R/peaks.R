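# Periodic peak extraction from the aperiodic-subtracted residual:
# human Pk1/Pk2 split at 15 Hz, the single mouse surface-EEG peak below
# 10 Hz (locally weighted smoothing), and the mouse LFP sub-peaks
# Pk1a/Pk1b split at the most prominent smoothed local minimum of the
# 2-10 Hz window (deterministic 6 Hz fallback when no interior minimum
# exists).

peak_record <- function(label, center, power, mode = "automatic",
                        weak = FALSE) {
  list(label = label, center_frequency = center, max_power = power,
       detection_mode = mode, weak = weak)
}

argmax_peak <- function(freqs, vals, label, mode = "automatic") {
  i <- which.max(vals)                     # ties -> lowest frequency
  peak_record(label, freqs[i], vals[i], mode = mode,
              weak = all(vals <= 0))
}

#' Human periodic peaks Pk1 / Pk2
#'
#' Pk1 is the residual maximum below `split` (alpha range), Pk2 the maximum
#' above it (beta/gamma). A side whose residual never rises above zero is
#' still reported but flagged `weak`.
#'
#' @param per a `periodic_spectrum`.
#' @param split boundary frequency, Hz (default 15).
#' @return list with elements `Pk1` and `Pk2`.
#' @export
find_peaks_human <- function(per, split = 15) {
  stopifnot(inherits(per, "periodic_spectrum"))
  lo <- per$freqs < split
  hi <- per$freqs > split
  if (!any(lo) || !any(hi))
    stop_invalid("residual must cover both sides of ", split, " Hz")
  res <- list(Pk1 = argmax_peak(per$freqs[lo], per$residual[lo], "Pk1"),
              Pk2 = argmax_peak(per$freqs[hi], per$residual[hi], "Pk2"))
  for (p in res) if (p$weak)
    warning(p$label, ": residual non-positive over its whole window")
  res
}

smooth_residual <- function(freqs, residual, span) {
  nb <- max(3L, ceiling(span * length(freqs)))
  if (nb < 3L) stop_invalid("smoother span below 3 bins")
  lowess(freqs, residual, f = nb / length(freqs), iter = 0L)$y
}

#' Mouse surface-EEG periodic peak
#'
#' The single low-frequency peak: argmax of the locally-weighted-regression
#' smoothed residual below `upper`. Both the smoothed and the raw residual
#' value at the centre are recorded.
#'
#' @param per a `periodic_spectrum`.
#' @param upper search bound, Hz (default 10).
#' @param smooth_span smoother span as a fraction of the window's bins
#'   (default 0.25).
#' @return a peak record labelled `Pk1` with `max_power` from the smoothed
#'   curve and `raw_power` alongside.
#' @export
find_peak_mouse_surface <- function(per, upper = 10, smooth_span = 0.25) {
  stopifnot(inherits(per, "periodic_spectrum"))
  keep <- per$freqs <= upper
  if (sum(keep) < 3L) stop_invalid("residual does not cover (f_lo, ", upper, "] Hz")
  f <- per$freqs[keep]
  if (ceiling(smooth_span * length(f)) < 3L && smooth_span * length(f) < 3)
    stop_invalid("smoother span below 3 bins")
  sm <- smooth_residual(f, per$residual[keep], smooth_span)
  pk <- argmax_peak(f, sm, "Pk1")
  pk$raw_power <- per$residual[keep][which.max(sm)]
  pk
}

#' Mouse LFP sub-peaks Pk1a / Pk1b
#'
#' Within the 2-10 Hz residual, the smoothed curve's interior local minima
#' (3-9 Hz) are candidates for the split between the two sub-peaks; the
#' minimum with the greatest prominence (depth below the smaller flanking
#' smoothed maximum) is used. If no interior minimum exists the split falls
#' back to `fallback_split` and both peaks are flagged accordingly.
#'
#' @param per a `periodic_spectrum` covering 2-10 Hz.
#' @param smooth_span smoother span, fraction of window bins (default 0.25).
#' @param fallback_split split frequency when no local minimum is found, Hz.
#' @param interior `[lo, hi]` Hz window in which minima are searched.
#' @param minimum_rule `"prominence"` (default) or `"value"` (literal largest
#'   residual value among the local minima).
#' @return list with `Pk1a`, `Pk1b` and the `split` frequency used.
#' @export
find_subpeaks <- function(per, smooth_span = 0.25, fallback_split = 6,
                          interior = c(3, 9),
                          minimum_rule = c("prominence", "value")) {
  stopifnot(inherits(per, "periodic_spectrum"))
  minimum_rule <- match.arg(minimum_rule)
  keep <- per$freqs >= 2 - 1e-9 & per$freqs <= 10 + 1e-9
  if (sum(keep) < 5L) stop_invalid("residual must cover 2-10 Hz")
  f <- per$freqs[keep]; r <- per$residual[keep]
  sm <- smooth_residual(f, r, smooth_span)

  n <- length(f)
  mins <- integer()
  for (i in 2:(n - 1L))
    if (sm[i] < sm[i - 1L] && sm[i] <= sm[i + 1L] &&
        f[i] >= interior[1L] && f[i] <= interior[2L])
      mins <- c(mins, i)

  if (length(mins)) {
    score <- vapply(mins, function(i) {
      if (minimum_rule == "value") return(sm[i])
      left <- max(sm[1:(i - 1L)])
      right <- max(sm[(i + 1L):n])
      min(left, right) - sm[i]               # prominence
    }, 0)
    split_i <- mins[which.max(score)]
    split <- f[split_i]
    mode <- "automatic"
  } else {
    split <- fallback_split
    mode <- "fallback_split"
  }
  lo <- f < split
  hi <- f > split
  if (!any(lo) || !any(hi)) { # split at window edge: fall back
    split <- fallback_split; mode <- "fallback_split"
    lo <- f < split; hi <- f > split
  }
  list(Pk1a = argmax_peak(f[lo], r[lo], "Pk1a", mode = mode),
       Pk1b = argmax_peak(f[hi], r[hi], "Pk1b", mode = mode),
       split = split)
}
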