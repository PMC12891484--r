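# Data-driven Lorentzian decomposition of a log-log power spectrum into an
# aperiodic component y(f) = b - log10(k + f^(-m)) and a periodic residual.
# Two variants: a pure power law (k = 0, surface EEG) anchored at the low
# edge with the steepest admissible slope, and a knee variant (depth LFP)
# anchored at the high-frequency power minimum with the shallowest
# admissible slope plus low-frequency knee estimation. Both pick anchors so
# the fitted curve never cuts above the spectrum at the candidate
# frequencies, keeping periodic power non-negative there.

# mean log-power and mean log10-frequency over a bin and its available
# neighbours (1 or 2); using the mean log-frequency as the x-coordinate makes
# the fit exact on spectra of the model's own class.
neigh_xy <- function(freqs, lp, i) {
  idx <- intersect((i - 1L):(i + 1L), seq_along(freqs))
  list(x = mean(log10(freqs[idx])), y = mean(lp[idx]))
}

slice_spectrum <- function(ps, lo, hi) {
  keep <- which(ps$freqs >= lo - 1e-9 & ps$freqs <= hi + 1e-9)
  if (length(keep) < 3L)
    stop_invalid("spectrum does not cover [", lo, ", ", hi, "] Hz")
  list(freqs = ps$freqs[keep], lp = ps$log_power[keep])
}

new_aperiodic_fit <- function(variant, b, m, knee, f_lo, f_hi, anchors,
                              notch_gap = NULL, warnings = character()) {
  offset <- b - log10(knee + f_lo^(-m))
  structure(list(variant = variant, b = b, m = m, knee = knee,
                 offset = offset, fit_range = c(f_lo, f_hi),
                 anchors = anchors, notch_gap = notch_gap,
                 warnings = warnings),
            class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> %s: b = %.4g, m = %.4g, knee = %.4g, offset = %.4g [%g-%g Hz]\n",
              x$variant, x$b, x$m, x$knee, x$offset,
              x$fit_range[1L], x$fit_range[2L]))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Linear (knee-free) aperiodic fit
#'
#' Fits `log10 P = b + m log10 f` to a spectrum in log-log space. The low
#' anchor is the average power over the lowest 0.6 Hz of the fitting range;
#' the second point is the candidate frequency above `search_min` whose line
#' through the anchor has the largest slope magnitude — any shallower line
#' would cut through the spectrum and produce negative periodic power.
#' Candidate y-values average the candidate bin and its two neighbours.
#'
#' @param ps a [power_spectrum] (subject-level epoch average).
#' @param f_lo lower fit edge, Hz (2 for mouse surface EEG, 3 for human).
#' @param search_min candidates must lie above this frequency, Hz.
#' @param f_hi upper fit edge, Hz.
#' @return an `aperiodic_fit` with `variant = "linear"`, `knee = 0`.
#' @export
fit_aperiodic_linear <- function(ps, f_lo = 2, search_min = 8, f_hi = 55) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (f_hi <= search_min) stop_invalid("f_hi must exceed search_min")
  s <- slice_spectrum(ps, f_lo, f_hi)
  if (!all(is.finite(s$lp))) stop_invalid("non-finite log power in fit range")
  low <- which(s$freqs < f_lo + 0.6)
  if (!length(low)) stop_invalid("no bins in the lowest 0.6 Hz of the range")
  x1 <- mean(log10(s$freqs[low])); y1 <- mean(s$lp[low])
  cand <- which(s$freqs > search_min + 1e-9)
  if (!length(cand)) stop_invalid("no candidate frequencies above ", search_min, " Hz")
  slopes <- vapply(cand, function(i) {
    p <- neigh_xy(s$freqs, s$lp, i)
    (p$y - y1) / (p$x - x1)
  }, 0)
  pick <- cand[which.max(abs(slopes))]          # ties -> lowest frequency
  m <- slopes[match(pick, cand)]
  b <- y1 - m * x1
  pa <- neigh_xy(s$freqs, s$lp, pick)
  warn <- if (m >= 0) "non-negative slope: spectrum does not decay over the search range" else character()
  if (length(warn)) warning(warn)
  new_aperiodic_fit("linear", b, m, 0, f_lo, f_hi,
                    anchors = data.frame(freq = c(10^x1, 10^pa$x),
                                         log_power = c(y1, pa$y)),
                    warnings = warn)
}

#' Knee-variant aperiodic fit
#'
#' Fits the full Lorentzian `log10 P = b - log10(k + f^(-m))`. The slope is
#' estimated from the high-frequency end: the first anchor is the frequency
#' with the lowest absolute power up to `hi_search_max` (skipping
#' `notch_gap` when mains filtering leaves a hole), and the second is the
#' candidate in `mid_search` whose line through that anchor is shallowest —
#' steeper lines would cut through the spectrum. The knee is then the mean of
#' `k = 10^(b - y) - x^(-m)` over local minima of log power inside
#' `knee_search` that fall below the line.
#'
#' @param ps a [power_spectrum].
#' @param f_lo lower fit edge, Hz.
#' @param hi_search_max upper fit edge / anchor search bound, Hz.
#' @param notch_gap optional `[lo, hi]` Hz band excluded from the anchor
#'   search (e.g. `c(45, 75)` around a mains notch), or `NULL`.
#' @param mid_search `[lo, hi]` Hz window for the slope candidate.
#' @param knee_search `[lo, hi]` Hz window for knee local minima.
#' @return an `aperiodic_fit` with `variant = "knee"`.
#' @export
fit_aperiodic_knee <- function(ps, f_lo = 1.5, hi_search_max = 175,
                               notch_gap = NULL, mid_search = c(9, 25),
                               knee_search = c(1.5, 2.24)) {
  stopifnot(inherits(ps, "power_spectrum"))
  s <- slice_spectrum(ps, f_lo, hi_search_max)
  if (!all(is.finite(s$lp))) stop_invalid("non-finite log power in fit range")
  warns <- character()

  hi_ok <- rep(TRUE, length(s$freqs))
  if (!is.null(notch_gap))
    hi_ok[s$freqs >= notch_gap[1L] & s$freqs <= notch_gap[2L]] <- FALSE
  i1 <- which(hi_ok)[which.min(s$lp[hi_ok])]
  p1 <- neigh_xy(s$freqs, s$lp, i1)

  cand <- which(s$freqs >= mid_search[1L] - 1e-9 &
                s$freqs <= mid_search[2L] + 1e-9)
  if (!length(cand)) stop_invalid("no slope candidates in mid_search window")
  slopes <- vapply(cand, function(i) {
    p <- neigh_xy(s$freqs, s$lp, i)
    (p1$y - p$y) / (p1$x - p$x)
  }, 0)
  pick <- cand[which.min(abs(slopes))]          # ties -> lowest frequency
  m <- slopes[match(pick, cand)]
  b <- p1$y - m * p1$x
  p2 <- neigh_xy(s$freqs, s$lp, pick)

  kb <- which(s$freqs >= knee_search[1L] - 1e-9 &
              s$freqs <= knee_search[2L] + 1e-9)
  below_line <- s$lp[kb] < b + m * log10(s$freqs[kb])
  is_min <- vapply(kb, function(i) {
    i > 1L && i < length(s$freqs) &&
      s$lp[i] < s$lp[i - 1L] && s$lp[i] <= s$lp[i + 1L]
  }, TRUE)
  use <- kb[is_min & below_line]
  if (!length(use) && any(below_line)) {
    # smooth/monotone spectra have no interior local minimum in the knee
    # window; every below-line bin then contributes a knee estimate
    use <- kb[below_line]
  }
  kvals <- 10^(b - s$lp[use]) - s$freqs[use]^(-m)
  kx <- s$freqs[use]; ky <- s$lp[use]
  if (!length(kvals)) {
    knee <- 0
    warns <- c(warns, "no valid knee candidate below the linear estimate; knee set to 0")
    warning(tail(warns, 1L))
  } else {
    knee <- mean(kvals)
    if (knee < 0) {
      knee <- 0
      warns <- c(warns, "negative mean knee estimate clamped to 0")
      warning(tail(warns, 1L))
    }
  }
  if (m >= 0) {
    warns <- c(warns, "non-negative slope: spectrum does not decay over the fit range")
    warning(tail(warns, 1L))
  }
  new_aperiodic_fit("knee", b, m, knee, f_lo, hi_search_max,
                    anchors = data.frame(freq = c(10^p1$x, 10^p2$x, kx),
                                         log_power = c(p1$y, p2$y, ky)),
                    notch_gap = notch_gap, warnings = warns)
}

#' Evaluate an aperiodic fit
#'
#' `y(f) = b - log10(knee + f^(-m))`; with `knee = 0` this is exactly
#' `b + m * log10(f)`.
#'
#' @param fit an `aperiodic_fit`.
#' @param freqs frequencies, Hz (all > 0).
#' @return log10-power values of the aperiodic model.
#' @export
aperiodic_eval <- function(fit, freqs) {
  stopifnot(inherits(fit, "aperiodic_fit"))
  if (any(freqs <= 0)) stop_invalid("frequencies must be > 0")
  if (fit$knee == 0) fit$b + fit$m * log10(freqs)
  else fit$b - log10(fit$knee + freqs^(-fit$m))
}

#' Subtract the aperiodic fit to obtain the periodic spectrum
#'
#' @param ps a [power_spectrum].
#' @param fit an `aperiodic_fit` covering the spectrum's grid.
#' @param restrict if `TRUE` (default) the residual is computed on the bins
#'   inside the fit range; if `FALSE`, bins outside the range are an error.
#' @return a `periodic_spectrum` with fields `freqs`, `residual` (log10-power
#'   difference) and the parent `fit`.
#' @export
subtract_aperiodic <- function(ps, fit, restrict = TRUE) {
  stopifnot(inherits(ps, "power_spectrum"), inherits(fit, "aperiodic_fit"))
  inside <- ps$freqs >= fit$fit_range[1L] - 1e-9 &
            ps$freqs <= fit$fit_range[2L] + 1e-9
  if (restrict) {
    if (!any(inside)) stop_invalid("spectrum grid does not intersect fit range")
    f <- ps$freqs[inside]; lp <- ps$log_power[inside]
  } else {
    if (!all(inside)) stop_invalid("spectrum grid extends outside fit range")
    f <- ps$freqs; lp <- ps$log_power
  }
  structure(list(freqs = f, residual = lp - aperiodic_eval(fit, f), fit = fit),
            class = "periodic_spectrum")
}

#' @export
print.periodic_spectrum <- function(x, ...) {
  cat(sprintf("<periodic_spectrum> %g-%g Hz, max residual %.3g at %g Hz\n",
              min(x$freqs), max(x$freqs), max(x$residual),
              x$freqs[which.max(x$residual)]))
  invisible(x)
}

#' Serialize an aperiodic fit to JSON
#'
#' @param fit an `aperiodic_fit`.
#' @param path optional path; when `NULL` the JSON string is returned.
#' @export
write_aperiodic_fit <- function(fit, path = NULL) {
  obj <- list(variant = fit$variant, b = fit$b, m = fit$m, knee = fit$knee,
              offset = fit$offset, fit_range = fit$fit_range,
              anchors = fit$anchors, notch_gap = fit$notch_gap,
              warnings = fit$warnings)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
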