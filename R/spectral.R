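#' Multitaper parameters from spectral resolution
#'
#' Calibrates the time-bandwidth product from the desired spectral
#' resolution `FR` (full bandwidth, Hz) and the segment length:
#' `TW = (FR * segment_length) / 2`, with `K = 2 * TW - 1` tapers (rounded
#' down). This is how a 2 Hz resolution is kept consistent across 2 s human
#' segments (TW 2, 3 tapers) and 5 s mouse segments (TW 5, 9 tapers); the
#' 1 Hz sub-peak pass gives TW 2.5 with 4 tapers.
#'
#' @param FR spectral resolution (full bandwidth), Hz.
#' @param segment_length seconds.
#' @param K optional explicit taper-count override.
#' @return a `taper_params` list with fields `FR`, `segment_length`, `TW`, `K`.
#' @export
taper_params <- function(FR, segment_length, K = NULL) {
  assert_scalar_num(FR, "FR", positive = TRUE)
  assert_scalar_num(segment_length, "segment_length", positive = TRUE)
  TW <- (FR * segment_length) / 2
  if (is.null(K)) K <- floor(2 * TW - 1)
  K <- as.integer(K)
  if (K < 1L)
    stop_invalid("resolution too fine for segment: K = ", K, " tapers")
  structure(list(FR = FR, segment_length = segment_length, TW = TW, K = K),
            class = "taper_params")
}

#' Multitaper parameters from an explicit time-bandwidth product
#'
#' @param TW time-bandwidth product.
#' @param segment_length seconds.
#' @param K optional taper count (default `2*TW - 1`).
#' @return a `taper_params` list; `FR = 2*TW/segment_length`.
#' @export
taper_params_tw <- function(TW, segment_length, K = NULL) {
  taper_params(2 * TW / segment_length, segment_length, K = K)
}

#' Power spectrum container
#'
#' Ascending frequency grid with linear power (µV²/Hz) and its log10 view,
#' plus resolution metadata.
#'
#' @param freqs strictly increasing frequencies, Hz.
#' @param power linear power values (> 0 wherever log power is used).
#' @param bin_width grid step, Hz.
#' @param n_epochs_averaged how many epochs the spectrum averages.
#' @param taper optional [taper_params] provenance.
#' @param interpolated whether the grid was interpolated.
#' @export
power_spectrum <- function(freqs, power, bin_width, n_epochs_averaged = 1L,
                           taper = NULL, interpolated = FALSE) {
  if (is.unsorted(freqs, strictly = TRUE)) stop_invalid("freqs must be strictly increasing")
  structure(list(freqs = freqs, power = power,
                 log_power = log10(power), bin_width = bin_width,
                 n_epochs_averaged = n_epochs_averaged, taper = taper,
                 interpolated = interpolated),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %g-%g Hz, bin %g Hz, %d epoch(s)%s\n",
              min(x$freqs), max(x$freqs), x$bin_width, x$n_epochs_averaged,
              if (x$interpolated) ", interpolated" else ""))
  invisible(x)
}

#' Multitaper power spectral density of an epoch set
#'
#' Per-epoch PSDs from Slepian tapers (no zero padding), averaged across
#' tapers, then the cohort-facing spectrum as the arithmetic mean of the
#' included epochs' linear power. One-sided density in µV²/Hz; the bin width
#' equals `1/segment_length`.
#'
#' @param es an [epoch_set].
#' @param tp a [taper_params].
#' @param fmax optional upper frequency bound for the returned grid, Hz.
#' @return list with `averaged` ([power_spectrum] over included epochs) and
#'   `per_epoch` (linear-power matrix, one column per epoch, all epochs).
#' @export
multitaper_psd <- function(es, tp, fmax = NULL) {
  stopifnot(inherits(es, "epoch_set"), inherits(tp, "taper_params"))
  if (sum(es$included) < 1L) stop_invalid("no included epochs")
  n <- nrow(es$epochs)
  fs <- es$sampling_rate
  if (tp$K >= 2 * tp$TW + 1)
    stop_invalid("K = ", tp$K, " exceeds usable taper count for TW = ", tp$TW)
  H <- dpss_tapers(n, tp$TW, tp$K)
  nh <- n %/% 2L + 1L
  freqs <- (seq_len(nh) - 1L) / es$segment_length
  keep <- if (is.null(fmax)) seq_len(nh) else which(freqs <= fmax + 1e-9)
  scale <- c(1, rep(2, nh - 2L), if (n %% 2L == 0L) 1 else 2)[keep] / fs
  per <- matrix(0, length(keep), n_epochs(es))
  for (j in seq_len(n_epochs(es))) {
    x <- es$epochs[, j]
    acc <- numeric(length(keep))
    for (k in seq_len(tp$K)) {
      X <- fft(x * H[, k])
      acc <- acc + Mod(X[keep])^2
    }
    per[, j] <- acc / tp$K * scale
  }
  avg <- rowMeans(per[, es$included, drop = FALSE])
  list(averaged = power_spectrum(freqs[keep], avg,
                                 bin_width = 1 / es$segment_length,
                                 n_epochs_averaged = sum(es$included),
                                 taper = tp),
       per_epoch = per, freqs = freqs[keep])
}

#' Average spectra on a common grid
#'
#' Element-wise (optionally weighted) mean of linear power; log power is
#' recomputed from the mean. Used for epoch, electrode and ROI averaging.
#'
#' @param spectra list of [power_spectrum] objects with identical grids.
#' @param weights optional numeric weights, one per spectrum.
#' @return a [power_spectrum].
#' @export
average_spectra <- function(spectra, weights = NULL) {
  stopifnot(length(spectra) >= 1L)
  f0 <- spectra[[1L]]$freqs
  for (s in spectra)
    if (length(s$freqs) != length(f0) || any(abs(s$freqs - f0) > 1e-9))
      stop_invalid("spectra are on different frequency grids")
  if (is.null(weights)) weights <- rep(1, length(spectra))
  weights <- weights / sum(weights)
  p <- Reduce(`+`, Map(function(s, w) s$power * w, spectra, weights))
  power_spectrum(f0, p, spectra[[1L]]$bin_width,
                 n_epochs_averaged = sum(vapply(spectra, `[[`, 0L,
                                               "n_epochs_averaged")),
                 taper = spectra[[1L]]$taper,
                 interpolated = spectra[[1L]]$interpolated)
}

#' Interpolate a spectrum onto a finer grid
#'
#' Linear interpolation of log10 power onto a finer regular grid (e.g. the
#' 0.1 Hz bins used for pediatric subjects); native-grid values are
#' reproduced exactly at native bins.
#'
#' @param ps a [power_spectrum].
#' @param target_bin new bin width, Hz; must be finer than the native bin.
#' @return a [power_spectrum] with the `interpolated` flag set.
#' @export
interpolate_psd <- function(ps, target_bin = 0.1) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (target_bin >= ps$bin_width - 1e-12)
    stop_invalid("target bin ", target_bin, " Hz is not finer than native ",
                 ps$bin_width, " Hz")
  grid <- seq(ps$freqs[1L], ps$freqs[length(ps$freqs)], by = target_bin)
  lp <- approx(ps$freqs, ps$log_power, xout = grid)$y
  power_spectrum(grid, 10^lp, target_bin,
                 n_epochs_averaged = ps$n_epochs_averaged, taper = ps$taper,
                 interpolated = TRUE)
}

#' Write / read the spectrum TSV interchange format
#'
#' Columns `frequency_hz`, `power`, `log10_power` preceded by `#` metadata
#' header lines (taper settings, epoch count, interpolation flag).
#'
#' @param ps a [power_spectrum].
#' @param path file path.
#' @export
write_spectrum <- function(ps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tp <- ps$taper
  writeLines(c(sprintf("# bin_width_hz=%g", ps$bin_width),
               sprintf("# n_epochs=%d", ps$n_epochs_averaged),
               sprintf("# interpolated=%d", as.integer(ps$interpolated)),
               if (!is.null(tp)) sprintf("# TW=%g K=%d", tp$TW, tp$K),
               "frequency_hz\tpower\tlog10_power"), con)
  writeLines(sprintf("%.10g\t%.10g\t%.10g", ps$freqs, ps$power, ps$log_power),
             con)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")][-1L]
  m <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  bw <- as.numeric(sub(".*=", "", grep("bin_width", meta, value = TRUE)[1L]))
  interp <- grepl("interpolated=1", paste(meta, collapse = " "))
  power_spectrum(m[, 1L], m[, 2L], bw, interpolated = interp)
}
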