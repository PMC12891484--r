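#' Phase/amplitude band grid for comodulograms
#'
#' Six 2 Hz-wide phase bands with centres stepping 1 Hz inside 2-9 Hz
#' (centres 3-8 Hz) and twenty-six 4 Hz-wide amplitude bands with centres
#' stepping 2 Hz whose lower edges span the 10-60 Hz region (centres
#' 12-62 Hz) — the only placements consistent with the stated band counts.
#'
#' @return list with `phase_bands` (6 x 2) and `amp_bands` (26 x 2) matrices
#'   of band edges in Hz plus centre vectors.
#' @export
pac_band_grid <- function() {
  pc <- 3:8
  ac <- seq(12, 62, by = 2)
  list(phase_bands = cbind(low = pc - 1, high = pc + 1),
       amp_bands = cbind(low = ac - 2, high = ac + 2),
       phase_centers = pc, amp_centers = ac)
}

#' Band-passed analytic signal
#'
#' Zero-phase (two-pass) least-squares FIR band-pass followed by the Hilbert
#' transform. The filter order is three cycles of the band's low edge,
#' mirroring the common EEG filtering routine.
#'
#' @param x numeric samples.
#' @param sampling_rate Hz.
#' @param band `[low, high]` Hz.
#' @param h optional pre-designed filter coefficients (for reuse over epochs).
#' @return list with `amplitude` (envelope) and `phase` (radians, (-pi, pi]).
#' @export
bandpass_analytic <- function(x, sampling_rate, band, h = NULL) {
  if (is.null(h)) h <- fir_bandpass(sampling_rate, band[1L], band[2L])
  xf <- fir_filtfilt(x, h)
  a <- hilbert_analytic(xf)
  list(amplitude = Mod(a), phase = Arg(a))
}

#' 18-bin phase-amplitude distribution
#'
#' Mean amplitude within each of `n_bins` equal phase bins on (-pi, pi],
#' normalized to sum to one. Empty bins contribute zero before
#' normalization.
#'
#' @param phase phase sequence, radians.
#' @param amplitude amplitude sequence, same length.
#' @param n_bins number of phase bins (default 18).
#' @return list with `PA` (probabilities), `bin_edges`, `bin_centers`.
#' @export
phase_amp_distribution <- function(phase, amplitude, n_bins = 18L) {
  if (length(phase) != length(amplitude))
    stop_invalid("phase and amplitude must have equal length")
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  idx <- findInterval(phase, edges, left.open = TRUE, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L          # phase == -pi lands in the first bin
  idx[idx > n_bins] <- n_bins
  sums <- numeric(n_bins)
  cnts <- tabulate(idx, n_bins)
  agg <- rowsum(amplitude, idx)
  sums[as.integer(rownames(agg))] <- agg
  means <- ifelse(cnts > 0, sums / pmax(cnts, 1L), 0)
  tot <- sum(means)
  if (tot <= 0) {
    warning("all-zero amplitude: uniform phase-amplitude distribution returned")
    means <- rep(1, n_bins)
    tot <- n_bins
  }
  list(PA = means / tot, bin_edges = edges,
       bin_centers = (edges[-1L] + edges[-(n_bins + 1L)]) / 2)
}

#' Modulation index of a phase-amplitude distribution
#'
#' Normalized entropy deficit `MI = (log N - H) / log N` with
#' `H = -sum PA_j log PA_j` (taking `0 log 0 = 0`). 0 for a uniform
#' distribution (no coupling), 1 when all amplitude concentrates in a single
#' phase bin; invariant to the logarithm base and to amplitude rescaling.
#'
#' @param pa a [phase_amp_distribution] result (or a bare probability vector).
#' @return MI in `[0, 1]`.
#' @export
modulation_index <- function(pa) {
  p <- if (is.list(pa)) pa$PA else pa
  if (abs(sum(p) - 1) > 1e-9) stop_invalid("PA must sum to 1")
  N <- length(p)
  nz <- p > 0
  H <- -sum(p[nz] * log(p[nz]))
  (log(N) - H) / log(N)
}

pac_filters <- function(sampling_rate, grid) {
  list(phase = apply(grid$phase_bands, 1L, function(b)
         fir_bandpass(sampling_rate, b[1L], b[2L]), simplify = FALSE),
       amp = apply(grid$amp_bands, 1L, function(b)
         fir_bandpass(sampling_rate, b[1L], b[2L]), simplify = FALSE))
}

epoch_band_signals <- function(es, grid, filters) {
  lapply(seq_len(n_epochs(es)), function(j) {
    x <- es$epochs[, j]
    list(phase = lapply(filters$phase, function(h)
           bandpass_analytic(x, es$sampling_rate, NULL, h = h)$phase),
         amp = lapply(filters$amp, function(h)
           bandpass_analytic(x, es$sampling_rate, NULL, h = h)$amplitude))
  })
}

mi_matrix <- function(phases, amps, grid, n_bins = 18L) {
  M <- matrix(0, length(phases), length(amps),
              dimnames = list(grid$phase_centers, grid$amp_centers))
  for (i in seq_along(phases))
    for (j in seq_along(amps))
      M[i, j] <- modulation_index(phase_amp_distribution(phases[[i]],
                                                         amps[[j]], n_bins))
  M
}

#' Per-epoch comodulograms
#'
#' For every included epoch, the 6 x 26 matrix of modulation indices over
#' all (phase band, amplitude band) pairs of the grid.
#'
#' @param es an [epoch_set] (5 s epochs in the reference analysis).
#' @param grid a [pac_band_grid].
#' @return list of 6 x 26 MI matrices, one per included epoch.
#' @export
comodulogram <- function(es, grid = pac_band_grid()) {
  stopifnot(inherits(es, "epoch_set"))
  filters <- pac_filters(es$sampling_rate, grid)
  sig <- epoch_band_signals(es, grid, filters)
  inc <- which(es$included)
  lapply(inc, function(j) mi_matrix(sig[[j]]$phase, sig[[j]]$amp, grid))
}

#' Epoch-shuffled noise comodulograms
#'
#' Destroys phase-amplitude alignment by pairing the phase signals of one
#' epoch with the amplitude signals of a different epoch (never the same),
#' yielding the chance-level MI against which true comodulograms are
#' noise-subtracted.
#'
#' @param es an [epoch_set] with at least two included epochs.
#' @param grid a [pac_band_grid].
#' @param pairing optional integer vector: `pairing[i]` is the amplitude
#'   epoch matched to phase epoch `i` (positions in the included-epoch list;
#'   no self-pairs). Randomly drawn when `NULL`.
#' @param seed RNG seed for the random pairing.
#' @return list with `mi` (per-pair MI matrices) and `pairing`.
#' @export
noise_comodulogram <- function(es, grid = pac_band_grid(), pairing = NULL,
                               seed = NULL) {
  stopifnot(inherits(es, "epoch_set"))
  inc <- which(es$included)
  ne <- length(inc)
  if (ne < 2L) stop_invalid("need >= 2 included epochs to shuffle")
  if (is.null(pairing)) {
    pairing <- with_seed(seed, vapply(seq_len(ne), function(i)
      sample(setdiff(seq_len(ne), i), 1L), 0L))
  }
  if (any(pairing == seq_along(pairing)))
    stop_invalid("pairing maps an epoch to itself")
  filters <- pac_filters(es$sampling_rate, grid)
  sig <- epoch_band_signals(es, grid, filters)
  mi <- lapply(seq_len(ne), function(i)
    mi_matrix(sig[[inc[i]]]$phase, sig[[inc[pairing[i]]]]$amp, grid))
  list(mi = mi, pairing = pairing)
}

#' Write a comodulogram matrix as TSV
#'
#' Rows are phase-band centres, columns amplitude-band centres.
#'
#' @param M an MI matrix (rows phase, columns amplitude).
#' @param path output path.
#' @export
write_comodulogram <- function(M, path) {
  df <- data.frame(phase_hz = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
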