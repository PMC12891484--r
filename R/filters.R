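# Filtering primitives: linear-phase least-squares FIR design, zero-phase
# (forward-backward) application, a biquad notch, and the analytic signal.
# These exist because no DSP package ships with the target stack; designs
# follow the textbook normal-equation route and are oracle-checked in tests.

# Least-squares linear-phase FIR (type I: even order, symmetric).
# bands: normalized edge pairs in [0, 1] (1 = Nyquist), desired: amplitude at
# each edge (piecewise linear inside each band, "don't care" between bands).
firls_design <- function(order, bands, desired) {
  if (order %% 2L != 0L) stop_invalid("firls order must be even (type I)")
  if (length(bands) %% 2L != 0L || length(bands) != length(desired))
    stop_invalid("bands/desired must be matched edge pairs")
  if (any(diff(bands) < 0) || any(bands < 0) || any(bands > 1))
    stop_invalid("band edges must be non-decreasing within [0, 1]")
  M <- order / 2L
  w <- matrix(bands * pi, nrow = 2L)   # columns = bands, radians
  nb <- ncol(w)
  d <- matrix(desired, nrow = 2L)

  # int cos(j w) dw  and  int w cos(j w) dw on [lo, hi]
  ic <- function(j, lo, hi) {
    if (j == 0) hi - lo else (sin(j * hi) - sin(j * lo)) / j
  }
  iwc <- function(j, lo, hi) {
    if (j == 0) (hi^2 - lo^2) / 2
    else (cos(j * hi) - cos(j * lo)) / j^2 + (hi * sin(j * hi) - lo * sin(j * lo)) / j
  }

  G <- matrix(0, M + 1L, M + 1L)
  rhs <- numeric(M + 1L)
  for (bnd in seq_len(nb)) {
    lo <- w[1L, bnd]; hi <- w[2L, bnd]
    if (hi <= lo) next
    d0 <- d[1L, bnd]
    slope <- if (hi > lo) (d[2L, bnd] - d[1L, bnd]) / (hi - lo) else 0
    for (j in 0:M) {
      rhs[j + 1L] <- rhs[j + 1L] +
        (d0 - slope * lo) * ic(j, lo, hi) + slope * iwc(j, lo, hi)
      for (k in j:M) {
        v <- 0.5 * (ic(j - k, lo, hi) + ic(j + k, lo, hi))
        G[j + 1L, k + 1L] <- G[j + 1L, k + 1L] + v
        if (k > j) G[k + 1L, j + 1L] <- G[k + 1L, j + 1L] + v
      }
    }
  }
  cf <- solve(G, rhs)
  h <- c(rev(cf[-1L] / 2), cf[1L], cf[-1L] / 2)
  h
}

# Band-pass design in Hz mirroring the common EEG filtering routine:
# order = 3 cycles of the low edge, 15% transition bands.
fir_bandpass <- function(sampling_rate, low, high, trans = 0.15,
                         order = NULL) {
  nyq <- sampling_rate / 2
  if (low <= 0 || high >= nyq || low >= high)
    stop_invalid("band [", low, ", ", high, "] Hz outside (0, Nyquist)")
  if (is.null(order)) order <- 3L * floor(sampling_rate / low)
  order <- as.integer(order)
  if (order %% 2L != 0L) order <- order + 1L
  f <- c(0, (1 - trans) * low, low, high, min((1 + trans) * high, nyq), nyq) / nyq
  f <- pmin(pmax(f, 0), 1)
  # guard degenerate transition bands at the Nyquist end
  if (f[5] >= f[6]) f[5] <- (f[4] + f[6]) / 2
  firls_design(order, f, c(0, 0, 1, 1, 0, 0))
}

fft_conv_full <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- nextn(n, c(2, 3, 5))
  y <- Re(fft(fft(c(x, numeric(nf - length(x)))) *
             fft(c(h, numeric(nf - length(h)))), inverse = TRUE)) / nf
  y[seq_len(n)]
}

# Zero-phase two-pass FIR filtering with reflective (odd) end extension.
fir_filtfilt <- function(x, h) {
  n <- length(x)
  L <- length(h)
  if (n <= 3L * L) stop_invalid("signal shorter than 3 filter lengths (",
                                3L * L, " samples needed, got ", n, ")")
  pad <- L
  xe <- c(2 * x[1L] - rev(x[2:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  one_pass <- function(v) {
    y <- fft_conv_full(v, h)
    y[(L - 1L) %/% 2L + seq_along(v)]       # "same" alignment, centre of h
  }
  y <- rev(one_pass(rev(one_pass(xe))))
  y[pad + seq_len(n)]
}

# Second-order IIR notch (biquad), MATLAB iirnotch convention:
# w0 and bw are fractions of Nyquist; -3 dB bandwidth = bw.
iir_notch_coef <- function(w0, bw) {
  if (w0 <= 0 || w0 >= 1) stop_invalid("notch centre outside (0, Nyquist)")
  if (bw <= 0) stop_invalid("notch bandwidth must be > 0")
  g <- 1 / (1 + tan(pi * bw / 2))
  list(b = g * c(1, -2 * cos(pi * w0), 1),
       a = c(1, -2 * g * cos(pi * w0), 2 * g - 1))
}

iir_filter <- function(x, b, a) {
  v <- fft_conv_full(x, b)[seq_along(x)]         # MA part (causal)
  as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
}

# Zero-phase IIR: forward-backward with odd extension at both ends.
iir_filtfilt <- function(x, b, a, pad = 200L) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xe <- c(2 * x[1L] - rev(x[2:(pad + 1L)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1L)]))
  y <- iir_filter(xe, b, a)
  y <- rev(iir_filter(rev(y), b, a))
  y[pad + seq_len(n)]
}

# Analytic signal via the FFT construction.
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  mult <- numeric(n)
  if (n %% 2L == 0L) {
    mult[1L] <- 1; mult[n / 2 + 1L] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[1L] <- 1
    mult[2:((n + 1L) / 2)] <- 2
  }
  fft(X * mult, inverse = TRUE) / n
}
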