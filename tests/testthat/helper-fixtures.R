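# shared fixtures: everything is generated in code at test time

fix_seed <- 20260910L

# canonical mouse-style aperiodic world (fast to synthesize at 500 Hz)
mouse_cfg <- function(duration = 100, seed = 1L, knee = 0, b = 1.5, m = -2,
                      peaks = list()) {
  sim_config(500, duration, aperiodic = list(b = b, m = m, knee = knee),
             peaks = peaks, seed = seed)
}

# spectrum of an exact aperiodic model on a regular grid
model_spectrum <- function(b, m, knee = 0, lo = 1.5, hi = 175, by = 0.2) {
  f <- seq(lo, hi, by = by)
  power_spectrum(f, 10^(b - log10(knee + f^(-m))), by)
}

# constructed periodic residual from a bump list: list(center, height, sd)
residual_spectrum <- function(bumps, lo = 2, hi = 55, by = 0.2) {
  f <- seq(lo, hi, by = by)
  r <- numeric(length(f))
  for (bp in bumps) r <- r + bp$height * exp(-(f - bp$center)^2 / (2 * bp$sd^2))
  fit <- structure(list(variant = "linear", b = 0, m = 0, knee = 0,
                        offset = 0, fit_range = c(lo, hi),
                        anchors = NULL, warnings = character()),
                   class = "aperiodic_fit")
  structure(list(freqs = f, residual = r, fit = fit),
            class = "periodic_spectrum")
}
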