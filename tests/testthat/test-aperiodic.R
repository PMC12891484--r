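test_that("aperiodic_eval arithmetic", {
  lin <- structure(list(variant = "linear", b = 3, m = -2, knee = 0),
                   class = "aperiodic_fit")
  expect_equal(aperiodic_eval(lin, 10), 1.0)
  kn <- structure(list(variant = "knee", b = 0, m = -2, knee = 99),
                  class = "aperiodic_fit")
  expect_equal(aperiodic_eval(kn, 1), -2)
  # knee curve approaches the knee-free line at high frequency
  kn2 <- structure(list(variant = "knee", b = 2, m = -2, knee = 25),
                   class = "aperiodic_fit")
  ln2 <- structure(list(variant = "linear", b = 2, m = -2, knee = 0),
                   class = "aperiodic_fit")
  expect_lt(abs(aperiodic_eval(kn2, 1000) - aperiodic_eval(ln2, 1000)), 0.01)
  expect_error(aperiodic_eval(lin, c(10, -1)), "> 0")
})

test_that("linear fit is exact on its own model class", {
  ps <- model_spectrum(3, -2, lo = 2, hi = 55)
  fit <- fit_aperiodic_linear(ps, f_lo = 2, f_hi = 55)
  expect_equal(fit$m, -2, tolerance = 1e-9)
  expect_equal(fit$b, 3, tolerance = 1e-9)
  expect_equal(fit$knee, 0)
  expect_equal(fit$offset, 3 - 2 * log10(2), tolerance = 1e-9)
  # flat spectrum -> m = 0 (tie broken toward the lowest candidate)
  flat <- power_spectrum(seq(2, 55, 0.2), rep(10, length(seq(2, 55, 0.2))), 0.2)
  expect_equal(suppressWarnings(fit_aperiodic_linear(flat, 2, f_hi = 55))$m,
               0, tolerance = 1e-12)
  expect_error(fit_aperiodic_linear(ps, f_lo = 2, search_min = 8, f_hi = 7),
               "exceed")
})

test_that("knee fit recovers in-range knees and clamps degenerate ones", {
  # knee frequency (2 Hz) inside the 1.5-2.24 Hz search window
  expect_silent(fit4 <- fit_aperiodic_knee(model_spectrum(4, -2, knee = 4)))
  expect_equal(fit4$m, -2, tolerance = 0.1)
  expect_equal(fit4$knee, 4, tolerance = 4 * 0.2)
  # large knee: log10 k within the +/-0.3 loop-closure band
  expect_silent(fit25 <- fit_aperiodic_knee(model_spectrum(4, -2, knee = 25)))
  expect_equal(fit25$m, -2, tolerance = 0.1)
  expect_lt(abs(log10(fit25$knee) - log10(25)), 0.3)
  expect_equal(fit25$offset,
               fit25$b - log10(fit25$knee + 1.5^(-fit25$m)), tolerance = 1e-12)
  # pure line input: knee candidates fail the below-line test -> knee = 0
  expect_warning(fit0 <- fit_aperiodic_knee(model_spectrum(4, -2, knee = 0)),
                 "knee")
  expect_equal(fit0$knee, 0)
  expect_equal(fit0$m, -2, tolerance = 1e-6)
  expect_equal(fit0$b, 4, tolerance = 1e-6)
})

test_that("notch gap is skipped in the high-anchor search", {
  ps <- model_spectrum(4, -2, knee = 4)
  dip <- ps$freqs >= 55 & ps$freqs <= 65      # notch hole, artificially low
  ps$power[dip] <- ps$power[dip] * 1e-3
  ps$log_power <- log10(ps$power)
  fit <- fit_aperiodic_knee(ps, notch_gap = c(45, 75))
  expect_gt(fit$anchors$freq[1], 75)          # anchor jumped past the hole
  expect_equal(fit$m, -2, tolerance = 0.1)
})

test_that("subtraction yields the periodic residual", {
  ps <- model_spectrum(3, -2, lo = 2, hi = 55)
  fit <- fit_aperiodic_linear(ps, 2, f_hi = 55)
  per <- subtract_aperiodic(ps, fit)
  expect_lt(max(abs(per$residual)), 1e-9)     # spectrum equals its own fit
  # injected bump on a known line recovers its height
  f <- ps$freqs
  bump <- 0.4 * exp(-(f - 10)^2 / (2 * 0.6^2))
  ps2 <- power_spectrum(f, 10^(ps$log_power + bump), 0.2)
  per2 <- subtract_aperiodic(ps2, fit_aperiodic_linear(ps2, 2, f_hi = 55))
  expect_equal(max(per2$residual), 0.4, tolerance = 0.1)
  expect_equal(per2$freqs[which.max(per2$residual)], 10, tolerance = 0.4)
  outside <- power_spectrum(seq(60, 80, 0.2), rep(1, 101), 0.2)
  expect_error(subtract_aperiodic(outside, fit), "intersect")
})

test_that("non-negativity: fitted curve never cuts above candidate points", {
  # property over random synthetic spectra, both variants
  set.seed(fix_seed)
  worst_lin <- worst_knee <- Inf
  for (i in 1:50) {
    b <- runif(1, 0.5, 3); m <- runif(1, -3, -0.8)
    f <- seq(2, 55, by = 0.2)
    lp <- b + m * log10(f) + 0.05 * rnorm(length(f)) +
      runif(1, 0, 0.6) * exp(-(f - runif(1, 4, 12))^2 / 2)
    ps <- power_spectrum(f, 10^lp, 0.2)
    fit <- fit_aperiodic_linear(ps, 2, f_hi = 55)
    cand <- which(f > 8)
    y <- vapply(cand, function(j) {
      idx <- intersect((j - 1):(j + 1), seq_along(f))
      mean(lp[idx]) - aperiodic_eval(fit, 10^mean(log10(f[idx])))
    }, 0)
    worst_lin <- min(worst_lin, min(y))

    fk <- seq(1.5, 175, by = 0.5)
    kn <- runif(1, 2, 30)
    lpk <- b + 1 - log10(kn + fk^(-m)) + 0.05 * rnorm(length(fk)) +
      runif(1, 0, 0.5) * exp(-(fk - runif(1, 3, 8))^2 / 2)
    psk <- power_spectrum(fk, 10^lpk, 0.5)
    fitk <- suppressWarnings(fit_aperiodic_knee(psk))
    candk <- which(fk >= 9 & fk <= 25)
    yk <- vapply(candk, function(j) {
      idx <- intersect((j - 1):(j + 1), seq_along(fk))
      mean(lpk[idx]) - aperiodic_eval(fitk, 10^mean(log10(fk[idx])))
    }, 0)
    worst_knee <- min(worst_knee, min(yk))
  }
  expect_gt(worst_lin, -1e-9)
  expect_gt(worst_knee, -1e-9)
})

test_that("fit serializes to JSON and back-evaluates", {
  fit <- fit_aperiodic_linear(model_spectrum(3, -2, lo = 2, hi = 55), 2,
                              f_hi = 55)
  js <- jsonlite::fromJSON(write_aperiodic_fit(fit))
  expect_equal(js$variant, "linear")
  expect_equal(js$b, 3, tolerance = 1e-9)
})
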