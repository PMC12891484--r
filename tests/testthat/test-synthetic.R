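test_that("config validation catches bad worlds", {
  expect_error(sim_config(0, 10), "> 0")
  expect_error(sim_config(100, -1), "> 0")
  expect_error(sim_config(100, 10, aperiodic = list(b = 1, m = -2, knee = -1)),
               ">= 0")
  expect_error(sim_config(100, 10, pac = list(phase_freq = 5, amp_freq = 40,
                                              coupling_strength = 1.2)),
               "\\[0, 1\\]")
  expect_error(sim_config(100, 10, pac = list(phase_freq = 30, amp_freq = 40,
                                              coupling_strength = 0.5)),
               "below")
  expect_error(sim_config(100, 10,
                          peaks = list(list(center_freq = 60, bandwidth = 4,
                                            height = 0.3))),
               "Nyquist")
})

test_that("generator is deterministic in the seed", {
  cfg <- mouse_cfg(duration = 20, seed = 42,
                   peaks = list(list(center_freq = 5, bandwidth = 2,
                                     height = 0.5, burst_rate = 0.3,
                                     burst_mean_duration = 0.5)))
  r1 <- gen_recording(cfg)
  r2 <- gen_recording(cfg)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$ground_truth, r2$ground_truth)
  cfg2 <- cfg; cfg2$seed <- 43L
  expect_false(identical(gen_recording(cfg2)$samples, r1$samples))
})

test_that("aperiodic series hits its spectral target", {
  # realized log-log slope over 2-100 Hz within 0.1 of the requested m
  sl <- sapply(1:8, function(s) {
    cfg <- sim_config(1000, 60, aperiodic = list(b = 2, m = -2, knee = 0),
                      seed = s)
    ps <- multitaper_psd(segment(gen_aperiodic_series(cfg), 5),
                         taper_params(2, 5), fmax = 110)$averaged
    k <- ps$freqs >= 2 & ps$freqs <= 100
    coef(lm(ps$log_power[k] ~ log10(ps$freqs[k])))[2]
  })
  expect_equal(mean(sl), -2, tolerance = 0.1)

  # m = 0 gives a flat spectrum: log-power variance below any m = -2 run
  cfg0 <- sim_config(1000, 60, aperiodic = list(b = 2, m = 0, knee = 0),
                     seed = 1)
  ps0 <- multitaper_psd(segment(gen_aperiodic_series(cfg0), 5),
                        taper_params(2, 5), fmax = 110)$averaged
  cfg2 <- sim_config(1000, 60, aperiodic = list(b = 2, m = -2, knee = 0),
                     seed = 1)
  ps2 <- multitaper_psd(segment(gen_aperiodic_series(cfg2), 5),
                        taper_params(2, 5), fmax = 110)$averaged
  k <- ps0$freqs >= 2 & ps0$freqs <= 100
  expect_lt(var(ps0$log_power[k]), var(ps2$log_power[k]))

  # knee target value at 1 Hz: b - log10(k + 1)
  cfgk <- sim_config(500, 100, aperiodic = list(b = 2, m = -2, knee = 25),
                     seed = 6, hp_floor_hz = 0.5)
  psk <- multitaper_psd(segment(gen_aperiodic_series(cfgk), 5),
                        taper_params(1, 5), fmax = 110)$averaged
  at1 <- psk$log_power[which.min(abs(psk$freqs - 1))]
  expect_equal(at1, 2 - log10(26), tolerance = 0.15)
})

test_that("bursty oscillation injection", {
  cfg <- mouse_cfg(duration = 100, seed = 8)
  rec <- gen_aperiodic_series(cfg)
  # burst_rate = 0 injects nothing
  r0 <- add_bursty_oscillation(rec, list(center_freq = 5, bandwidth = 2,
                                         height = 0.5, burst_rate = 0,
                                         burst_mean_duration = 0.4))
  expect_identical(r0$samples, rec$samples)
  expect_equal(nrow(r0$ground_truth$bursts[[1]]$intervals_s), 0L)
  # Poisson event count: 99% interval of rate 0.5/s over 100 s
  counts <- sapply(1:10, function(s)
    nrow(add_bursty_oscillation(rec, list(center_freq = 5, bandwidth = 4,
                                          height = 0.5, burst_rate = 0.5,
                                          burst_mean_duration = 0.4),
                                seed = s)$ground_truth$bursts[[1]]$events_s))
  lim <- qpois(c(0.005, 0.995), 50)
  expect_true(all(counts >= lim[1] & counts <= lim[2]))
  # injected 5 Hz bursty peak -> periodic spectrum maximal in 4-6 Hz
  cfg5 <- mouse_cfg(duration = 150, seed = 9,
                    peaks = list(list(center_freq = 5, bandwidth = 2,
                                      height = 0.6, burst_rate = 0.8,
                                      burst_mean_duration = 0.6)))
  ps <- multitaper_psd(segment(gen_recording(cfg5), 5),
                       taper_params(2, 5), fmax = 60)$averaged
  per <- subtract_aperiodic(ps, fit_aperiodic_linear(ps, 2, f_hi = 55))
  pk_f <- per$freqs[which.max(per$residual)]
  expect_gte(pk_f, 4); expect_lte(pk_f, 6)
  expect_error(add_bursty_oscillation(rec, list(center_freq = 249,
                                                bandwidth = 4, height = 1)),
               "Nyquist")
})

test_that("piezo generator produces detectable (or sub-threshold) bouts", {
  none <- gen_piezo(50, 200, 0, 3, 5, seed = 1)
  expect_equal(nrow(none$intervals_s), 0L)
  expect_equal(movement_bouts(none$piezo, 200)$percent_time_moving, 0)
  some <- gen_piezo(100, 200, 0.1, 3, 5, seed = 3)
  expect_gt(nrow(some$intervals_s), 0L)
  expect_true(all(some$piezo >= 0))
})

test_that("cohorts: hierarchy, subject effects and determinism", {
  base <- sim_config(250, 5, aperiodic = list(b = 2, m = -2, knee = 0),
                     seed = 1)
  spec0 <- cohort_spec(n_groups = 2, n_subjects = 3, n_epochs = 4,
                       subject_sd = 0, seed = 5)
  coh <- gen_cohort(spec0, base)
  expect_length(coh$groups, 2L)
  expect_length(coh$groups[[1]], 3L)
  expect_equal(ncol(coh$groups[[1]][[1]]$epochs$epochs), 4L)
  # subject_sd = 0, no effects: all subjects share generative parameters
  params <- lapply(unlist(coh$groups, recursive = FALSE), `[[`, "params")
  for (p in params) expect_equal(p$aperiodic, base$aperiodic)
  # determinism
  coh2 <- gen_cohort(spec0, base)
  expect_identical(coh$groups[[2]][[3]]$epochs$epochs,
                   coh2$groups[[2]][[3]]$epochs$epochs)
  # subject_sd > 0 perturbs parameters per subject
  specs <- cohort_spec(n_groups = 1, n_subjects = 3, n_epochs = 2,
                       subject_sd = 0.3, seed = 5)
  cohs <- gen_cohort(specs, base)
  bs <- vapply(cohs$groups[[1]], function(s) s$params$aperiodic$b, 0)
  expect_gt(sd(bs), 0)
  # group effect shifts the target parameter
  spec_eff <- cohort_spec(n_groups = 2, n_subjects = 2, n_epochs = 2,
                          subject_sd = 0, seed = 5,
                          group_effects = list(NULL,
                                               list(aperiodic = list(b = 0.5))))
  coh_eff <- gen_cohort(spec_eff, base)
  expect_equal(coh_eff$groups[[2]][[1]]$params$aperiodic$b, 2.5)
  expect_error(cohort_spec(n_subjects = 0), ">= 1")
})
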