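test_that("percentile threshold leaves ~10% of samples above", {
  cfg <- mouse_cfg(duration = 100, seed = 3)
  rec <- gen_recording(cfg)
  bs <- burst_detect(rec, burst_config(band = c(2, 10)),
                     analysis_length_s = 100)
  idx <- bs$window_start + seq_len(bs$window_samples) - 1L
  env <- bandpass_analytic(rec$samples[idx], 500, c(2, 10))$amplitude
  frac <- mean(env > bs$threshold_value)
  n <- bs$window_samples
  expect_lte(abs(frac * n - 0.1 * n), ceiling(0.1 * n) - floor(0.1 * n) + 1)
  expect_true(all(bs$durations_ms > 3))
})

test_that("burst statistics are invariant to amplitude scaling", {
  cfg <- mouse_cfg(duration = 100, seed = 5,
                   peaks = list(list(center_freq = 6, bandwidth = 4,
                                     height = 1.7, burst_rate = 0.5,
                                     burst_mean_duration = 0.4)))
  rec <- gen_recording(cfg)
  b1 <- burst_detect(rec, burst_config(band = c(2, 10)), 100)
  b2 <- burst_detect(recording(4.2 * rec$samples, 500),
                     burst_config(band = c(2, 10)), 100)
  expect_equal(b1$count, b2$count)
  expect_equal(b1$durations_ms, b2$durations_ms)
  expect_equal(b2$threshold_value, 4.2 * b1$threshold_value, tolerance = 1e-9)
  # count non-increasing in the minimum duration
  b3 <- burst_detect(rec, burst_config(band = c(2, 10),
                                       min_duration_ms = 50), 100)
  expect_lte(b3$count, b1$count)
  expect_error(burst_detect(recording(rnorm(1000), 500),
                            burst_config(), 100), "shorter")
})

test_that("high-SNR ground-truth bursts are recovered", {
  rel <- sapply(1:6, function(s) {
    cfg <- mouse_cfg(duration = 100, seed = s, b = 1,
                     peaks = list(list(center_freq = 6, bandwidth = 4,
                                       height = 1.7, burst_rate = 0.5,
                                       burst_mean_duration = 0.4)))
    rec <- gen_recording(cfg)
    truth <- nrow(rec$ground_truth$bursts[[1]]$intervals_s)
    burst_detect(rec, burst_config(band = c(2, 10)), 100)$count / truth
  })
  expect_equal(mean(rel), 1, tolerance = 0.15)
})

test_that("movement bouts: threshold, buffer bridging, percent moving", {
  fs <- 500
  expect_equal(movement_bouts(rep(0, fs * 10), fs)$percent_time_moving, 0)
  # two 1 s bouts separated by a 0.5 s gap merge into one bout
  pz <- rep(0, fs * 10)
  pz[(2 * fs):(3 * fs)] <- 5
  pz[(3.5 * fs):(4.5 * fs)] <- 5
  mv <- movement_bouts(pz, fs)
  expect_equal(nrow(mv$intervals), 1L)
  expect_gt(mv$percent_time_moving, 24)        # gap counted as movement
  # bridging is idempotent
  mv2 <- movement_bouts(mv$state * 5, fs)
  expect_equal(mv2$state, mv$state)
  # below-threshold bouts are invisible
  low <- gen_piezo(100, fs, 0.1, 3, amplitude_mV = 1, seed = 2)
  expect_equal(movement_bouts(low$piezo, fs)$percent_time_moving, 0)
  # generated 5 mV bouts: detected percent within 2 points of truth
  pzg <- gen_piezo(100, fs, 0.1, 3, amplitude_mV = 5, seed = 2)
  truth_pct <- 100 * sum(pmin(pzg$intervals_s[, 2], 100) -
                           pzg$intervals_s[, 1]) / 100
  got <- movement_bouts(pzg$piezo, fs)$percent_time_moving
  expect_lt(abs(got - truth_pct), 2)
})

test_that("burst-movement alignment judges bursts at onset", {
  cfg <- mouse_cfg(duration = 100, seed = 5,
                   peaks = list(list(center_freq = 6, bandwidth = 4,
                                     height = 1.7, burst_rate = 0.5,
                                     burst_mean_duration = 0.4)))
  bs <- burst_detect(gen_recording(cfg), burst_config(band = c(2, 10)), 100)
  n <- bs$window_samples
  all0 <- align_bursts_movement(bs, rep(0L, n))
  expect_equal(all0$fraction_during_movement, 0)
  all1 <- align_bursts_movement(bs, rep(1L, n))
  expect_equal(all1$fraction_during_movement, 1)
  expect_equal(all1$percent_time_moving, 100)
  expect_error(align_bursts_movement(bs, rep(1L, 10)), "length")
  # movement only outside every burst -> fraction 0
  st <- rep(1L, n)
  for (r in seq_len(nrow(bs$intervals)))
    st[bs$intervals[r, "start"]:bs$intervals[r, "end"]] <- 0L
  expect_lt(align_bursts_movement(bs, st)$fraction_during_movement, 0.1)
})

test_that("human burst metrics average across channels", {
  fs <- 250
  t <- (0:(fs * 95 - 1)) / fs
  set.seed(fix_seed)
  ch <- recording(sin(2 * pi * 8 * t) * (1 + sin(2 * pi * 0.2 * t)) +
                    0.3 * rnorm(length(t)), fs)
  cfgh <- burst_config(band = c(7, 12), metric = "log_squared_amplitude")
  one <- burst_detect(ch, cfgh, 90, start_s = 0)
  two <- human_burst_detect(list(ch, ch), cfgh, 90, start_s = 0)
  expect_equal(two$count, one$count)           # identical channels
  expect_equal(two$mean_duration_ms, mean(one$durations_ms))
  expect_equal(two$per_channel[[1]]$metric, "log_squared_amplitude")
})

test_that("multitaper spectrogram frames and localization", {
  fs <- 200
  set.seed(fix_seed)
  rec <- recording(rnorm(fs * 100), fs)
  sg <- mt_spectrogram(rec, fmax = 60)
  expect_length(sg$times, 130L)                # floor((100-3)/0.75)+1
  # stationary noise: frame-to-frame mean log power varies < 20%
  frame_power <- colMeans(log10(sg$power))
  expect_lt(diff(range(frame_power)) / abs(mean(frame_power)), 0.2)
  # a 5 Hz burst at t = 50 s dominates 4-6 Hz power there
  x <- rnorm(fs * 100) * 0.1
  tb <- seq(50 * fs, 51 * fs)
  x[tb] <- x[tb] + 5 * sin(2 * pi * 5 * (tb / fs))
  sg2 <- mt_spectrogram(recording(x, fs), fmax = 60)
  band <- sg2$freqs >= 4 & sg2$freqs <= 6
  peak_t <- sg2$times[which.max(colSums(sg2$power[band, ]))]
  expect_lt(abs(peak_t - 50.5), 2)
  expect_error(mt_spectrogram(recording(rnorm(fs), fs)), "shorter")
})
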