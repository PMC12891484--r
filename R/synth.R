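# Synthetic signal generator with known ground truth. Aperiodic background
# by frequency-domain amplitude shaping (deterministic target amplitudes,
# uniformly random phases) so the expected log10 PSD is exactly
# b - log10(k + f^(-m)); oscillatory peaks injected in the time domain as
# (optionally bursty) envelope-modulated carriers so burst statistics are
# ground-truthed too; phase-amplitude-coupled signals with an analytic MI
# oracle; nested group/subject/epoch cohorts for the bootstrap stage.

#' Simulation configuration
#'
#' @param sampling_rate Hz.
#' @param duration seconds; `duration * sampling_rate` must be integral.
#' @param aperiodic list with `b` (intercept, log10 power), `m` (slope,
#'   <= 0) and `knee` (>= 0).
#' @param peaks list of peak specs: `center_freq` Hz, `bandwidth` Hz,
#'   `height` (log10-power units above the aperiodic curve),
#'   optional `burst_rate` (events/s; `NULL` = continuous) and
#'   `burst_mean_duration` (s).
#' @param pac optional list: `phase_freq`, `amp_freq` Hz,
#'   `coupling_strength` in `[0, 1]`, optional `slow_amp`, `fast_amp`,
#'   `noise_sd`.
#' @param line_noise optional list: `freq` Hz, `height` (log10 units).
#' @param seed integer seed.
#' @param analysis_halfbw intended analysis half-bandwidth W in Hz (default
#'   1, i.e. a 2 Hz spectral resolution); used to calibrate injected peak
#'   amplitudes so the residual height matches `height`.
#' @param hp_floor_hz acquisition high-pass corner, Hz (default 1): the
#'   target PSD is held flat below this frequency, emulating the hardware
#'   high-pass of real recordings (a knee-free power law would otherwise
#'   diverge at DC, which no physical recording does).
#' @return a `sim_config` list.
#' @export
sim_config <- function(sampling_rate, duration,
                       aperiodic = list(b = 2, m = -2, knee = 0),
                       peaks = list(), pac = NULL, line_noise = NULL,
                       seed = 1L, analysis_halfbw = 1, hp_floor_hz = 1) {
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar_num(duration, "duration", positive = TRUE)
  n <- sampling_rate * duration
  if (abs(n - round(n)) > 1e-8 || round(n) < 2)
    stop_invalid("duration x sampling_rate must be an integer >= 2")
  assert_scalar_num(aperiodic$b, "aperiodic$b")
  assert_scalar_num(aperiodic$m, "aperiodic$m")
  if (is.null(aperiodic$knee)) aperiodic$knee <- 0
  assert_scalar_num(aperiodic$knee, "aperiodic$knee", nonneg = TRUE)
  for (p in peaks) {
    assert_scalar_num(p$center_freq, "peak center_freq", positive = TRUE)
    assert_scalar_num(p$height, "peak height")
    if (p$center_freq + p$bandwidth / 2 >= sampling_rate / 2)
      stop_invalid("peak band extends past Nyquist")
  }
  if (!is.null(pac)) {
    assert_scalar_num(pac$coupling_strength, "coupling_strength", nonneg = TRUE)
    if (pac$coupling_strength > 1) stop_invalid("coupling_strength must be in [0, 1]")
    if (pac$phase_freq >= pac$amp_freq / 2)
      stop_invalid("phase_freq must be below amp_freq / 2")
  }
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 aperiodic = aperiodic, peaks = peaks, pac = pac,
                 line_noise = line_noise, seed = as.integer(seed),
                 analysis_halfbw = analysis_halfbw,
                 hp_floor_hz = hp_floor_hz),
            class = "sim_config")
}

aperiodic_psd_at <- function(ap, f) 10^ap$b / (ap$knee + f^(-ap$m))

#' Generate the aperiodic (1/f) background series
#'
#' @param config a [sim_config]; peaks/pac are ignored by this operation.
#' @return a [recording] whose expected log10 PSD is
#'   `b - log10(knee + f^(-m))`, with the generative parameters in
#'   `ground_truth`.
#' @export
gen_aperiodic_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  ap <- config$aperiodic
  with_seed(config$seed, {
    nh <- n %/% 2L
    f <- (1:nh) / config$duration               # positive frequencies
    P <- aperiodic_psd_at(ap, pmax(f, config$hp_floor_hz))
    amp <- sqrt(P * fs * n / 2)
    ph <- runif(nh, -pi, pi)
    X <- complex(modulus = amp, argument = ph)
    if (n %% 2L == 0L) X[nh] <- complex(real = sqrt(P[nh] * fs * n), imaginary = 0)
    full <- c(0, X, Conj(rev(X[seq_len(nh - 1L + n %% 2L)])))
    x <- Re(fft(full, inverse = TRUE)) / n
  })
  recording(x, fs, channel_label = "sim",
            ground_truth = list(aperiodic = ap,
                                analysis_halfbw = config$analysis_halfbw))
}

# amplitude giving a continuous carrier the requested residual height h
# (log10 units) over the aperiodic curve: line power a^2/2 smeared over the
# 2W analysis bandwidth of the multitaper estimator.
peak_amplitude <- function(height, center, ap, halfbw, duty = 1) {
  sqrt(2 * (2 * halfbw) * (10^height - 1) * aperiodic_psd_at(ap, center) /
         max(duty, 1e-12))
}

#' Add a (bursty) oscillatory peak to a recording
#'
#' A sinusoidal carrier at the peak's centre frequency whose envelope is on
#' during Poisson-sampled bursts (exponential durations) and off otherwise,
#' with raised-cosine ramps of ~1/bandwidth seconds. A peak with
#' `burst_rate = NULL` is continuous (envelope always on);
#' `burst_rate = 0` injects nothing. Ground-truth burst intervals are
#' appended to the recording's `ground_truth`.
#'
#' @param rec a [recording] (normally from [gen_aperiodic_series]).
#' @param peak a peak spec (see [sim_config]).
#' @param seed RNG seed.
#' @return the recording with the oscillation added.
#' @export
add_bursty_oscillation <- function(rec, peak, seed = 1L) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$sampling_rate
  bw <- if (is.null(peak$bandwidth)) 1 else peak$bandwidth
  if (peak$center_freq - bw / 2 <= 0 || peak$center_freq + bw / 2 >= fs / 2)
    stop_invalid("peak band outside (0, Nyquist)")
  n <- length(rec$samples)
  dur_s <- n / fs
  continuous <- is.null(peak$burst_rate) || !is.finite(peak$burst_rate)
  if (!continuous && peak$burst_rate < 0) stop_invalid("burst_rate must be >= 0")
  if (!continuous && peak$burst_rate == 0) {
    empty <- cbind(start = numeric(), end = numeric())
    rec$ground_truth$bursts <- c(rec$ground_truth$bursts,
                                 list(list(center_freq = peak$center_freq,
                                           events_s = empty,
                                           intervals_s = empty)))
    return(rec)
  }
  ap <- rec$ground_truth$aperiodic
  if (is.null(ap)) stop_invalid("recording carries no aperiodic ground truth")
  halfbw <- rec$ground_truth$analysis_halfbw

  with_seed(seed, {
    if (continuous) {
      onsets <- 0; durs <- dur_s
      duty <- 1
    } else {
      k <- rpois(1L, peak$burst_rate * dur_s)
      onsets <- sort(runif(k, 0, dur_s))
      durs <- rexp(k, rate = 1 / peak$burst_mean_duration)
      duty <- min(1, peak$burst_rate * peak$burst_mean_duration)
    }
    env <- numeric(n)
    ramp_n <- max(2L, round(fs / bw / 2))
    for (i in seq_along(onsets)) {
      s <- floor(onsets[i] * fs) + 1L
      e <- min(n, s + round(durs[i] * fs) - 1L)
      if (e < s) next
      seg <- s:e
      w <- rep(1, length(seg))
      r <- min(ramp_n, floor(length(seg) / 2))
      if (r > 0) {
        ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
        w[seq_len(r)] <- ramp
        w[length(seg) - r + seq_len(r)] <- rev(ramp)
      }
      env[seg] <- pmax(env[seg], w)
    }
    a <- peak_amplitude(peak$height, peak$center_freq, ap, halfbw, duty)
    phase0 <- runif(1L, -pi, pi)
    t <- (seq_len(n) - 1L) / fs
    rec$samples <- rec$samples + a * env * cos(2 * pi * peak$center_freq * t + phase0)
    truth_iv <- if (length(onsets))
      cbind(start = onsets, end = pmin(onsets + durs, dur_s))
    else cbind(start = numeric(), end = numeric())
  })
  rec$ground_truth$bursts <- c(rec$ground_truth$bursts,
                               list(list(center_freq = peak$center_freq,
                                         amplitude = a,
                                         events_s = truth_iv,
                                         intervals_s = merge_intervals(truth_iv))))
  rec
}

# union of possibly overlapping [start, end] rows: overlapping events are
# observationally a single burst, so detection is scored against the merge
merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  o <- order(iv[, 1L])
  iv <- iv[o, , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (r in seq_len(nrow(iv))[-1L]) {
    k <- nrow(out)
    if (iv[r, 1L] <= out[k, 2L]) out[k, 2L] <- max(out[k, 2L], iv[r, 2L])
    else out <- rbind(out, iv[r, , drop = FALSE])
  }
  out
}

#' Generate a full synthetic recording
#'
#' Aperiodic background plus every peak in the config (continuous or
#' bursty) plus optional line noise.
#'
#' @param config a [sim_config].
#' @return a [recording] with complete ground truth.
#' @export
gen_recording <- function(config) {
  rec <- gen_aperiodic_series(config)
  for (i in seq_along(config$peaks))
    rec <- add_bursty_oscillation(rec, config$peaks[[i]],
                                  seed = child_seed(config$seed, paste0("peak", i)))
  if (!is.null(config$line_noise)) {
    ln <- list(center_freq = config$line_noise$freq, bandwidth = 4,
               height = config$line_noise$height)
    rec <- add_bursty_oscillation(rec, ln, seed = child_seed(config$seed, "line"))
  }
  rec
}

#' Generate a phase-amplitude-coupled series
#'
#' Slow carrier at `phase_freq` plus a fast narrowband-noise component
#' centred at `amp_freq` (Gaussian spectral bump, emulating broadband
#' gamma) whose instantaneous amplitude is proportional to
#' `1 + coupling_strength * cos(phase_slow)`, plus white noise. A pure fast
#' tone would confine the coupling to two sidebands at
#' `amp_freq +/- phase_freq`, which no amplitude band of a comodulogram
#' could follow; the noise carrier spreads it across the bump. The implied
#' 18-bin phase-amplitude distribution is `PA_j` proportional to
#' `1 + coupling_strength * cos(phi_j)`, giving an analytic MI oracle (see
#' [pac_mi_oracle]).
#'
#' @param config a [sim_config] with a `pac` component; optional pac fields:
#'   `slow_amp` (default 1), `fast_amp` (default 0.5), `noise_sd` (default
#'   0.1), `amp_bw` (FWHM of the fast bump, Hz; default `phase_freq`),
#'   `slow_bw` (FWHM of the slow bump, Hz; default `phase_freq / 5`,
#'   the bandwidth of a physiological rhythm of quality factor ~5).
#' @return a [recording] with the PAC parameters in `ground_truth`.
#' @export
gen_pac_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pac <- config$pac
  if (is.null(pac)) stop_invalid("config has no pac component")
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  slow_amp <- if (is.null(pac$slow_amp)) 1 else pac$slow_amp
  fast_amp <- if (is.null(pac$fast_amp)) 0.5 else pac$fast_amp
  noise_sd <- if (is.null(pac$noise_sd)) 0.1 else pac$noise_sd
  amp_bw <- if (is.null(pac$amp_bw)) pac$phase_freq else pac$amp_bw
  slow_bw <- if (is.null(pac$slow_bw)) pac$phase_freq / 5 else pac$slow_bw
  with_seed(config$seed, {
    f <- c(0, 1:(n %/% 2L), if (n %% 2L == 0L) (n %/% 2L - 1L):1L
           else (n %/% 2L):1L) * fs / n
    bump <- function(center, fwhm) {        # unit-RMS narrowband noise
      sigma <- fwhm / 2.355
      prof <- exp(-(f - center)^2 / (2 * sigma^2))
      y <- Re(fft(fft(rnorm(n)) * prof, inverse = TRUE)) / n
      y / sd(y)
    }
    # slow oscillation with drifting phase (a perfectly periodic carrier
    # would survive epoch shuffling and defeat the noise comodulogram)
    slow <- bump(pac$phase_freq, slow_bw)
    phi <- Arg(hilbert_analytic(slow))
    fast <- bump(pac$amp_freq, amp_bw)
    x <- slow_amp * slow +
      fast_amp * (1 + pac$coupling_strength * cos(phi)) * fast +
      (if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0)
  })
  recording(x, fs, channel_label = "sim_pac",
            ground_truth = list(pac = pac))
}

#' Analytic modulation-index oracle for the coupled generator
#'
#' Evaluates the MI formula directly on the analytic phase-amplitude vector
#' `PA_j` proportional to `1 + kappa * cos(phi_j)` over `n_bins` bins.
#'
#' @param kappa coupling strength in `[0, 1]`.
#' @param n_bins number of phase bins (default 18).
#' @return the oracle MI.
#' @export
pac_mi_oracle <- function(kappa, n_bins = 18L) {
  centers <- seq(-pi, pi, length.out = n_bins + 1L)
  centers <- (centers[-1L] + centers[-(n_bins + 1L)]) / 2
  pa <- 1 + kappa * cos(centers)
  modulation_index(pa / sum(pa))
}

#' Generate a rectified piezo movement trace
#'
#' Poisson movement bouts (exponential durations) of the given amplitude
#' over a near-zero noise baseline; ground-truth bout intervals returned.
#'
#' @param duration seconds.
#' @param sampling_rate Hz.
#' @param bout_rate bouts per second.
#' @param bout_duration mean bout duration, seconds.
#' @param amplitude_mV bout amplitude (must exceed the 2 mV detection
#'   threshold for positive cases).
#' @param seed RNG seed.
#' @return list with `piezo` (non-negative mV trace) and `intervals_s`
#'   (ground-truth bout times).
#' @export
gen_piezo <- function(duration, sampling_rate, bout_rate, bout_duration,
                      amplitude_mV, seed = 1L) {
  n <- round(duration * sampling_rate)
  with_seed(seed, {
    piezo <- 0.02 * abs(rnorm(n))
    if (bout_rate > 0) {
      k <- rpois(1L, bout_rate * duration)
      onsets <- sort(runif(k, 0, duration))
      durs <- rexp(k, rate = 1 / bout_duration)
    } else {
      onsets <- numeric(); durs <- numeric()
    }
    for (i in seq_along(onsets)) {
      s <- floor(onsets[i] * sampling_rate) + 1L
      e <- min(n, s + round(durs[i] * sampling_rate) - 1L)
      if (e >= s)
        piezo[s:e] <- amplitude_mV * (0.75 + 0.5 * runif(e - s + 1L))
    }
  })
  iv <- if (length(onsets)) cbind(start = onsets,
                                  end = pmin(onsets + durs, duration))
        else cbind(start = numeric(), end = numeric())
  list(piezo = piezo, intervals_s = merge_intervals(iv))
}

#' Cohort specification for synthetic group studies
#'
#' @param n_groups number of groups (default 2).
#' @param n_subjects subjects per group (scalar or vector per group).
#' @param n_epochs epochs per subject.
#' @param subject_sd between-subject SD added (Gaussian) to the log-scale
#'   generative parameters: intercept `b`, slope `m`, and peak heights.
#' @param group_effects optional list (one element per group) of additive
#'   offsets: each is a list with optional `aperiodic` (named offsets on
#'   `b`/`m`/`knee`) and `peaks` (list of named offsets per peak, e.g.
#'   `height`, `center_freq`).
#' @param seed integer seed.
#' @export
cohort_spec <- function(n_groups = 2L, n_subjects = 10L, n_epochs = 20L,
                        subject_sd = 0.1, group_effects = NULL, seed = 1L) {
  if (any(c(n_groups, n_subjects, n_epochs) < 1L))
    stop_invalid("all cohort counts must be >= 1")
  if (subject_sd < 0) stop_invalid("subject_sd must be >= 0")
  n_subjects <- rep_len(n_subjects, n_groups)
  structure(list(n_groups = n_groups, n_subjects = n_subjects,
                 n_epochs = n_epochs, subject_sd = subject_sd,
                 group_effects = group_effects, seed = as.integer(seed)),
            class = "cohort_spec")
}

apply_group_effect <- function(config, eff) {
  if (is.null(eff)) return(config)
  for (nm in names(eff$aperiodic))
    config$aperiodic[[nm]] <- config$aperiodic[[nm]] + eff$aperiodic[[nm]]
  for (i in seq_along(eff$peaks))
    for (nm in names(eff$peaks[[i]]))
      config$peaks[[i]][[nm]] <- config$peaks[[i]][[nm]] + eff$peaks[[i]][[nm]]
  config
}

#' Generate a synthetic cohort
#'
#' Per subject, generative parameters are base + group effect + a Gaussian
#' subject-level perturbation (sd = `subject_sd`, applied to `b`, `m` and
#' peak heights); each of `n_epochs` epochs is an independent realization of
#' the subject's configuration with `duration` equal to the base config's
#' duration. Fully reproducible from the spec seed.
#'
#' @param spec a [cohort_spec].
#' @param base a [sim_config] describing one epoch.
#' @return a `synthetic_cohort`: list of groups, each a list of subjects
#'   holding `params` (the realized [sim_config]) and `epochs` (an
#'   [epoch_set], one column per epoch).
#' @export
gen_cohort <- function(spec, base) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(base, "sim_config"))
  groups <- vector("list", spec$n_groups)
  names(groups) <- paste0("group", seq_len(spec$n_groups))
  for (g in seq_len(spec$n_groups)) {
    gcfg <- apply_group_effect(base, spec$group_effects[[g]])
    subjects <- vector("list", spec$n_subjects[g])
    for (s in seq_len(spec$n_subjects[g])) {
      sseed <- child_seed(spec$seed, sprintf("g%d_s%d", g, s))
      scfg <- gcfg
      if (spec$subject_sd > 0) {
        pert <- with_seed(sseed, rnorm(2L + length(scfg$peaks),
                                       sd = spec$subject_sd))
        scfg$aperiodic$b <- scfg$aperiodic$b + pert[1L]
        scfg$aperiodic$m <- scfg$aperiodic$m + pert[2L]
        for (i in seq_along(scfg$peaks))
          scfg$peaks[[i]]$height <- scfg$peaks[[i]]$height + pert[2L + i]
      }
      cols <- vector("list", spec$n_epochs)
      for (e in seq_len(spec$n_epochs)) {
        ecfg <- scfg
        ecfg$seed <- child_seed(sseed, paste0("epoch", e))
        cols[[e]] <- gen_recording(ecfg)$samples
      }
      subjects[[s]] <- list(params = scfg,
                            epochs = epoch_set(do.call(cbind, cols),
                                               base$duration,
                                               base$sampling_rate))
    }
    groups[[g]] <- subjects
  }
  structure(list(groups = groups, spec = spec, base = base),
            class = "synthetic_cohort")
}

#' Per-epoch spectra of a synthetic cohort
#'
#' Runs [multitaper_psd] over every subject's epochs, yielding the
#' group/subject/epoch hierarchy of log10-power spectra consumed by the
#' bootstrap statistics.
#'
#' @param cohort a `synthetic_cohort`.
#' @param tp a [taper_params].
#' @param fmax optional frequency cap, Hz.
#' @param log10_scale return log10 power (default) or linear.
#' @return a [cohort_dataset].
#' @export
cohort_spectra <- function(cohort, tp, fmax = NULL, log10_scale = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  grid <- NULL
  groups <- lapply(cohort$groups, function(subjects)
    lapply(subjects, function(su) {
      out <- multitaper_psd(su$epochs, tp, fmax = fmax)
      grid <<- out$freqs
      if (log10_scale) log10(out$per_epoch) else out$per_epoch
    }))
  cohort_dataset(groups, grid = grid)
}
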