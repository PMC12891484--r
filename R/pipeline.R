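#' Analysis profiles
#'
#' Named presets bundling the stage parameters for the four reference
#' dataset families:
#' \describe{
#'   \item{human_child}{3 Hz lower fit edge, 2 s segments, TW 2 (3 tapers),
#'     0.1 Hz interpolated bins, linear fit, Pk1/Pk2 split at 15 Hz.}
#'   \item{human_adult}{as human_child but native 0.5 Hz bins.}
#'   \item{mouse_surface}{2 Hz edge, 5 s segments, TW 5 (9 tapers), linear
#'     fit, single smoothed peak below 10 Hz.}
#'   \item{mouse_lfp}{1.5 Hz edge, 5 s segments, TW 5 full-range pass with
#'     knee fit out to 175 Hz, plus a TW 2.5 (4 taper) high-resolution pass
#'     for the 2-10 Hz sub-peaks; PAC and burst analysis enabled.}
#' }
#'
#' @param name profile name.
#' @return a named list of stage parameters.
#' @export
analysis_profile <- function(name = c("mouse_lfp", "mouse_surface",
                                      "human_child", "human_adult")) {
  name <- match.arg(name)
  base <- list(name = name, amp_reject_uv = Inf, interpolate_bin = NULL,
               notch = NULL, do_pac = FALSE, do_bursts = FALSE,
               burst = NULL, boot_ci = 99, smooth_span = 0.25)
  switch(name,
    human_child = modifyList(base, list(
      segment_length = 2, FR = 2, f_lo = 3, f_hi = 55, fit = "linear",
      search_min = 8, peak_rule = "human", peak_split = 15,
      interpolate_bin = 0.1, amp_reject_uv = 120, boot_levels = 1L,
      boot_ci = 95)),
    human_adult = modifyList(base, list(
      segment_length = 2, FR = 2, f_lo = 3, f_hi = 55, fit = "linear",
      search_min = 8, peak_rule = "human", peak_split = 15,
      amp_reject_uv = 120, boot_levels = 2L, boot_ci = 95)),
    mouse_surface = modifyList(base, list(
      segment_length = 5, FR = 2, f_lo = 2, f_hi = 55, fit = "linear",
      search_min = 8, peak_rule = "surface", peak_upper = 10,
      boot_levels = 2L)),
    mouse_lfp = modifyList(base, list(
      segment_length = 5, FR = 2, f_lo = 1.5, f_hi = 175, fit = "knee",
      mid_search = c(9, 25), knee_search = c(1.5, 2.24),
      subpeak_FR = 1, peak_rule = "subpeaks", boot_levels = 2L,
      do_pac = TRUE, do_bursts = TRUE,
      burst = list(band = c(2, 10), length_s = 100))))
}

fit_profile_spectrum <- function(ps, prof) {
  if (prof$fit == "knee")
    fit_aperiodic_knee(ps, f_lo = prof$f_lo, hi_search_max = prof$f_hi,
                       notch_gap = prof$notch_gap,
                       mid_search = prof$mid_search,
                       knee_search = prof$knee_search)
  else
    fit_aperiodic_linear(ps, f_lo = prof$f_lo, search_min = prof$search_min,
                         f_hi = prof$f_hi)
}

#' Analyze one subject's recording under a profile
#'
#' Runs the per-subject pipeline: detrend, optional notch, segmentation,
#' artifact exclusion, multitaper spectrum, aperiodic fit, peak extraction
#' (including the high-resolution sub-peak pass for the LFP profile), and
#' optionally bursts and PAC.
#'
#' @param rec a [recording].
#' @param prof an [analysis_profile].
#' @param seed stage seed.
#' @param do_pac,do_bursts override the profile's stage switches.
#' @return list with `epochs`, `spectrum`, `per_epoch`, `fit`, `periodic`,
#'   `peaks`, and optionally `bursts`, `pac`, `pac_noise`.
#' @export
analyze_subject <- function(rec, prof, seed = 1L, do_pac = prof$do_pac,
                            do_bursts = prof$do_bursts) {
  rec <- detrend_mean(rec)
  if (!is.null(prof$notch))
    rec <- notch_filter(rec, prof$notch$freq, prof$notch$bandwidth)
  es <- segment(rec, prof$segment_length)
  es <- if (is.finite(prof$amp_reject_uv)) amplitude_reject(es, prof$amp_reject_uv)
        else exclude_artifact_epochs(es)
  tp <- taper_params(prof$FR, prof$segment_length)
  out <- multitaper_psd(es, tp, fmax = prof$f_hi + 5)
  ps <- out$averaged
  if (!is.null(prof$interpolate_bin)) ps <- interpolate_psd(ps, prof$interpolate_bin)
  fit <- fit_profile_spectrum(ps, prof)
  per <- subtract_aperiodic(ps, fit)
  peaks <- switch(prof$peak_rule,
    human = find_peaks_human(per, split = prof$peak_split),
    surface = list(Pk1 = find_peak_mouse_surface(per, upper = prof$peak_upper,
                                                 smooth_span = prof$smooth_span)),
    subpeaks = {
      tp2 <- taper_params(prof$subpeak_FR, prof$segment_length)
      ps2 <- multitaper_psd(es, tp2, fmax = 12)$averaged
      find_subpeaks(subtract_aperiodic(ps2, fit), smooth_span = prof$smooth_span)
    })
  res <- list(epochs = es, spectrum = ps, per_epoch = out$per_epoch,
              freqs = out$freqs, fit = fit, periodic = per, peaks = peaks)
  if (do_bursts) {
    bc <- burst_config(band = prof$burst$band)
    len <- min(prof$burst$length_s, duration_s(rec))
    bs <- burst_detect(rec, bc, analysis_length_s = len,
                       seed = child_seed(seed, "burst_start"))
    if (!is.null(rec$piezo)) {
      mv <- movement_bouts(rec$piezo[bs$window_start +
                                       seq_len(bs$window_samples) - 1L],
                           rec$sampling_rate)
      bs <- align_bursts_movement(bs, mv)
    }
    res$bursts <- bs
  }
  if (do_pac) {
    grid <- pac_band_grid()
    res$pac <- comodulogram(es, grid)
    res$pac_noise <- noise_comodulogram(es, grid,
                                        seed = child_seed(seed, "pac_noise"))$mi
  }
  res
}

result_record <- function(id, group, prof, sub, seed) {
  pk <- lapply(Filter(is.list, sub$peaks), function(p)
    if (!is.null(p$label))
      list(label = p$label, center_frequency_hz = p$center_frequency,
           max_power_log10 = p$max_power, detection_mode = p$detection_mode)
    else NULL)
  pk <- Filter(Negate(is.null), pk)
  list(subject = id, group = group, profile = prof$name,
       n_epochs_included = sum(sub$epochs$included),
       n_epochs_total = ncol(sub$epochs$epochs),
       aperiodic = list(variant = sub$fit$variant, b = sub$fit$b,
                        m = sub$fit$m, knee = sub$fit$knee,
                        offset = sub$fit$offset),
       peaks = pk,
       bursts = if (!is.null(sub$bursts))
         list(count = sub$bursts$count,
              median_duration_ms = if (sub$bursts$count)
                median(sub$bursts$durations_ms) else NA,
              percent_time_moving = sub$bursts$percent_time_moving),
       provenance = list(seed = seed,
                         package_version = as.character(packageVersion("oscphen"))))
}

#' Run the full pipeline over a set of subjects
#'
#' Preprocess, spectra, aperiodic fit, peaks (plus PAC and bursts where the
#' profile enables them) per subject, then a hierarchical bootstrap of the
#' log-power spectra between the first two groups.
#'
#' @param subjects list of entries, each `list(id =, group =, rec =)` with
#'   `rec` a [recording] (or `file =` pointing at a delimited recording).
#' @param profile an [analysis_profile] (or its name).
#' @param seed global seed, fanned out to stage child seeds.
#' @param n_boot bootstrap replicates (default 1000).
#' @param out_dir optional directory; when set, per-subject JSON result
#'   records and the bootstrap TSV are written.
#' @return list with `records`, per-subject `analyses`, and `bootstrap`.
#' @export
run_pipeline <- function(subjects, profile = "mouse_lfp", seed = 1L,
                         n_boot = 1000L, out_dir = NULL) {
  prof <- if (is.character(profile)) analysis_profile(profile) else profile
  analyses <- list(); records <- list()
  groups <- character(length(subjects))
  for (i in seq_along(subjects)) {
    su <- subjects[[i]]
    rec <- if (!is.null(su$rec)) su$rec else read_recording(su$file)
    sub <- analyze_subject(rec, prof, seed = child_seed(seed, su$id))
    analyses[[su$id]] <- sub
    groups[i] <- su$group
    records[[su$id]] <- result_record(su$id, su$group, prof, sub, seed)
  }
  boot <- NULL
  glev <- unique(groups)
  if (length(glev) >= 2L) {
    items <- lapply(glev[1:2], function(g)
      lapply(analyses[groups == g], function(s) log10(s$per_epoch)))
    cfg <- bootstrap_config(n_boot = n_boot, ci_level = prof$boot_ci,
                            levels = prof$boot_levels,
                            seed = child_seed(seed, "bootstrap"))
    boot <- hier_bootstrap_diff(items[[1L]], items[[2L]], cfg,
                                grid = analyses[[1L]]$freqs)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(records))
      jsonlite::write_json(records[[id]],
                           file.path(out_dir, paste0(id, "_result.json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
    if (!is.null(boot))
      write.table(data.frame(frequency_hz = boot$grid, median = boot$median,
                             lower = boot$lower, upper = boot$upper,
                             significant = boot$significant),
                  file.path(out_dir, "bootstrap_spectrum_diff.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(records = records, analyses = analyses, bootstrap = boot,
       profile = prof)
}
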