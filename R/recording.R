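#' Construct a recording
#'
#' A recording is a single-channel voltage time series in microvolts with its
#' sampling rate, an optional sample-aligned rectified piezo movement trace in
#' millivolts, and optional generator ground truth (burst/bout intervals,
#' generative parameters) carried alongside for validation.
#'
#' @param samples numeric vector, microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_label character scalar naming the channel.
#' @param piezo optional non-negative numeric vector, millivolts, same length
#'   as `samples`.
#' @param ground_truth optional list of generator-emitted truth.
#' @return an object of class `recording`.
#' @export
recording <- function(samples, sampling_rate, channel_label = "ch1",
                      piezo = NULL, ground_truth = NULL) {
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop_invalid("recording has no samples")
  if (!all(is.finite(samples))) stop_invalid("samples must be finite")
  if (!is.null(piezo)) {
    piezo <- as.numeric(piezo)
    if (length(piezo) != length(samples))
      stop_invalid("piezo trace length must match samples")
    if (any(piezo < 0)) stop_invalid("piezo trace must be non-negative (rectified)")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_label = as.character(channel_label)[1L],
                 piezo = piezo, ground_truth = ground_truth),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d samples @ %g Hz (%.1f s)%s\n",
              x$channel_label, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              if (is.null(x$piezo)) "" else " + piezo"))
  invisible(x)
}

#' @export
length.recording <- function(x) length(x$samples)

duration_s <- function(rec) length(rec$samples) / rec$sampling_rate

#' Write a recording to the delimited time-series format
#'
#' Header lines `# sampling_rate_hz=`, `# channel=`, then one sample (µV) per
#' line; when a piezo trace is present it is a second tab-separated column in
#' millivolts.
#'
#' @param rec a [recording].
#' @param path output file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz=%.10g", rec$sampling_rate),
               sprintf("# channel=%s", rec$channel_label)), con)
  if (is.null(rec$piezo)) {
    writeLines(formatC(rec$samples, format = "g", digits = 10), con)
  } else {
    writeLines(paste(formatC(rec$samples, format = "g", digits = 10),
                     formatC(rec$piezo, format = "g", digits = 10),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a recording from the delimited time-series format
#'
#' @param path file written by [write_recording] (or any file following the
#'   dialect: `#`-prefixed `key=value` header then one or two numeric columns).
#' @return a [recording].
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  if (is.null(meta$sampling_rate_hz)) stop_invalid("missing sampling_rate_hz header")
  body <- trimws(lines[-hdr])
  body <- body[nzchar(body)]
  parts <- strsplit(body, "[\t ,]+")
  ncol <- length(parts[[1L]])
  vals <- as.numeric(unlist(parts))
  m <- matrix(vals, ncol = ncol, byrow = TRUE)
  recording(m[, 1L], as.numeric(meta$sampling_rate_hz),
            channel_label = if (is.null(meta$channel)) "ch1" else meta$channel,
            piezo = if (ncol >= 2L) m[, 2L] else NULL)
}
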