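# Minimal EDF (European Data Format) continuous-recording I/O: ASCII header
# (256 bytes + 256 per signal) and little-endian int16 data records with
# linear physical scaling. Covers plain continuous EDF only — no EDF+
# annotations, no discontinuous records — which is all the pipeline needs to
# select channels by label from human-style multichannel exports.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Read an EDF file
#'
#' @param path EDF file.
#' @param channels optional character vector of channel labels to keep
#'   (default: all).
#' @return a named list of [recording] objects, one per selected channel.
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nb) rawToChar(readBin(con, "raw", nb))
  num <- function(nb) as.numeric(trimws(rd(nb)))
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # patient, recording, date, time
  num(8)                                  # header bytes
  rd(44)                                  # reserved
  n_rec <- num(8)
  rec_dur <- num(8)
  ns <- as.integer(num(4))
  fields <- function(nb) vapply(seq_len(ns), function(i) rd(nb), "")
  labels <- trimws(fields(16))
  fields(80); fields(8)                   # transducer, dimension
  phys_min <- as.numeric(trimws(fields(8)))
  phys_max <- as.numeric(trimws(fields(8)))
  dig_min <- as.numeric(trimws(fields(8)))
  dig_max <- as.numeric(trimws(fields(8)))
  fields(80)                              # prefiltering
  nsamp <- as.integer(trimws(fields(8)))  # samples per record per signal
  fields(32)                              # reserved
  keep <- if (is.null(channels)) seq_len(ns) else match(channels, labels)
  if (anyNA(keep)) stop_invalid("channel(s) not found: ",
                                paste(channels[is.na(keep)], collapse = ", "))
  out <- lapply(keep, function(i) vector("list", n_rec))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", nsamp[i], size = 2L, signed = TRUE,
                     endian = "little")
      j <- match(i, keep)
      if (!is.na(j)) out[[j]][[r]] <- dig
    }
  }
  res <- lapply(seq_along(keep), function(j) {
    i <- keep[j]
    dig <- unlist(out[[j]])
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    phys <- (dig - dig_min[i]) * gain + phys_min[i]
    recording(phys, nsamp[i] / rec_dur, channel_label = labels[i])
  })
  names(res) <- labels[keep]
  res
}

#' Write recordings to a minimal EDF file
#'
#' Intended for round-trip tests and interoperability; all recordings must
#' share one sampling rate and duration. Samples are quantized to int16 over
#' each channel's observed physical range.
#'
#' @param recs a list of [recording] objects.
#' @param path output path.
#' @param record_duration data-record length in seconds (default 1).
#' @export
write_edf <- function(recs, path, record_duration = 1) {
  if (inherits(recs, "recording")) recs <- list(recs)
  ns <- length(recs)
  fs <- recs[[1L]]$sampling_rate
  n <- length(recs[[1L]]$samples)
  for (r in recs)
    if (r$sampling_rate != fs || length(r$samples) != n)
      stop_invalid("all channels must share sampling rate and length")
  nsamp <- round(fs * record_duration)
  if (abs(nsamp - fs * record_duration) > 1e-9)
    stop_invalid("record_duration x sampling_rate must be integral")
  n_rec <- floor(n / nsamp)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, eos = NULL)
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44)
  wr(n_rec, 8); wr(format(record_duration), 8); wr(ns, 4)
  pmin_ <- vapply(recs, function(r) min(r$samples), 0)
  pmax_ <- vapply(recs, function(r) max(r$samples), 0)
  pad_rng <- pmax_ <= pmin_
  pmax_[pad_rng] <- pmin_[pad_rng] + 1
  for (r in recs) wr(r$channel_label, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin_) wr(formatC(v, format = "g", digits = 7), 8)
  for (v in pmax_) wr(formatC(v, format = "g", digits = 7), 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(nsamp, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * nsamp + seq_len(nsamp)
    for (i in seq_len(ns)) {
      x <- recs[[i]]$samples[idx]
      dig <- round((x - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}
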