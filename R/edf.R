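# Minimal European Data Format (EDF) writer/reader.
#
# Covers the subset of EDF used by this package: continuous recordings,
# 1-second data records, one identical sampling rate for all signals, 16-bit
# samples with a symmetric per-channel physical range. The header layout
# follows the EDF field widths exactly, so files read back in standard EDF
# tools.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

# Format a positive physical range so that both "x" and "-x" fit the 8-byte
# EDF fields; returns the string together with its exact parsed value so the
# quantization can use precisely what the header says.
.edf_range <- function(x) {
  for (d in 7:1) {
    s <- trimws(formatC(x, format = "g", digits = d))
    if (nchar(s) <= 7) return(list(string = s, value = as.numeric(s)))
  }
  stop("cannot format physical range ", x)
}

#' Write an EEG recording to an EDF file
#'
#' Samples are quantized to 16 bits over a symmetric per-channel physical
#' range (the maximum absolute amplitude of the channel), so the round-trip
#' error is bounded by `range / 65534` per sample. The recording length must
#' be a whole number of seconds.
#'
#' @param recording an [eeg_recording] (amplitudes in microvolts).
#' @param path output file path.
#' @param patient_id,recording_id free-text header fields (80 bytes each).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, patient_id = "X", recording_id = "synthetic") {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  n <- ncol(recording$data)
  if (n %% fs != 0)
    stop("recording length must be a whole number of seconds for EDF export")
  n_rec <- n %/% fs
  ns <- nrow(recording$data)
  phys_max <- apply(abs(recording$data), 1, max)
  rng <- lapply(ifelse(phys_max > 0, phys_max * 1.001, 1), .edf_range)
  phys_str <- vapply(rng, `[[`, "", "string")
  phys_max <- vapply(rng, `[[`, 0, "value")

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad(patient_id, 80), .edf_pad(recording_id, 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (ns + 1), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad("1", 8), .edf_pad(ns, 4))
  sig_hdr <- paste0(
    paste(vapply(recording$channel_labels, .edf_pad, "", width = 16), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(paste0("-", phys_str), .edf_pad, "", width = 8), collapse = ""),
    paste(vapply(phys_str, .edf_pad, "", width = 8), collapse = ""),
    paste(rep(.edf_pad("-32767", 8), ns), collapse = ""),
    paste(rep(.edf_pad("32767", 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 80), ns), collapse = ""),
    paste(rep(.edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(.edf_pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  # digital = physical / phys_max * 32767 (symmetric range)
  dig <- round(recording$data / phys_max * 32767)
  dig[dig > 32767] <- 32767; dig[dig < -32767] <- -32767
  # interleave: per record, all samples of signal 1, then signal 2, ...
  arr <- array(t(dig), dim = c(fs, n_rec, ns))       # sample x record x signal
  out <- as.integer(aperm(arr, c(1, 3, 2)))          # sample, signal, record
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file into an [eeg_recording]
#'
#' Supports the continuous-recording subset written by [write_edf()] (equal
#' sampling rate across signals, integer samples-per-record).
#'
#' @param path EDF file path.
#' @return An [eeg_recording].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd_num <- function(width) as.numeric(rd_str(width))
  rd_str(8); rd_str(80); rd_str(80); rd_str(8); rd_str(8)
  rd_num(8); rd_str(44)
  n_rec <- rd_num(8); rec_dur <- rd_num(8); ns <- as.integer(rd_num(4))
  rdn <- function(width) vapply(seq_len(ns), function(i) rd_str(width), "")
  labels <- rdn(16); rdn(80); rdn(8)
  phys_min <- as.numeric(rdn(8)); phys_max <- as.numeric(rdn(8))
  dig_min <- as.numeric(rdn(8)); dig_max <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8)); rdn(32)
  if (length(unique(spr)) != 1)
    stop("read_edf supports a single common sampling rate only")
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 signed = TRUE, endian = "little")
  arr <- array(raw, dim = c(spr[1], ns, n_rec))
  dig <- matrix(aperm(arr, c(1, 3, 2)), nrow = spr[1] * n_rec, ncol = ns)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_max - scale * dig_max
  phys <- sweep(sweep(dig, 2, scale, `*`), 2, offset, `+`)
  eeg_recording(t(phys), labels, spr[1] / rec_dur)
}
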