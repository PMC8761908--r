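#' EEG recording container
#'
#' A multichannel sampled EEG signal. Rows of `data` are channels (in the
#' order of `channel_labels`), columns are samples, amplitudes in microvolts.
#'
#' @param data numeric matrix, channels x samples.
#' @param channel_labels character vector of unique channel names, one per row.
#' @param sampling_rate sampling frequency in Hz.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels, sampling_rate) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (length(channel_labels) != nrow(data))
    stop("`channel_labels` must have one entry per row of `data`")
  if (anyDuplicated(channel_labels))
    stop("`channel_labels` must be unique")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number")
  rownames(data) <- channel_labels
  structure(
    list(data = data, channel_labels = as.character(channel_labels),
         sampling_rate = sampling_rate),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  invisible(x)
}

#' A single fixed-length EEG epoch
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param channel_labels channel names, one per row.
#' @param sampling_rate sampling frequency in Hz.
#' @param epoch_index index of the epoch within its source recording.
#' @param subject_id optional subject identifier.
#' @return An object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(data, channel_labels, sampling_rate,
                      epoch_index = NA_integer_, subject_id = NA_character_) {
  rec <- eeg_recording(data, channel_labels, sampling_rate)
  structure(
    list(data = rec$data, channel_labels = rec$channel_labels,
         sampling_rate = sampling_rate, epoch_index = epoch_index,
         subject_id = subject_id),
    class = c("eeg_epoch", "eeg_recording"))
}

#' Standard 19-channel 10-20 montage labels
#' @return Character vector of the 19 scalp electrode labels.
#' @export
default_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz")
}

#' Frequency band definition
#'
#' @param name band name (conventionally one of delta, theta, alpha, beta).
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0.5 <= low_hz < high_hz <= 30`.
#' @return A one-row data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!is.character(name) || length(name) != 1)
    stop("`name` must be a single string")
  if (low_hz < 0.5 || high_hz > 30 || low_hz >= high_hz)
    stop("band edges must satisfy 0.5 <= low_hz < high_hz <= 30; got [",
         low_hz, ", ", high_hz, "]")
  data.frame(name = name, low_hz = low_hz, high_hz = high_hz,
             stringsAsFactors = FALSE)
}

#' Clinical EEG bands tiling 0.5-30 Hz
#'
#' The conventional clinical bands: delta 0.5-4, theta 4-8, alpha 8-13,
#' beta 13-30 Hz. Together they tile the 0.5-30 Hz broadband range without
#' overlap.
#'
#' @return A data frame with one row per band.
#' @export
default_bands <- function() {
  rbind(band_definition("delta", 0.5, 4),
        band_definition("theta", 4, 8),
        band_definition("alpha", 8, 13),
        band_definition("beta", 13, 30))
}

# --- zero-phase Butterworth filtering -------------------------------------

# Steady-state initial conditions for a direct-form-II-transposed filter
# (companion-matrix solve, so that filtering a constant has no transient).
.lfilter_zi <- function(b, a) {
  nc <- max(length(b), length(a))
  b <- c(b, rep(0, nc - length(b)))
  a <- c(a, rep(0, nc - length(a)))
  b <- b / a[1]; a <- a / a[1]
  n <- nc - 1
  A <- matrix(0, n, n)
  A[1, ] <- -a[-1]
  if (n > 1) A[cbind(2:n, 1:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  M <- diag(n) - t(A)
  # narrow bands put a pole next to z = 1 and make M numerically singular;
  # the minimum-norm (pseudoinverse) solution is the right steady state
  # because the near-null direction is the DC mode the band-pass rejects
  sv <- svd(M)
  keep <- sv$d > max(dim(M)) * .Machine$double.eps * sv$d[1]
  drop(sv$v[, keep, drop = FALSE] %*%
         ((t(sv$u[, keep, drop = FALSE]) %*% B) / sv$d[keep]))
}

# Design a Butterworth filter and package everything the C++ kernel needs.
.design_filter <- function(low_hz, high_hz, fs, order) {
  nyq <- fs / 2
  if (high_hz >= nyq) stop("upper band edge must be below the Nyquist frequency")
  bt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  nc <- max(length(bt$b), length(bt$a))
  # 3 s of odd-reflection padding: long enough for the slowest band-edge
  # pole transients (time constants of a few hundred samples) to die out
  list(b = bt$b, a = bt$a, zi = .lfilter_zi(bt$b, bt$a),
       padlen = max(3L * (nc - 1L), as.integer(3 * fs)))
}

# Apply a designed zero-phase filter to a channels-x-samples matrix.
.filtfilt_channels <- function(data, flt) {
  t(.filtfilt_cpp(flt$b, flt$a, t(data), flt$zi, flt$padlen))
}

#' Broadband 0.5-30 Hz zero-phase band-pass filter
#'
#' Retains the 0.5-30 Hz content of every channel with a Butterworth filter
#' applied forward and backward (zero phase); the DC component is removed by
#' the high-pass edge.
#'
#' @param recording an [eeg_recording].
#' @param low_hz,high_hz pass-band edges in Hz (defaults 0.5 and 30).
#' @param order Butterworth filter order (default 4).
#' @return The filtered recording (same class and shape).
#' @export
bandpass_broadband <- function(recording, low_hz = 0.5, high_hz = 30, order = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (recording$sampling_rate < 64)
    stop("sampling rate must be at least 64 Hz")
  flt <- .design_filter(low_hz, high_hz, recording$sampling_rate, order)
  if (ncol(recording$data) <= flt$padlen)
    stop("recording too short to filter: need more than ", flt$padlen, " samples")
  recording$data <- .filtfilt_channels(recording$data, flt)
  recording
}

#' Average-reference an epoch
#'
#' Subtracts the instantaneous cross-channel mean from every channel, so the
#' per-sample channel sums of the output are zero.
#'
#' @param epoch an [eeg_epoch] (or any `eeg_recording`) with at least two
#'   channels.
#' @return The re-referenced object.
#' @export
rereference_average <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_recording"))
  if (nrow(epoch$data) < 2)
    stop("average reference requires at least 2 channels")
  epoch$data <- sweep(epoch$data, 2, colMeans(epoch$data))
  epoch
}

#' Normalize channel labels to the montage's naming convention
#'
#' Renames channels by an alias map, by default translating the modern
#' temporal-chain names (T7/T8/P7/P8) to the legacy 10-20 labels
#' (T3/T4/T5/T6) used throughout this package. Unmapped labels pass through.
#'
#' @param recording an [eeg_recording].
#' @param map named character vector, `names(map)` = labels to rename,
#'   values = replacement labels.
#' @return The recording with normalized `channel_labels`.
#' @export
normalize_channel_labels <- function(recording,
                                     map = c(T7 = "T3", T8 = "T4",
                                             P7 = "T5", P8 = "T6")) {
  stopifnot(inherits(recording, "eeg_recording"))
  hit <- recording$channel_labels %in% names(map)
  recording$channel_labels[hit] <- unname(map[recording$channel_labels[hit]])
  if (anyDuplicated(recording$channel_labels))
    stop("channel-label normalization produced duplicate labels")
  rownames(recording$data) <- recording$channel_labels
  recording
}

# Shared epoch-window selection: non-overlapping half-open windows of `len`
# samples starting at sample one; `n_select` window indices sampled uniformly
# without replacement under `seed`, returned in chronological order.
.select_windows <- function(n_samples, len, n_select, seed, eligible = NULL) {
  n_windows <- n_samples %/% len
  idx <- seq_len(n_windows)
  if (!is.null(eligible)) {
    if (length(eligible) != n_windows)
      stop("`eligible` must have one entry per complete window (", n_windows, ")")
    idx <- idx[eligible]
  }
  if (length(idx) < n_select)
    stop("only ", length(idx), " eligible complete windows available, ",
         n_select, " requested")
  sort(with_seed(seed, sample(idx, n_select)))
}

#' Cut a recording into 15-s epochs and randomly select a subset
#'
#' The recording is divided into non-overlapping consecutive windows of
#' `epoch_seconds` starting at sample one (half-open windows; a trailing
#' partial window is discarded), and `n_select` of them are sampled uniformly
#' without replacement under the given seed. Selected epochs are returned in
#' chronological order.
#'
#' @param recording an [eeg_recording].
#' @param n_select number of epochs to select.
#' @param epoch_seconds epoch duration in seconds (default 15).
#' @param seed integer seed controlling the selection.
#' @param eligible optional logical vector, one entry per complete window;
#'   windows marked `FALSE` (e.g. containing discharges or artifacts) are
#'   excluded before selection. Absent mask means all windows are eligible.
#' @param subject_id optional subject identifier stamped on the epochs.
#' @return A list of [eeg_epoch] objects.
#' @export
epoch_and_select <- function(recording, n_select, epoch_seconds = 15,
                             seed = 1L, eligible = NULL, subject_id = NA_character_) {
  stopifnot(inherits(recording, "eeg_recording"))
  len <- epoch_seconds * recording$sampling_rate
  if (len != round(len)) stop("epoch length must be a whole number of samples")
  len <- as.integer(round(len))
  chosen <- .select_windows(ncol(recording$data), len, n_select, seed, eligible)
  lapply(seq_along(chosen), function(j) {
    w <- chosen[j]
    eeg_epoch(recording$data[, ((w - 1) * len + 1):(w * len), drop = FALSE],
              recording$channel_labels, recording$sampling_rate,
              epoch_index = w, subject_id = subject_id)
  })
}

#' Decompose an epoch (or recording) into frequency bands
#'
#' Produces one zero-phase band-filtered copy per band; shape and class are
#' preserved.
#'
#' @param x an [eeg_epoch] or [eeg_recording].
#' @param bands a band-definition data frame as from [default_bands()].
#' @param order Butterworth filter order (default 4).
#' @return A named list (one entry per band) of filtered copies of `x`.
#' @export
band_decompose <- function(x, bands = default_bands(), order = 4) {
  stopifnot(inherits(x, "eeg_recording"))
  if (any(bands$low_hz < 0.5) || any(bands$high_hz > 30) ||
      any(bands$low_hz >= bands$high_hz))
    stop("band edges must lie within [0.5, 30] Hz with low < high")
  out <- lapply(seq_len(nrow(bands)), function(i) {
    flt <- .design_filter(bands$low_hz[i], bands$high_hz[i],
                          x$sampling_rate, order)
    y <- x
    y$data <- .filtfilt_channels(x$data, flt)
    y
  })
  names(out) <- bands$name
  out
}
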