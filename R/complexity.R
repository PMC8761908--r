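#' Median binarization of a signal segment
#'
#' Maps a real-valued segment to a 0/1 sequence: 1 where the sample exceeds
#' the segment median, 0 otherwise (ties map to 0, so a constant signal is
#' all zeros). The binarization depends only on the ranks of the samples, so
#' any strictly monotone pointwise transform of the signal leaves it
#' unchanged.
#'
#' @param x numeric vector of length at least 2.
#' @return Integer vector of 0/1 symbols, same length as `x`.
#' @export
binarize_median <- function(x) {
  if (!is.numeric(x) || length(x) < 2)
    stop("`x` must be a numeric vector of length >= 2")
  as.integer(x > median(x))
}

#' Difference binarization of a signal segment
#'
#' Assigns 1 where the difference between two sequential samples is positive
#' and 0 where it is negative (a zero difference also maps to 0). The output
#' is one sample shorter than the input. Differences keep their signs under
#' positive affine maps, so the binarization is invariant to them.
#'
#' @param x numeric vector of length at least 3.
#' @return Integer vector of 0/1 symbols of length `length(x) - 1`.
#' @export
binarize_difference <- function(x) {
  if (!is.numeric(x) || length(x) < 3)
    stop("`x` must be a numeric vector of length >= 3")
  as.integer(diff(x) > 0)
}

#' LZ76 production-parsing complexity count c(n)
#'
#' Scans a binary sequence left to right, extending the current word while it
#' can be reproduced as a substring of the history extended to one symbol
#' before the current position; each failure closes a word and increments the
#' count, and the final (possibly still reproducible) word also counts. For a
#' long equiprobable random sequence `c(n)` approaches `n / log2(n)`.
#'
#' @param s integer (or numeric) vector of 0/1 symbols, length >= 2.
#' @return The integer word count `c(n)`, between 1 and `length(s)`.
#' @export
lz76_parse <- function(s) {
  if (length(s) < 2) stop("`s` must have length >= 2")
  s <- as.integer(s)
  if (anyNA(s) || any(s != 0L & s != 1L))
    stop("`s` must contain only 0/1 symbols")
  .lz76_count_cpp(s)
}

#' Normalized Lempel-Ziv complexity of a signal
#'
#' Median-binarizes the segment, runs LZ76 production parsing, and normalizes
#' the word count by `b(n) = n / log2(n)` so that long equiprobable random
#' sequences score close to 1 independently of length.
#'
#' @param x numeric vector of length at least 2.
#' @return An object of class `lzc_result`: a list with the word count `c`,
#'   the normalizer `b`, and the normalized value `lzc = c / b`.
#' @export
lzc <- function(x) {
  b <- binarize_median(x)
  n <- length(b)
  cn <- lz76_parse(b)
  bn <- n / log2(n)
  structure(list(c = cn, b = bn, lzc = cn / bn), class = "lzc_result")
}

#' Kolmogorov complexity estimate of a signal (difference method)
#'
#' The algorithmic complexity of the segment is estimated on its
#' difference-binarized sequence: the LZ76 word count `c(m)` of the 0/1
#' difference sequence (length `m = n - 1`) is normalized per symbol as
#' `c(m) * log2(m) / m` (Kaspar-Schuster estimator). The true shortest-program
#' length is uncomputable; this estimator converges to 1 for incompressible
#' sequences and is invariant under positive affine transforms of the signal.
#'
#' @param x numeric vector of length at least 3.
#' @return An object of class `kc_result`: a list with the word count `c` of
#'   the difference sequence and the estimate `kc`.
#' @export
kc <- function(x) {
  b <- binarize_difference(x)
  m <- length(b)
  cn <- lz76_parse(b)
  structure(list(c = cn, kc = cn * log2(m) / m), class = "kc_result")
}

#' @export
print.lzc_result <- function(x, ...) {
  cat(sprintf("LZC = %.4f  (c = %d, b = %.2f)\n", x$lzc, x$c, x$b))
  invisible(x)
}

#' @export
print.kc_result <- function(x, ...) {
  cat(sprintf("KC = %.4f  (c = %d)\n", x$kc, x$c))
  invisible(x)
}

#' Per-channel complexity of one epoch
#'
#' Computes, for every channel of an epoch, both the normalized Lempel-Ziv
#' complexity ([lzc]) and the difference-method Kolmogorov complexity
#' estimate ([kc]) in one pass.
#'
#' @param epoch an [eeg_epoch] (or `eeg_recording`).
#' @return A numeric matrix with rows `lzc` and `kc` and one column per
#'   channel.
#' @export
epoch_complexity <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_recording"))
  out <- .epoch_complexity_cpp(t(epoch$data))
  dimnames(out) <- list(c("lzc", "kc"), epoch$channel_labels)
  out
}

#' Band-wise complexity features for one subject
#'
#' Runs the preprocessing chain on a raw recording and returns per-subject
#' complexity features: the recording is broadband filtered (0.5-30 Hz),
#' decomposed into frequency bands (filters are applied to the continuous
#' signal, before epoching, to avoid boundary transients inside epochs),
#' cut into `epoch_seconds` epochs of which `n_epochs` are selected at random
#' under `seed`, average-referenced, and both complexity estimators are
#' computed per (epoch, channel, band). Per-subject features are the means
#' over the selected epochs.
#'
#' @param recording a raw [eeg_recording].
#' @param subject_id subject identifier attached to the output rows.
#' @param bands band definitions as from [default_bands()].
#' @param n_epochs number of epochs to select (default 15).
#' @param epoch_seconds epoch duration in seconds (default 15).
#' @param seed seed for the epoch selection.
#' @param order Butterworth filter order (default 4).
#' @param eligible optional per-window eligibility mask passed to
#'   [epoch_and_select()].
#' @param estimator which estimators to compute: `"both"` (default),
#'   `"lzc"`, or `"kc"`.
#' @return A data frame with columns `subject_id`, `channel`, `band`,
#'   `estimator` ("lzc"/"kc"), `value`.
#' @details All stages are linear and channel-homogeneous, so filtering the
#'   continuous signal, average-referencing once, and then slicing epochs is
#'   exactly equivalent to the epoch-wise composition of
#'   [bandpass_broadband()], [epoch_and_select()], [rereference_average()],
#'   [band_decompose()], and [epoch_complexity()]; the batched path is used
#'   for speed.
#' @export
extract_complexity_features <- function(recording, subject_id,
                                        bands = default_bands(),
                                        n_epochs = 15, epoch_seconds = 15,
                                        seed = 1L, order = 4, eligible = NULL,
                                        estimator = c("both", "lzc", "kc")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(recording, "eeg_recording"))
  if (recording$sampling_rate < 64) stop("sampling rate must be at least 64 Hz")
  fs <- recording$sampling_rate
  len <- as.integer(round(epoch_seconds * fs))
  chosen <- .select_windows(ncol(recording$data), len, n_epochs, seed, eligible)
  starts0 <- as.integer((chosen - 1L) * len)   # 0-based for the C++ kernel

  flt <- .design_filter(0.5, 30, fs, order)
  if (ncol(recording$data) <= flt$padlen)
    stop("recording too short to filter: need more than ", flt$padlen, " samples")
  M <- .filtfilt_cpp(flt$b, flt$a, t(recording$data), flt$zi, flt$padlen)
  want <- c(lzc = estimator != "kc", kc = estimator != "lzc")
  acc <- vector("list", nrow(bands))
  for (i in seq_len(nrow(bands))) {
    bf <- .design_filter(bands$low_hz[i], bands$high_hz[i], fs, order)
    Mb <- .filtfilt_cpp(bf$b, bf$a, M, bf$zi, bf$padlen)
    cx <- .epochs_complexity_cpp(Mb, starts0, len, want["lzc"], want["kc"],
                                 TRUE)
    rows <- lapply(names(want)[want], function(est) {
      v <- rowMeans(cx[[est]])                 # mean over selected epochs
      data.frame(subject_id = subject_id, channel = recording$channel_labels,
                 band = bands$name[i], estimator = est, value = v,
                 stringsAsFactors = FALSE)
    })
    acc[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out
}
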