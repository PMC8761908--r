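make_rec <- function(x, fs = 256, labels = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(x)))
  eeg_recording(x, labels, fs)
}

test_that("broadband filter passes 10 Hz and rejects 50 Hz", {
  tt <- seq(1 / 256, 60, by = 1 / 256)
  mid <- 3000:12000  # away from edges
  s50 <- sin(2 * pi * 50 * tt)
  s10 <- sin(2 * pi * 10 * tt)
  y50 <- bandpass_broadband(make_rec(s50))$data[1, ]
  y10 <- bandpass_broadband(make_rec(s10))$data[1, ]
  expect_lt(sqrt(mean(y50[mid]^2)) / sqrt(mean(s50[mid]^2)), 0.05)
  expect_gt(sqrt(mean(y10[mid]^2)) / sqrt(mean(s10[mid]^2)), 0.90)
  # linearity: zero in, zero out
  expect_equal(bandpass_broadband(make_rec(rep(0, 4000)))$data[1, ],
               rep(0, 4000))
  # DC removal
  ydc <- bandpass_broadband(make_rec(rep(3, 4000)))$data[1, ]
  expect_lt(max(abs(ydc[1000:3000])), 1e-6)
  expect_error(bandpass_broadband(make_rec(rnorm(10))), "too short")
})

test_that("average reference zeroes the per-sample channel sums", {
  withr::local_seed(1)
  ep <- eeg_epoch(matrix(rnorm(5 * 100), 5), paste0("c", 1:5), 256)
  re <- rereference_average(ep)
  expect_lt(max(abs(colSums(re$data))), 1e-9 * max(abs(ep$data)))
  # idempotent on already zero-mean data
  expect_equal(rereference_average(re)$data, re$data)
  # two antisymmetric channels are unchanged
  v <- rnorm(50)
  ep2 <- eeg_epoch(rbind(v, -v), c("a", "b"), 256)
  expect_equal(rereference_average(ep2)$data, ep2$data,
               ignore_attr = TRUE)
  ep1 <- eeg_epoch(matrix(v, 1), "a", 256)
  expect_error(rereference_average(ep1), "2 channels")
})

test_that("epoching selects non-overlapping 15-s windows reproducibly", {
  withr::local_seed(2)
  rec <- make_rec(matrix(rnorm(2 * 256 * 70), 2), 256)  # 70 s -> 4 windows
  eps <- epoch_and_select(rec, 3, seed = 9)
  expect_length(eps, 3)
  expect_true(all(vapply(eps, function(e) ncol(e$data), 0) == 3840))
  idx <- vapply(eps, `[[`, 0L, "epoch_index")
  expect_identical(idx, sort(unique(idx)))  # chronological, no repeats
  eps2 <- epoch_and_select(rec, 3, seed = 9)
  expect_identical(lapply(eps, `[[`, "data"), lapply(eps2, `[[`, "data"))
  # forced selection takes every window regardless of seed
  all1 <- epoch_and_select(rec, 4, seed = 1)
  all2 <- epoch_and_select(rec, 4, seed = 99)
  expect_identical(vapply(all1, `[[`, 0L, "epoch_index"), 1:4)
  expect_identical(lapply(all1, `[[`, "data"), lapply(all2, `[[`, "data"))
  expect_error(epoch_and_select(rec, 5), "4 eligible")
  # eligibility mask excludes windows before selection
  eps3 <- epoch_and_select(rec, 2, seed = 1,
                           eligible = c(TRUE, FALSE, TRUE, FALSE))
  expect_true(all(vapply(eps3, `[[`, 0L, "epoch_index") %in% c(1L, 3L)))
  # epochs tile the recording: concatenation reproduces the analyzed span
  expect_equal(do.call(cbind, lapply(all1, `[[`, "data")),
               rec$data[, 1:(4 * 3840)], ignore_attr = TRUE)
})

test_that("band decomposition routes energy to the right band", {
  tt <- seq(1 / 256, 30, by = 1 / 256)
  mid <- 1500:6000
  bands <- default_bands()
  energy_by_band <- function(f) {
    rec <- make_rec(sin(2 * pi * f * tt))
    bd <- band_decompose(rec, bands)
    vapply(bd, function(b) sum(b$data[1, mid]^2), 0)
  }
  e10 <- energy_by_band(10)
  expect_gt(e10["alpha"] / sum(e10), 0.90)
  e2 <- energy_by_band(2)
  expect_identical(names(which.max(e2)), "delta")
  bad <- data.frame(name = "x", low_hz = 0.3, high_hz = 29)
  expect_error(band_decompose(make_rec(sin(tt)), bad), "within")
})

test_that("band variances of white noise nearly tile the broadband variance", {
  withr::local_seed(3)
  rec <- make_rec(matrix(rnorm(2 * 57600), 2), 256)
  bb <- bandpass_broadband(rec)
  bd <- band_decompose(bb)
  mid <- 2000:55000
  v_bb <- mean(apply(bb$data[, mid], 1, var))
  v_sum <- sum(vapply(bd, function(b) mean(apply(b$data[, mid], 1, var)), 0))
  expect_gt(v_sum / v_bb, 0.85)
  expect_lt(v_sum / v_bb, 1.15)
})

test_that("zero-phase filtering commutes with time reversal", {
  withr::local_seed(4)
  x <- rnorm(6000)
  fwd <- band_decompose(make_rec(x))$alpha$data[1, ]
  resv <- band_decompose(make_rec(rev(x)))$alpha$data[1, ]
  expect_equal(fwd, rev(resv), tolerance = 1e-6)
})

test_that("channel-label normalization maps temporal-chain aliases", {
  rec <- make_rec(matrix(rnorm(3 * 10), 3), labels = c("Fp1", "T7", "P8"))
  out <- normalize_channel_labels(rec)
  expect_identical(out$channel_labels, c("Fp1", "T3", "T6"))
  expect_identical(rownames(out$data), out$channel_labels)
  expect_identical(out$data[2, ], rec$data[2, ])
  rec2 <- make_rec(matrix(rnorm(2 * 10), 2), labels = c("T3", "T7"))
  expect_error(normalize_channel_labels(rec2), "duplicate")
})

test_that("recording and band containers validate their invariants", {
  expect_error(eeg_recording(matrix(1:4, 2), c("a", "a"), 256), "unique")
  expect_error(eeg_recording(matrix(1:4, 2), "a", 256), "one entry per row")
  expect_error(eeg_recording(matrix(1:4, 2), c("a", "b"), -1), "positive")
  expect_error(band_definition("d", 0.1, 4), "0.5")
  expect_error(band_definition("d", 8, 4), "0.5")
  expect_length(default_channels(), 19)
  b <- default_bands()
  expect_equal(b$low_hz[-1], b$high_hz[-nrow(b)])  # bands tile [0.5, 30]
  expect_equal(b$low_hz[1], 0.5)
  expect_equal(b$high_hz[nrow(b)], 30)
})
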