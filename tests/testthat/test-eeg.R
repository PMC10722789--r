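test_that("skirt exclusion on the 128-channel montage retains 82 channels", {
  m <- build_montage("egi128")
  expect_equal(nrow(m$channels), 128)
  expect_length(m$skirt, 46)
  expect_length(retained_channels(m), 82)
  expect_true(all(m$mastoids %in% retained_channels(m)))
  # override must be validated
  expect_error(build_montage("egi128", skirt = "E999"), "unknown skirt")
})

test_that("PSD of a unit 10 Hz sine is 0.5 uV^2/Hz at the 10 Hz bin", {
  fs <- 128
  tt <- (0:(fs * 8 - 1)) / fs
  data <- rbind(a = sin(2 * pi * 10 * tt), b = sin(2 * pi * 10 * tt))
  ep <- make_epochs(data, fs, c("a", "b"))
  psd <- compute_psd(ep)
  expect_equal(psd$freqs, 0:64)
  i10 <- which(psd$freqs == 10)
  expect_equal(unname(psd$psd[, i10]), c(0.5, 0.5), tolerance = 1e-10)
  expect_lt(max(abs(psd$psd[, -i10])), 1e-20)

  # zero signal -> all-zero PSD
  psd0 <- compute_psd(make_epochs(matrix(0, 2, fs * 4), fs, c("a", "b")))
  expect_true(all(psd0$psd == 0))
})

test_that("band power closed forms: 5 Hz -> theta 0.125; 10 Hz -> alpha 0.5/6", {
  fs <- 128
  tt <- (0:(fs * 8 - 1)) / fs
  ep5 <- make_epochs(matrix(sin(2 * pi * 5 * tt), 1), fs, "a")
  b5 <- band_power(compute_psd(ep5), "theta")
  expect_equal(b5$grand, 0.5 / 4, tolerance = 1e-10)
  expect_equal(band_power(compute_psd(ep5), "alpha")$grand, 0, tolerance = 1e-12)

  ep10 <- make_epochs(matrix(sin(2 * pi * 10 * tt), 1), fs, "a")
  expect_equal(band_power(compute_psd(ep10), "alpha")$grand, 0.5 / 6,
               tolerance = 1e-10)
  expect_equal(band_power(compute_psd(ep10), "theta")$grand, 0, tolerance = 1e-12)
})

test_that("flat spectrum gives equal band power in both bands; Nyquist guarded", {
  psd <- structure(list(freqs = 0:64,
                        psd = matrix(3.7, 1, 65, dimnames = list("a", NULL)),
                        labels = "a", n_epochs = 1),
                   class = "psd_spectrum")
  expect_equal(band_power(psd, "theta")$grand, 3.7)
  expect_equal(band_power(psd, "alpha")$grand, 3.7)
  expect_error(band_power(psd, c(60, 70)), "Nyquist")
})

test_that("one-sided PSD satisfies Parseval on white noise", {
  set.seed(7)
  fs <- 128
  x <- matrix(rnorm(fs * 100), 1)
  ep <- make_epochs(x, fs, "a")
  psd <- compute_psd(ep)
  total <- sum(psd$psd) * 1  # df = 1 Hz
  expect_equal(total, mean(x^2), tolerance = 0.05)
})

test_that("scaling the signal by k scales PSD and band power by k^2", {
  set.seed(3)
  fs <- 128
  x <- matrix(rnorm(fs * 10), 1)
  p1 <- compute_psd(make_epochs(x, fs, "a"))
  p3 <- compute_psd(make_epochs(3 * x, fs, "a"))
  expect_equal(p3$psd, 9 * p1$psd, tolerance = 1e-12)
  expect_equal(band_power(p3, "alpha")$grand,
               9 * band_power(p1, "alpha")$grand, tolerance = 1e-12)
})

test_that("zero-phase filter passes the band, kills DC, line noise and drift", {
  fs <- 128
  tt <- (0:(fs * 20 - 1)) / fs
  gain_at <- function(f) {
    x <- matrix(sin(2 * pi * f * tt), 1)
    y <- filter_eeg(x, fs)
    sqrt(mean(y[, (5 * fs):(15 * fs)]^2) / mean(x[, (5 * fs):(15 * fs)]^2))
  }
  expect_equal(gain_at(10), 1, tolerance = 0.01)
  expect_equal(gain_at(5), 1, tolerance = 0.01)
  expect_lt(gain_at(50), 1e-3)   # notch
  expect_lt(gain_at(0.05), 1e-3) # below high-pass
  expect_lt(gain_at(60), 0.15)   # above low-pass
  # DC is removed exactly
  dc <- filter_eeg(matrix(1, 1, fs * 20), fs)
  expect_lt(mean(dc^2), 1e-20)
})

test_that("frequency-domain zero-phase filtering matches filtfilt away from edges", {
  skip_if_not_installed("signal")
  set.seed(5)
  fs <- 128
  n <- fs * 30
  x <- rnorm(n)
  mine <- as.vector(filter_eeg(matrix(x, 1), fs, bandpass = c(0.5, 45),
                               notch = NULL))
  bf <- signal::butter(4, c(0.5, 45) / (fs / 2), type = "pass")
  ref <- signal::filtfilt(bf, x)
  # analog-prototype magnitude vs bilinear-transform digital filter: close but
  # not identical near Nyquist
  mid <- (5 * fs):(25 * fs)
  expect_gt(stats::cor(mine[mid], ref[mid]), 0.99)
  expect_equal(stats::sd(mine[mid]), stats::sd(ref[mid]), tolerance = 0.05)
})

test_that("preprocess retains the right channels and rejects the spiked epoch", {
  mont <- build_montage("desk32")
  fs <- 128; dur <- 20
  tt <- (0:(fs * dur - 1)) / fs
  set.seed(21)
  amps <- runif(nrow(mont$channels), 6, 10)   # heterogeneous channel amplitudes
  data <- outer(amps, sin(2 * pi * 10 * tt))
  rec <- eeg_recording(data, fs, mont$channels$label)
  # plant a 500 uV spike inside epoch 5 on a retained channel
  ci <- which(rec$labels == "C3")
  rec$data[ci, 128 * 4 + 60] <- rec$data[ci, 128 * 4 + 60] + 500
  epo <- preprocess(rec, params = list(blink_regress = FALSE))
  expect_setequal(epo$labels, retained_channels(mont))
  expect_identical(epo$interpolated, character(0))
  expect_true(5 %in% epo$rejected$epoch)
  expect_equal(dim(epo$epochs)[1], 20 - nrow(epo$rejected))
  # the retained epochs must be well below the rejection threshold
  expect_lt(max(abs(epo$epochs)), 150)
})

test_that("a dead channel is detected and interpolated from its neighbors", {
  mont <- build_montage("desk32")
  fs <- 128; dur <- 15
  tt <- (0:(fs * dur - 1)) / fs
  set.seed(22)
  amps <- runif(nrow(mont$channels), 6, 10)
  data <- outer(amps, sin(2 * pi * 10 * tt)) +
    matrix(rnorm(nrow(mont$channels) * fs * dur), nrow(mont$channels))
  ci <- which(mont$channels$label == "CP3")
  data[ci, ] <- rnorm(fs * dur, sd = 0.001)   # essentially flat channel
  rec <- eeg_recording(data, fs, mont$channels$label)
  epo <- preprocess(rec, params = list(blink_regress = FALSE))
  expect_true("CP3" %in% epo$interpolated)
  # interpolated channel now carries neighbor-scale signal
  v <- apply(epo$epochs[, match("CP3", epo$labels), ], 1, stats::var)
  expect_gt(mean(v), 1)
})

test_that("preprocess on constant input returns near-zero power", {
  mont <- build_montage("desk32")
  data <- matrix(7.3, nrow(mont$channels), 128 * 12)
  rec <- eeg_recording(data, 128, mont$channels$label)
  epo <- preprocess(rec, params = list(blink_regress = FALSE))
  expect_lt(mean(epo$epochs^2), 1e-12)
})

test_that("preprocess errors when everything is rejected or mastoids missing", {
  mont <- build_montage("desk32")
  set.seed(2)
  data <- matrix(rnorm(nrow(mont$channels) * 128 * 12, sd = 400),
                 nrow(mont$channels))
  rec <- eeg_recording(data, 128, mont$channels$label)
  expect_error(preprocess(rec), "no clean data")
  keep <- setdiff(mont$channels$label, "M1")
  expect_error(
    eeg_recording(data[match(keep, mont$channels$label), ], 128, keep),
    "mastoid")
})

test_that("re-referencing and channel exclusion commute with epoch-averaged PSD", {
  # with zero mastoid signal, re-referencing is a no-op: PSD of preprocess
  # output equals PSD computed from the filtered retained channels directly
  set.seed(9)
  mont <- build_montage("desk32")
  nch <- nrow(mont$channels)
  data <- matrix(rnorm(nch * 128 * 15, sd = 5), nch)
  data[mont$channels$label %in% mont$mastoids, ] <- 0
  rec <- eeg_recording(data, 128, mont$channels$label)
  epo <- preprocess(rec, params = list(blink_regress = FALSE,
                                       p2p_reject = Inf, jump_reject = Inf,
                                       bad_z = Inf))
  psd1 <- compute_psd(epo)
  filt <- filter_eeg(data, 128)[match(epo$labels, mont$channels$label), ]
  psd2 <- compute_psd(make_epochs(filt, 128, epo$labels))
  expect_equal(psd1$psd, psd2$psd, tolerance = 1e-10)
})
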