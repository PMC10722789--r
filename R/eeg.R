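# squared-magnitude responses of the analysis filters (zero-phase application)
butter_bp_mag2 <- function(f, low, high, order = 4) {
  r <- rep(0, length(f))
  pos <- f > 0
  w <- (f[pos]^2 - low * high) / (f[pos] * (high - low))
  r[pos] <- 1 / (1 + w^(2 * order))
  r
}

notch_mag2 <- function(f, f0, q = 30) {
  num <- (f^2 - f0^2)^2
  num / (num + (f * f0 / q)^2)
}

#' Zero-phase filter a channels-by-samples matrix
#'
#' Applies the analysis filter chain (Butterworth bandpass + IIR notch) with
#' zero phase by multiplying the signal spectrum with the squared magnitude
#' response -- the transfer function of forward-backward filtering, free of
#' edge transients. The DC gain of the bandpass is exactly zero.
#'
#' @param data Channels-by-samples matrix.
#' @param fs Sampling rate, Hz.
#' @param bandpass Length-2 passband in Hz, or `NULL` to skip.
#' @param notch Notch centre frequency in Hz, or `NULL` to skip.
#' @param notch_q Notch quality factor (bandwidth = `notch / notch_q`).
#' @param order Butterworth order (before the zero-phase doubling).
#' @return Filtered matrix of the same shape.
#' @export
filter_eeg <- function(data, fs, bandpass = c(0.5, 45), notch = 50,
                       notch_q = 30, order = 4) {
  g <- filter_gain(ncol(data), fs, bandpass, notch, notch_q, order)
  t(filter_fd(t(data), g))
}

filter_gain <- function(n, fs, bandpass = c(0.5, 45), notch = 50,
                        notch_q = 30, order = 4) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n  # two-sided frequency axis
  g <- rep(1, n)
  # one-pass power gain |H(f)|^2 is the amplitude gain of forward-backward filtering
  if (!is.null(bandpass)) {
    g <- g * butter_bp_mag2(f, bandpass[1], bandpass[2], order)
  }
  if (!is.null(notch) && notch < fs / 2) {
    g <- g * notch_mag2(f, notch, notch_q)
  }
  g
}

# multiply the spectrum of each column (samples x channels, real) by the real
# symmetric gain g; two real channels are packed into one complex FFT
filter_fd <- function(x, g) {
  n <- nrow(x)
  nc <- ncol(x)
  odd <- seq(1, nc, by = 2)
  pad <- length(odd) * 2 > nc
  z <- x[, odd, drop = FALSE] +
    (0 + 1i) * cbind(x[, odd[odd + 1 <= nc] + 1, drop = FALSE],
                     if (pad) matrix(0, n, 1))
  zf <- stats::mvfft(stats::mvfft(z) * g, inverse = TRUE) / n
  out <- matrix(0, n, nc)
  out[, odd] <- Re(zf)
  even <- odd[odd + 1 <= nc] + 1
  out[, even] <- Im(zf[, seq_along(even), drop = FALSE])
  out
}

#' Preprocess an EEG recording into clean 1-s epochs
#'
#' Applies, in order: zero-phase bandpass (0.5-45 Hz) and 50 Hz notch
#' filtering; exclusion of the montage's skirt channels; robust bad-channel
#' detection (log-RMS outliers) with inverse-distance interpolation over the 4
#' nearest good neighbors; segmentation into 1-s epochs; epoch rejection by
#' peak-to-peak amplitude (default 150 uV) and sample-to-sample jump (default
#' 100 uV); blink removal by regression on a low-passed frontal template; and
#' re-referencing to the mastoid average. Every removal and interpolation is
#' logged. The per-step parameters can be overridden through `params`.
#'
#' @param rec An [eeg_recording()].
#' @param params Named list overriding any of: `bandpass` (c(0.5, 45)),
#'   `notch` (50), `notch_q` (30), `filter_order` (4), `bad_z` (4),
#'   `epoch_s` (1), `p2p_reject` (150), `jump_reject` (100),
#'   `blink_regress` (TRUE), `blink_lowpass` (4).
#' @return An object of class `epoched_eeg`: list with `fs`, `labels`
#'   (retained channels), `epochs` (epoch x channel x sample array, uV),
#'   `rejected` (tibble: epoch, reason), `interpolated` (channel labels),
#'   `montage`, `participant_id`.
#' @export
preprocess <- function(rec, params = list()) {
  stopifnot(inherits(rec, "eeg_recording"))
  p <- utils::modifyList(list(
    bandpass = c(0.5, 45), notch = 50, notch_q = 30, filter_order = 4,
    bad_z = 4, epoch_s = 1, p2p_reject = 150, jump_reject = 100,
    blink_regress = TRUE, blink_lowpass = 4
  ), params)
  if (ncol(rec$data) < 10 * rec$fs) stop("recording shorter than 10 s")
  mont <- build_montage(rec$montage)
  if (!all(mont$mastoids %in% rec$labels)) stop("mastoid channels absent")

  # work sample-major; filtering is per-channel, so the skirt channels can be
  # dropped first without changing the retained channels' output
  keep <- setdiff(rec$labels, mont$skirt)
  xs <- t(rec$data[match(keep, rec$labels), , drop = FALSE])  # samples x channels
  g <- filter_gain(nrow(xs), rec$fs, p$bandpass, p$notch, p$notch_q, p$filter_order)
  xs <- filter_fd(xs, g)
  nch <- length(keep)

  # bad channels: robust outliers of log RMS amplitude
  rms <- sqrt(colMeans(xs^2))
  lz <- log(pmax(rms, .Machine$double.eps))
  med <- stats::median(lz)
  # floor the spread estimate so near-identical channels are never flagged
  madv <- max(stats::mad(lz), 0.05)
  bad <- which(abs(lz - med) / madv > p$bad_z)
  interpolated <- character(0)
  if (length(bad) > 0 && length(bad) < nch - 4) {
    xy <- mont$channels[match(keep, mont$channels$label), ]
    good <- setdiff(seq_len(nch), bad)
    for (b in bad) {
      d <- sqrt((xy$x[good] - xy$x[b])^2 + (xy$y[good] - xy$y[b])^2)
      nb <- good[order(d)][1:min(4, length(good))]
      w <- 1 / pmax(d[order(d)][1:length(nb)], 1e-6)
      xs[, b] <- as.vector(xs[, nb, drop = FALSE] %*% (w / sum(w)))
      interpolated <- c(interpolated, keep[b])
    }
  }

  # 1-s epochs
  len <- round(rec$fs * p$epoch_s)
  n_ep <- floor(nrow(xs) / len)
  if (n_ep < 1) stop("no clean data: recording too short for one epoch")
  xs <- xs[seq_len(n_ep * len), , drop = FALSE]

  # per (epoch, channel) peak-to-peak and max sample jump, vectorized
  m <- matrix(xs, nrow = len)                     # len x (n_ep * nch), epoch-fast
  cmax <- apply(m, 2, max)
  cmin <- apply(m, 2, min)
  p2p_ec <- matrix(cmax - cmin, n_ep, nch)
  jmp_ec <- matrix(apply(abs(m[-1, , drop = FALSE] - m[-len, , drop = FALSE]), 2, max),
                   n_ep, nch)
  p2p <- do.call(pmax, as.data.frame(p2p_ec))
  jump <- do.call(pmax, as.data.frame(jmp_ec))
  drop_p2p <- p2p > p$p2p_reject
  drop_jump <- jump > p$jump_reject & !drop_p2p
  rejected <- dplyr::bind_rows(
    tibble::tibble(epoch = which(drop_p2p), reason = "peak-to-peak"),
    tibble::tibble(epoch = which(drop_jump), reason = "sample-jump")
  )
  keep_ep <- which(!(drop_p2p | drop_jump))
  if (length(keep_ep) == 0) stop("no clean data: all epochs rejected")
  ne <- length(keep_ep)
  if (ne < n_ep) {
    sel <- as.vector(outer(seq_len(len), (keep_ep - 1) * len, `+`))
    xs <- xs[sel, , drop = FALSE]   # concatenated retained epochs, sample-major
  }

  # blink regression: low-passed frontal template, one coefficient per channel
  frontal <- intersect(mont$frontal, keep)
  if (isTRUE(p$blink_regress) && length(frontal) > 0) {
    fi <- match(frontal, keep)
    templ <- filter_fd(
      matrix(rowMeans(xs[, fi, drop = FALSE]), ncol = 1),
      filter_gain(nrow(xs), rec$fs, bandpass = c(0.3, p$blink_lowpass),
                  notch = NULL))[, 1]
    vt <- sum(templ^2)
    if (vt > 0) {
      beta <- as.vector(crossprod(xs, templ)) / vt
      xs <- xs - outer(templ, beta)
    }
  }

  # re-reference to the mastoid average
  mi <- match(mont$mastoids, keep)
  xs <- xs - rowMeans(xs[, mi, drop = FALSE])

  # epoch x channel x sample
  ep <- aperm(array(xs, dim = c(len, ne, nch)), c(2, 3, 1))

  structure(list(
    fs = rec$fs, labels = keep, epochs = ep,
    rejected = rejected, interpolated = interpolated,
    montage = rec$montage, participant_id = rec$participant_id
  ), class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  cat(sprintf("<epoched_eeg %s: %d epochs x %d ch x %d samples (%d rejected)>\n",
              x$participant_id, dim(x$epochs)[1], dim(x$epochs)[2],
              dim(x$epochs)[3], nrow(x$rejected)))
  invisible(x)
}

#' One-sided FFT power spectral density
#'
#' Per epoch and channel: discrete Fourier transform, squared magnitude with
#' periodogram normalization, conversion of the two-sided spectrum to
#' one-sided (doubling all bins except DC and Nyquist), division by the
#' frequency resolution, then averaging across epochs. For 1-s epochs the
#' frequency resolution is exactly 1 Hz. A rectangular window (no taper) is
#' used, matching the bare-FFT estimator; set `window = "hann"` for a tapered
#' variant.
#'
#' @param epochs An [preprocess()] result (`epoched_eeg`).
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return An object of class `psd_spectrum`: list with `freqs` (Hz), `psd`
#'   (channel x frequency matrix, uV^2/Hz), `labels`, `n_epochs`.
#' @export
compute_psd <- function(epochs, window = c("rectangular", "hann")) {
  stopifnot(inherits(epochs, "epoched_eeg"))
  window <- match.arg(window)
  ne <- dim(epochs$epochs)[1]
  if (ne < 1) stop("zero epochs")
  nch <- dim(epochs$epochs)[2]
  len <- dim(epochs$epochs)[3]
  fs <- epochs$fs
  # samples x (epoch*channel)
  flat <- matrix(aperm(epochs$epochs, c(3, 2, 1)), nrow = len)
  u <- 1
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (0:(len - 1)) / (len - 1)))
    flat <- flat * w
    u <- mean(w^2)
  }
  # pack pairs of real columns into one complex FFT and unpack by symmetry
  ncf <- ncol(flat)
  odd <- seq(1, ncf, by = 2)
  even <- odd[odd + 1 <= ncf] + 1
  z <- flat[, odd, drop = FALSE] +
    (0 + 1i) * cbind(flat[, even, drop = FALSE],
                     if (length(even) < length(odd)) matrix(0, len, 1))
  zf <- stats::mvfft(z)
  zrev <- Conj(zf[c(1, len:2), , drop = FALSE])
  pg <- matrix(0, len, ncf)
  pg[, odd] <- Mod((zf + zrev) / 2)^2
  pg[, even] <- Mod((zf[, seq_along(even), drop = FALSE] -
                     zrev[, seq_along(even), drop = FALSE]) / (0 + 2i))^2
  pg <- pg / (len * fs * u)
  half <- floor(len / 2)
  one <- pg[1:(half + 1), , drop = FALSE]
  dbl <- 2:(if (len %% 2 == 0) half else half + 1)
  one[dbl, ] <- 2 * one[dbl, ]
  # average over epochs: columns are channel-major within epoch
  pm <- array(one, dim = c(half + 1, nch, ne))
  psd <- t(apply(pm, c(1, 2), mean))  # channel x freq
  rownames(psd) <- epochs$labels
  structure(list(freqs = (0:half) * fs / len, psd = psd,
                 labels = epochs$labels, n_epochs = ne),
            class = "psd_spectrum")
}

#' Theta / alpha band summary of a PSD
#'
#' Mean PSD over the frequency bins inside the band (endpoints inclusive):
#' theta 4-7 Hz, alpha 8-13 Hz. Reports the per-channel values and the grand
#' mean over retained channels (unweighted).
#'
#' @param psd A [compute_psd()] result.
#' @param band `"theta"` or `"alpha"`, or a numeric length-2 range in Hz.
#' @return An object of class `band_psd`: list with `band`, `range`,
#'   `per_channel` (tibble: channel, value), `grand` (scalar, uV^2/Hz).
#' @export
band_power <- function(psd, band = c("theta", "alpha")) {
  stopifnot(inherits(psd, "psd_spectrum"))
  if (is.character(band)) {
    band <- match.arg(band)
    rng <- switch(band, theta = c(4, 7), alpha = c(8, 13))
    nm <- band
  } else {
    rng <- as.numeric(band)
    nm <- paste0(rng[1], "-", rng[2], "Hz")
  }
  if (rng[2] > max(psd$freqs)) stop("band extends beyond the Nyquist frequency")
  sel <- which(psd$freqs >= rng[1] & psd$freqs <= rng[2])
  if (length(sel) == 0) stop("no frequency bins inside the band")
  per <- rowMeans(psd$psd[, sel, drop = FALSE])
  structure(list(
    band = nm, range = rng,
    per_channel = tibble::tibble(channel = psd$labels, value = unname(per)),
    grand = mean(per)
  ), class = "band_psd")
}

#' @export
print.band_psd <- function(x, ...) {
  cat(sprintf("<band_psd %s [%g-%g Hz]: grand mean %.4g uV^2/Hz over %d channels>\n",
              x$band, x$range[1], x$range[2], x$grand, nrow(x$per_channel)))
  invisible(x)
}
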