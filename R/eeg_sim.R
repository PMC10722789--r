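#' Construct an EEG recording object
#'
#' @param data Channels-by-samples numeric matrix, microvolts.
#' @param fs Sampling rate, Hz.
#' @param labels Channel labels (length = `nrow(data)`).
#' @param montage Montage name (see [build_montage()]).
#' @param participant_id Optional identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels, montage = "desk32",
                          participant_id = NA_character_) {
  data <- as.matrix(data)
  stopifnot(fs > 0, nrow(data) == length(labels))
  mont <- build_montage(montage)
  miss <- setdiff(labels, mont$channels$label)
  if (length(miss)) stop("labels not in montage '", montage, "': ",
                         paste(utils::head(miss, 5), collapse = ", "))
  if (!all(mont$mastoids %in% labels)) {
    stop("mastoid channels (", paste(mont$mastoids, collapse = ", "),
         ") must be present in the recording")
  }
  rownames(data) <- labels
  structure(list(fs = fs, labels = labels, data = data, montage = montage,
                 participant_id = participant_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s: %d ch x %d samples @ %g Hz (%s)>\n",
              x$participant_id, nrow(x$data), ncol(x$data), x$fs, x$montage))
  invisible(x)
}

#' Simulate a multichannel EEG recording
#'
#' Synthesizes a child EEG matched to the session duration. Each channel is the
#' sum of:
#' * a `1/f^chi` background (`background_rms` microvolts RMS over the analysis
#'   band, exponent `background_exponent`);
#' * band-limited theta and alpha oscillations with Gaussian spectral bumps
#'   (centre/bandwidth from the config) whose RMS amplitude is
#'   `amp * exp(-coupling * trait)` times a per-subject log-normal variability
#'   multiplier (`subject_amp_sd`) -- lower latent trait means higher band
#'   power, which induces the negative behavior-PSD correlations;
#' * a 50 Hz sinusoidal line-noise component;
#' * blink transients (half-sine waves, `blink_width` s) with a frontal
#'   topography;
#' * occasional broadband motion bursts (Hann-windowed white noise,
#'   `motion_amp` microvolts) across all channels.
#'
#' Mastoid channels carry the background and oscillations attenuated by
#' `mastoid_gain`. Stochastic spectra are synthesized in the frequency domain
#' (Hermitian random spectrum, one inverse FFT per channel), so the expected
#' one-sided PSD of each component equals its target spectral shape exactly.
#'
#' @inheritParams simulate_dyad_session
#' @return An [eeg_recording()].
#' @export
simulate_eeg <- function(participant, config, seed) {
  validate_config(config)
  e <- config$eeg
  trait <- as.numeric(participant$trait)
  id <- as.character(participant$id)
  set.seed(derive_seed(seed, paste0("eeg-", id)))

  mont <- build_montage(e$montage)
  labels <- mont$channels$label
  nch <- length(labels)
  fs <- e$fs
  dur <- config$session$duration
  n <- round(fs * dur)
  half <- n %/% 2
  freqs <- (1:(half - 1)) * fs / n  # strictly positive, below Nyquist

  # one-sided PSD shape per channel (uV^2/Hz)
  chi <- e$background_exponent
  f2 <- fs / 2
  c_bg <- e$background_rms^2 * (if (chi == 1) 1 / log(f2 / 0.3) else
    (1 - chi) / (f2^(1 - chi) - 0.3^(1 - chi)))
  s_bg <- ifelse(freqs >= 0.3, c_bg / freqs^chi, c_bg / 0.3^chi)

  subj_mult <- exp(stats::rnorm(2, 0, e$subject_amp_sd))  # theta, alpha
  amp_th <- e$theta$amp * exp(-e$theta$coupling * trait) * subj_mult[1]
  amp_al <- e$alpha$amp * exp(-e$alpha$coupling * trait) * subj_mult[2]
  bump <- function(f0, bw) stats::dnorm(freqs, f0, bw / 2)
  s_th <- bump(e$theta$freq, e$theta$bw)
  s_al <- bump(e$alpha$freq, e$alpha$bw)

  gain <- ifelse(labels %in% mont$mastoids, e$mastoid_gain, 1)
  ch_jit <- exp(stats::rnorm(nch, 0, 0.10))  # mild per-channel amplitude jitter

  # Hermitian random spectrum: E[2|X_k|^2 / (n fs)] = S(f_k); two channels are
  # packed per inverse FFT (real/imaginary parts stay independent because the
  # packed spectrum is the sum of a Hermitian and an anti-Hermitian part)
  base <- s_bg + amp_th^2 * s_th + amp_al^2 * s_al      # per-frequency shape
  sd_mat <- sqrt(outer(base, gain * ch_jit) * n * fs / 4)  # (half-1) x nch
  nk <- half - 1
  re <- matrix(stats::rnorm(nk * nch), nk, nch) * sd_mat
  im <- matrix(stats::rnorm(nk * nch), nk, nch) * sd_mat
  x <- matrix(0, nch, n)
  for (ci in seq(1, nch, by = 2)) {
    ci2 <- min(ci + 1, nch)
    s1 <- complex(real = re[, ci], imaginary = im[, ci])
    s2 <- if (ci2 > ci) complex(real = re[, ci2], imaginary = im[, ci2]) else
      rep(0 + 0i, nk)
    z <- rep(0 + 0i, n)
    z[2:half] <- s1 + (0 + 1i) * s2
    z[n - (1:nk) + 1] <- Conj(s1) + (0 + 1i) * Conj(s2)
    zt <- stats::fft(z, inverse = TRUE) / n
    x[ci, ] <- Re(zt)
    if (ci2 > ci) x[ci2, ] <- Im(zt)
  }

  tt <- (0:(n - 1)) / fs
  # line noise: common phase, equal amplitude
  phi <- stats::runif(1, 0, 2 * pi)
  x <- x + matrix(e$line_amp * sin(2 * pi * e$line_freq * tt + phi),
                  nch, n, byrow = TRUE)

  # blinks: frontal topography
  n_blink <- stats::rpois(1, e$blink_rate * dur)
  if (n_blink > 0) {
    xy <- mont$channels
    w_blink <- exp(-((xy$x)^2 + (xy$y - 1)^2) / 0.35)
    w_blink[labels %in% mont$mastoids] <- 0
    times <- sort(stats::runif(n_blink, 0, dur - e$blink_width))
    amps <- e$blink_amp * exp(stats::rnorm(n_blink, 0, 0.2))
    for (k in seq_len(n_blink)) {
      i0 <- floor(times[k] * fs) + 1
      len <- max(2L, round(e$blink_width * fs))
      idx <- i0:min(n, i0 + len - 1)
      wave <- sin(pi * seq(0, 1, length.out = length(idx))) * amps[k]
      x[, idx] <- x[, idx] + outer(w_blink, wave)
    }
  }

  # motion bursts: broadband, all channels
  n_mot <- stats::rpois(1, e$motion_rate * dur)
  if (n_mot > 0) {
    times <- stats::runif(n_mot, 0, dur - e$motion_width)
    for (k in seq_len(n_mot)) {
      i0 <- floor(times[k] * fs) + 1
      len <- max(4L, round(e$motion_width * fs))
      idx <- i0:min(n, i0 + len - 1)
      win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = length(idx))))
      burst <- matrix(stats::rnorm(nch * length(idx), 0, e$motion_amp / 2),
                      nch, length(idx))
      x[, idx] <- x[, idx] + sweep(burst, 2, win, `*`)
    }
  }

  eeg_recording(x, fs = fs, labels = labels, montage = e$montage,
                participant_id = id)
}

#' Write / read an EEG recording as a delimited matrix plus JSON sidecar
#'
#' The matrix file is tab-separated, samples in rows and channels in columns
#' with a header of channel labels; the sidecar (`<path>.json`) carries `fs`,
#' `labels`, `montage` and `participant_id`.
#'
#' @param rec An [eeg_recording()].
#' @param path Matrix file path (the sidecar gets `.json` appended).
#' @return `write_eeg` returns `path` invisibly; `read_eeg` an
#'   [eeg_recording()].
#' @export
write_eeg <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- t(rec$data)
  colnames(m) <- rec$labels
  readr::write_tsv(tibble::as_tibble(m), path)
  jsonlite::write_json(
    list(fs = rec$fs, labels = rec$labels, montage = rec$montage,
         participant_id = rec$participant_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  m <- readr::read_tsv(path, show_col_types = FALSE)
  eeg_recording(t(as.matrix(m)[, meta$labels, drop = FALSE]),
                fs = meta$fs, labels = meta$labels, montage = meta$montage,
                participant_id = meta$participant_id %||% NA_character_)
}
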