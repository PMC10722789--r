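# fixtures built in code, shared across test files

# small session with a clean caregiver-initiated exchange
make_exchange_session <- function() {
  coded_session(
    data.frame(
      actor = c("caregiver", "child", "child", "caregiver"),
      code = c("bid", "respond", "engage", "engage"),
      onset = c(0, 1, 2, 2),
      offset = c(2, 2, 10, 10)
    ),
    duration = 15, session_id = "exchange"
  )
}

# a pure-sine recording on the desk montage (all channels identical)
make_sine_recording <- function(freq = 10, amp = 1, fs = 128, dur = 20,
                                montage = "desk32") {
  mont <- build_montage(montage)
  tt <- (0:(fs * dur - 1)) / fs
  wave <- amp * sin(2 * pi * freq * tt)
  data <- matrix(rep(wave, nrow(mont$channels)), nrow = nrow(mont$channels),
                 byrow = TRUE)
  eeg_recording(data, fs = fs, labels = mont$channels$label, montage = montage,
                participant_id = "sine")
}

# epoched_eeg built directly (bypassing preprocess) from a channels x samples matrix
make_epochs <- function(data, fs, labels, epoch_s = 1) {
  len <- round(fs * epoch_s)
  n_ep <- floor(ncol(data) / len)
  ep <- aperm(array(data[, seq_len(n_ep * len)],
                    dim = c(nrow(data), len, n_ep)), c(3, 1, 2))
  structure(list(fs = fs, labels = labels, epochs = ep,
                 rejected = tibble::tibble(epoch = integer(), reason = character()),
                 interpolated = character(0), montage = "desk32",
                 participant_id = "fixture"),
            class = "epoched_eeg")
}

# tiny config for fast behavioral tests
fast_config <- function(duration = 120) {
  cfg <- default_config()
  cfg$session$duration <- duration
  cfg
}
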