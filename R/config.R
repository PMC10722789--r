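#' Default generator configuration
#'
#' Returns the configuration of the synthetic cohort generator. The defaults are
#' the package's calibrated study conditions: a cohort of 23 ASD-with-DD, 17
#' ASD-without-DD and 45 TD preschool children, 180-s free-play sessions coded
#' at 1-s resolution, and a desk-scale EEG profile (32-channel montage, 128 Hz).
#' Behavioral and EEG parameters are calibrated (see [calibrate_generator()])
#' so that the simulated group means of the attainable indicator and band-power
#' targets match the published group parameters.
#'
#' The generative model ties everything to a latent social trait (TD mean 0,
#' SD 1; ASD group means negative):
#' * caregiver bids arrive as a Poisson process with rate
#'   `cg_rate * exp(-cg_rate_slope * trait)` (caregivers of lower-trait
#'   children initiate more);
#' * child bids with rate `ch_rate * exp(ch_rate_slope * trait)`;
#' * a bid is answered with probability `plogis(resp_intercept + resp_slope *
#'   trait)` after an Exponential(`latency_mean`) latency truncated at
#'   `timeout`; unanswered bids close after `timeout` seconds;
#' * answered bids open a mutual-engagement episode with Gamma-distributed
#'   duration, mean `engage_mean * exp(engage_mean_slope * trait)`;
#' * EEG theta/alpha oscillation RMS amplitude is
#'   `amp * exp(-coupling * trait)`, so lower trait implies higher band power,
#'   inducing the negative behavior-PSD correlations;
#' * clinical severity for ASD participants is an affine function of trait plus
#'   noise (`cars = cars_intercept - cars_slope * trait + eps`).
#'
#' @param profile `"desk"` (32 channels, 128 Hz; the default, sized so the full
#'   cohort simulates in seconds per replicate) or `"full"` (128-channel
#'   geodesic-style montage at 1000 Hz, mimicking a high-density lab recording).
#' @return A nested list of class `dyad_config`.
#' @examples
#' cfg <- default_config()
#' cfg$groups$TD$n
#' @export
default_config <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    groups = list(
      ASD_DD = list(
        n = 23, trait_mean = -1.627, trait_sd = 1, female_p = 4 / 23,
        age = c(mean = 4.87, sd = 0.863),
        viq = c(mean = 47.91, sd = 6.62), piq = c(mean = 55.13, sd = 9.16),
        fsiq = c(mean = 48.52, sd = 6.38)
      ),
      ASD_noDD = list(
        n = 17, trait_mean = -1.344, trait_sd = 1, female_p = 1 / 17,
        age = c(mean = 4.80, sd = 1.072),
        viq = c(mean = 67.12, sd = 20.00), piq = c(mean = 85.88, sd = 15.42),
        fsiq = c(mean = 82.22, sd = 18.76)
      ),
      TD = list(
        n = 45, trait_mean = 0, trait_sd = 1, female_p = 22 / 45,
        age = c(mean = 4.98, sd = 1.006),
        viq = c(mean = 77.65, sd = 16.17), piq = c(mean = 87.53, sd = 26.30),
        fsiq = c(mean = 91.30, sd = 15.16)
      )
    ),
    session = list(duration = 180, frame = 1),
    behavior = list(
      cg_rate = 0.080, cg_rate_slope = 0.30,
      ch_rate = 0.139, ch_rate_slope = 0.50,
      resp_intercept = 1.172, resp_slope = 0.42,
      latency_mean = 1, timeout = 3,
      engage_shape = 2, engage_mean = 10.06, engage_mean_slope = 0.35
    ),
    eeg = list(
      montage = if (profile == "desk") "desk32" else "egi128",
      fs = if (profile == "desk") 128 else 1000,
      background_rms = 5, background_exponent = 1,
      theta = list(freq = 5.5, bw = 1.5, amp = 1.88, coupling = 0.21),
      alpha = list(freq = 10, bw = 2.0, amp = 1.52, coupling = 0.24),
      subject_amp_sd = 0.34,
      line_freq = 50, line_amp = 5,
      blink_rate = 0.20, blink_amp = 120, blink_width = 0.3,
      motion_rate = 0.02, motion_amp = 300, motion_width = 1,
      mastoid_gain = 0.3
    ),
    severity = list(
      cars_intercept = 30, cars_slope = 3.1, cars_sd = 5,
      css_intercept = 7, css_slope = 0.3, css_sd = 1.5
    ),
    analysis = list(
      response_window = 3, gap_close = 2,
      iq_range = c(20, 160), age_range = c(3, 5)
    )
  )
  structure(cfg, class = "dyad_config")
}

#' Validate a generator configuration
#'
#' Checks the structural invariants of a [default_config()]-shaped list: group
#' sizes non-negative, rates non-negative, positive session duration, response
#' probability parameters finite, EEG sampling rate positive, known montage.
#'
#' @param config A `dyad_config` list.
#' @return `config`, invisibly, or an error describing the first violation.
#' @export
validate_config <- function(config) {
  need <- c("groups", "session", "behavior", "eeg", "severity", "analysis")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("configuration error: missing sections ", paste(miss, collapse = ", "))
  for (g in names(config$groups)) {
    grp <- config$groups[[g]]
    if (is.null(grp$n) || grp$n < 0 || grp$n != round(grp$n)) {
      stop("configuration error: group ", g, " has invalid size")
    }
    if (!is.null(grp$female_p) && (grp$female_p < 0 || grp$female_p > 1)) {
      stop("configuration error: group ", g, " female_p outside [0,1]")
    }
  }
  if (config$session$duration <= 0) stop("configuration error: session duration must be > 0")
  b <- config$behavior
  if (any(c(b$cg_rate, b$ch_rate, b$latency_mean, b$timeout, b$engage_shape, b$engage_mean) < 0)) {
    stop("configuration error: behavioral rates and durations must be >= 0")
  }
  if (config$eeg$fs <= 0) stop("configuration error: eeg fs must be > 0")
  known <- c("desk32", "egi128")
  if (!config$eeg$montage %in% known) {
    stop("unknown montage '", config$eeg$montage, "'; available: ", paste(known, collapse = ", "))
  }
  invisible(config)
}

#' Read / write a configuration as YAML
#'
#' @param path File path.
#' @param config A `dyad_config` list.
#' @return `read_config` returns the validated `dyad_config`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_config())
  cfg <- utils::modifyList(base, cfg)
  class(cfg) <- "dyad_config"
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.dyad_config <- function(x, ...) {
  ns <- vapply(x$groups, function(g) g$n, numeric(1))
  cat(sprintf(
    "<dyad_config profile=%s: %s; %ds sessions; EEG %s @ %g Hz>\n",
    x$profile, paste(names(ns), ns, sep = "=", collapse = " "),
    x$session$duration, x$eeg$montage, x$eeg$fs
  ))
  invisible(x)
}
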