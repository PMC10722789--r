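#' Simulate a coded caregiver-child play session
#'
#' Draws one session from the semi-Markov interaction model. While the dyad is
#' idle, caregiver and child bids compete as Poisson processes with rates
#' `cg_rate * exp(-cg_rate_slope * trait)` and `ch_rate * exp(ch_rate_slope *
#' trait)`. A bid is answered with probability `plogis(resp_intercept +
#' resp_slope * trait)`; the answer arrives after an Exponential latency
#' (mean `latency_mean`) truncated at `timeout`, as a 1-s `respond` event
#' followed by a mutual `engage` episode of Gamma(`engage_shape`) duration with
#' mean `engage_mean * exp(engage_mean_slope * trait)`. The initiator stays in
#' `bid` until engagement starts. Unanswered bids close after `timeout`
#' seconds. Events are truncated at the session boundary, so the stream is a
#' valid [coded_session()] by construction.
#'
#' This process is a test harness with matched first moments and correlation
#' signs, not a claim about the true behavioral mechanism.
#'
#' @param participant One roster row (a list or one-row data frame with at
#'   least `id` and `trait`).
#' @param config A [default_config()] list.
#' @param seed Integer seed; deterministic given `(participant, config, seed)`.
#' @return A [coded_session()] whose `participant_id` is `participant$id`.
#' @examples
#' cfg <- default_config()
#' p <- list(id = "TD-01", trait = 0)
#' s <- simulate_dyad_session(p, cfg, seed = 1)
#' @export
simulate_dyad_session <- function(participant, config, seed) {
  validate_config(config)
  b <- config$behavior
  trait <- as.numeric(participant$trait)
  id <- as.character(participant$id)
  dur <- config$session$duration
  set.seed(derive_seed(seed, paste0("session-", id)))

  lam_cg <- b$cg_rate * exp(-b$cg_rate_slope * trait)
  lam_ch <- b$ch_rate * exp(b$ch_rate_slope * trait)
  p_resp <- stats::plogis(b$resp_intercept + b$resp_slope * trait)
  eng_mean <- b$engage_mean * exp(b$engage_mean_slope * trait)

  e_actor <- character(0)
  e_code <- character(0)
  e_on <- numeric(0)
  e_off <- numeric(0)
  add <- function(actor, code, onset, offset) {
    onset <- max(0, onset)
    offset <- min(dur, offset)
    if (offset > onset) {
      e_actor[[length(e_actor) + 1L]] <<- actor
      e_code[[length(e_code) + 1L]] <<- code
      e_on[[length(e_on) + 1L]] <<- onset
      e_off[[length(e_off) + 1L]] <<- offset
    }
  }

  t <- 0
  lam_tot <- lam_cg + lam_ch
  while (lam_tot > 0 && t < dur) {
    t_b <- t + stats::rexp(1, lam_tot)
    if (t_b >= dur) break
    initiator <- if (stats::runif(1) < lam_cg / lam_tot) "caregiver" else "child"
    responder <- setdiff(DYAD_ACTORS, initiator)
    if (stats::runif(1) < p_resp) {
      # truncated-exponential latency via inverse CDF
      u <- stats::runif(1, 0, stats::pexp(b$timeout, 1 / b$latency_mean))
      lat <- stats::qexp(u, 1 / b$latency_mean)
      g <- stats::rgamma(1, shape = b$engage_shape,
                         scale = eng_mean / b$engage_shape)
      t_r <- t_b + lat
      add(initiator, "bid", t_b, t_r + 1)
      add(responder, "respond", t_r, t_r + 1)
      add("child", "engage", t_r + 1, t_r + 1 + g)
      add("caregiver", "engage", t_r + 1, t_r + 1 + g)
      t <- t_r + 1 + g
    } else {
      add(initiator, "bid", t_b, t_b + b$timeout)
      t <- t_b + b$timeout
    }
  }
  ev <- tibble::tibble(actor = e_actor, code = e_code,
                       onset = e_on, offset = e_off)
  # construction guarantees validity (events clipped to [0, dur], no same-actor
  # same-code overlap); validation stays available via validate_session()
  coded_session(ev, duration = dur, session_id = id, participant_id = id,
                validate = FALSE)
}
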