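#' Segment a frame stream into attributed interaction episodes
#'
#' An interaction episode opens at the first `bid` frame of either actor (on a
#' simultaneous bid the caregiver is taken as initiator). The episode is
#' *answered* when the other actor shows `respond` or `engage` within
#' `response_window` seconds of the opening frame. An answered episode stays
#' open while interaction continues and closes after `gap_close` consecutive
#' frames in which neither actor is in `respond`/`engage` (counted from the
#' first answer frame onward); its end is the first frame of that closing run.
#' An unanswered episode ends when the initiator's opening bid run ends or the
#' response window expires, whichever is first. A bid by the other actor during
#' an open episode does not open a new episode (it is a re-initiating bid,
#' attributed to both initiators by [compute_indicators()]); frames inside the
#' closing run belong to no episode, and the next episode can open at any bid
#' frame after the run.
#'
#' @param frames A `frame_stream` from [rasterize()].
#' @param response_window Seconds the other actor has to answer (default 3).
#' @param gap_close Consecutive inactive seconds that close an answered
#'   episode (default 2).
#' @return A tibble with one row per episode: `start`, `end` (seconds,
#'   half-open), `start_frame`, `end_frame` (0-based frame indices, end
#'   exclusive), `initiator`, `answered`.
#' @export
segment_episodes <- function(frames, response_window = 3, gap_close = 2) {
  stopifnot(inherits(frames, "frame_stream"))
  frame_s <- attr(frames, "frame_s") %||% 1
  w <- max(1L, round(response_window / frame_s))
  g <- max(1L, round(gap_close / frame_s))
  ch <- frames$child
  cg <- frames$caregiver
  n <- length(ch)
  resp_like <- function(s) s %in% c("respond", "engage")
  act_ch <- resp_like(ch)
  act_cg <- resp_like(cg)
  active <- act_ch | act_cg

  eps <- list()
  i <- 1L
  while (i <= n) {
    if (cg[i] == "bid" || ch[i] == "bid") {
      initiator <- if (cg[i] == "bid") "caregiver" else "child"
      other_act <- if (initiator == "caregiver") act_ch else act_cg
      init_bid <- if (initiator == "caregiver") cg == "bid" else ch == "bid"
      win <- i:min(n, i + w)
      a_rel <- which(other_act[win])
      if (length(a_rel) == 0) {
        # unanswered: closes when the opening bid run ends or the window expires
        run <- 0L
        while (i + run <= n && init_bid[i + run]) run <- run + 1L
        last <- i + min(run, w) - 1L   # 1-based last frame of the episode
        eps[[length(eps) + 1L]] <- c(start = i, last = last,
                                     initiator = initiator, answered = FALSE)
        i <- last + 1L
      } else {
        a_f <- win[a_rel[1]]
        # scan for the first run of g consecutive inactive frames at/after the answer
        j <- a_f
        gap <- 0L
        while (j <= n && gap < g) {
          gap <- if (active[j]) 0L else gap + 1L
          j <- j + 1L
        }
        if (gap >= g) {
          last <- j - g - 1L   # frame before the closing run
          resume <- j          # first frame after the completed closing run
        } else {
          last <- n
          resume <- n + 1L
        }
        eps[[length(eps) + 1L]] <- c(start = i, last = last,
                                     initiator = initiator, answered = TRUE)
        i <- resume
      }
    } else {
      i <- i + 1L
    }
  }
  if (length(eps) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          start_frame = integer(), end_frame = integer(),
                          initiator = character(), answered = logical()))
  }
  m <- do.call(rbind, eps)
  start_frame <- as.integer(m[, "start"]) - 1L
  end_frame <- as.integer(m[, "last"])   # 0-based exclusive end == 1-based last frame
  tibble::tibble(
    start = start_frame * frame_s,
    end = end_frame * frame_s,
    start_frame = start_frame,
    end_frame = end_frame,
    initiator = as.character(m[, "initiator"]),
    answered = as.logical(m[, "answered"])
  )
}

#' Compute the five behavioral indicators
#'
#' Given a rasterized session and its episode list, computes:
#' \describe{
#'   \item{SIC}{Social Involvement of Children: proportion of frames in which
#'     the child is in `bid`, `respond`, or `engage`.}
#'   \item{IT}{Interaction Time: proportion of frames with both actors
#'     simultaneously in `respond`/`engage`.}
#'   \item{RSC}{Response of Children to Social Cues: answered caregiver-initiated
#'     episodes / all caregiver-initiated episodes; undefined (`NA`, flagged)
#'     when the caregiver initiated none — a zero here would fabricate a
#'     deficit.}
#'   \item{GIS}{proportion of frames inside caregiver-initiated episodes,
#'     including unanswered bid frames.}
#'   \item{CIS}{the child-initiated analogue of GIS.}
#' }
#' Frames covered by a re-initiating bid (the non-initiating actor bidding
#' inside an open episode) count toward both GIS and CIS; this double
#' attribution is why group-level GIS + CIS can slightly exceed 1.
#'
#' @param frames A `frame_stream` from [rasterize()].
#' @param episodes Episode tibble from [segment_episodes()] on the same stream.
#' @return One-row tibble: `sic`, `it`, `rsc`, `gis`, `cis`, `rsc_defined`,
#'   `n_frames`.
#' @export
compute_indicators <- function(frames, episodes) {
  stopifnot(inherits(frames, "frame_stream"))
  n <- nrow(frames)
  if (n == 0) stop("empty frame stream")
  if (nrow(episodes) > 0 && max(episodes$end_frame) > n) {
    stop("episodes reference frames outside the stream")
  }
  ch <- frames$child
  cg <- frames$caregiver
  resp_like <- function(s) s %in% c("respond", "engage")
  sic <- mean(ch %in% ACTIVE_STATES)
  it <- mean(resp_like(ch) & resp_like(cg))
  cg_eps <- episodes[episodes$initiator == "caregiver", ]
  rsc <- if (nrow(cg_eps) > 0) mean(cg_eps$answered) else NA_real_
  in_cg <- rep(FALSE, n)
  in_ch <- rep(FALSE, n)
  if (nrow(episodes) > 0) {
    for (k in seq_len(nrow(episodes))) {
      idx <- (episodes$start_frame[k] + 1L):episodes$end_frame[k]
      if (episodes$initiator[k] == "caregiver") {
        in_cg[idx] <- TRUE
        in_ch[idx] <- in_ch[idx] | (ch[idx] == "bid")   # re-initiating child bid
      } else {
        in_ch[idx] <- TRUE
        in_cg[idx] <- in_cg[idx] | (cg[idx] == "bid")   # re-initiating caregiver bid
      }
    }
  }
  tibble::tibble(
    sic = sic, it = it, rsc = rsc,
    gis = mean(in_cg), cis = mean(in_ch),
    rsc_defined = nrow(cg_eps) > 0, n_frames = n
  )
}

#' Square-root transform of proportion-scale values
#'
#' The analysis scale of the pipeline: indicator proportions and band PSD
#' values are square-root transformed before model fitting to meet normality
#' assumptions. `NA` (undefined) inputs propagate as `NA`.
#'
#' @param values Numeric vector, all non-negative (or `NA`).
#' @return `sqrt(values)`.
#' @export
sqrt_transform <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stop("sqrt_transform: negative input")
  sqrt(values)
}

#' Score a set of coded sessions
#'
#' Convenience wrapper chaining [rasterize()], [segment_episodes()] and
#' [compute_indicators()] over a list of sessions.
#'
#' @param sessions A list of [coded_session()] objects (or a single one).
#' @param response_window,gap_close Passed to [segment_episodes()].
#' @param frame Frame length in seconds.
#' @return A tibble with one row per session: `session_id`, `participant_id`,
#'   the five indicators, `rsc_defined`, `n_frames`.
#' @export
score_sessions <- function(sessions, response_window = 3, gap_close = 2, frame = 1) {
  if (inherits(sessions, "coded_session")) sessions <- list(sessions)
  purrr::map_dfr(sessions, function(s) {
    fr <- rasterize(s, frame = frame)
    ep <- segment_episodes(fr, response_window, gap_close)
    dplyr::bind_cols(
      tibble::tibble(session_id = s$session_id, participant_id = s$participant_id),
      compute_indicators(fr, ep)
    )
  })
}
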