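# behavioral vocabulary of the coding scheme
DYAD_ACTORS <- c("child", "caregiver")
DYAD_CODES <- c("bid", "respond", "engage", "no_response", "unengaged")
# codes that count as an active state when rasterized; others map to idle
ACTIVE_STATES <- c("bid", "respond", "engage")

#' Construct a coded dyadic play session
#'
#' A coded session is the second-resolution annotation of one caregiver-child
#' free-play session: a set of timed events, each an interval `[onset, offset)`
#' in 0-based seconds attributed to one actor with one behavioral code from the
#' vocabulary `bid`, `respond`, `engage`, `no_response`, `unengaged`.
#'
#' @param events A data frame with columns `actor`, `code`, `onset`, `offset`.
#' @param duration Session duration in seconds.
#' @param session_id,participant_id Identifier strings.
#' @param validate If `TRUE` (default) fail on any invariant violation.
#' @return An object of class `coded_session`.
#' @export
coded_session <- function(events, duration, session_id = "s1",
                          participant_id = session_id, validate = TRUE) {
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0) {
    events <- tibble::tibble(actor = character(), code = character(),
                             onset = numeric(), offset = numeric())
  }
  events <- dplyr::arrange(events, .data$onset, .data$actor, .data$code)
  x <- structure(
    list(session_id = session_id, participant_id = participant_id,
         duration = as.numeric(duration), events = events),
    class = "coded_session"
  )
  if (validate) {
    v <- validate_session(x)
    if (nrow(v) > 0) {
      stop("invalid session '", session_id, "': ",
           paste(sprintf("event %s: %s", v$event, v$rule), collapse = "; "))
    }
  }
  x
}

#' @export
print.coded_session <- function(x, ...) {
  cat(sprintf("<coded_session %s: %gs, %d events>\n",
              x$session_id, x$duration, nrow(x$events)))
  invisible(x)
}

#' Validate a coded session
#'
#' Checks every session invariant and returns violations as data, not errors:
#' intervals well-formed (`onset < offset`), within `[0, duration]`, codes and
#' actors in vocabulary, and no overlap between two events of the same actor
#' with the same code.
#'
#' @param session A [coded_session()].
#' @return A tibble with columns `event` (row index into `session$events`, NA
#'   for session-level rules), `rule`, `detail`; zero rows iff the session is
#'   valid.
#' @export
validate_session <- function(session) {
  ev <- session$events
  out <- list()
  bad <- function(i, rule, detail = "") {
    tibble::tibble(event = as.integer(i), rule = rule, detail = detail)
  }
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      if (!e$actor %in% DYAD_ACTORS) {
        out <- c(out, list(bad(i, "unknown actor", e$actor)))
      }
      if (!e$code %in% DYAD_CODES) {
        out <- c(out, list(bad(i, "unknown code", e$code)))
      }
      if (!is.finite(e$onset) || !is.finite(e$offset) || e$offset <= e$onset) {
        out <- c(out, list(bad(i, "inverted or empty interval",
                               sprintf("[%g, %g)", e$onset, e$offset))))
      } else {
        if (e$onset < 0 || e$offset > session$duration) {
          out <- c(out, list(bad(i, "out of bounds",
                                 sprintf("[%g, %g) vs duration %g",
                                         e$onset, e$offset, session$duration))))
        }
      }
    }
    # same-actor same-code overlap, O(n log n) per stratum
    strata <- dplyr::group_split(dplyr::mutate(ev, .row = dplyr::row_number()),
                                 .data$actor, .data$code)
    for (s in strata) {
      if (nrow(s) < 2) next
      s <- dplyr::arrange(s, .data$onset)
      ov <- which(s$onset[-1] < s$offset[-nrow(s)])
      for (k in ov) {
        out <- c(out, list(bad(s$.row[k + 1], "same-actor overlap",
                               sprintf("%s/%s events %d and %d",
                                       s$actor[1], s$code[1], s$.row[k], s$.row[k + 1]))))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(event = integer(), rule = character(), detail = character()))
  }
  dplyr::bind_rows(out)
}

#' Read behavioral annotations
#'
#' Reads a coded session from the package CSV dialect (UTF-8, header
#' `session_id,actor,onset_s,offset_s,code`, `.` decimal separator) or from an
#' ELAN EAF (XML) file. EAF support is read-only and requires a `tier_map`
#' giving the tier-name-to-actor correspondence, because ELAN tier naming is
#' site-specific.
#'
#' @param path File path.
#' @param format `"csv"` or `"eaf"`.
#' @param duration Session duration in seconds; default: the largest offset,
#'   rounded up to a whole second.
#' @param participant_id Participant identifier; defaults to the session id.
#' @param tier_map Named character vector mapping EAF tier ids to
#'   `"child"`/`"caregiver"` (EAF only).
#' @return A validated [coded_session()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("session_id,actor,onset_s,offset_s,code",
#'              "s1,child,2.0,5.0,engage"), f)
#' read_annotations(f)
#' @export
read_annotations <- function(path, format = c("csv", "eaf"), duration = NULL,
                             participant_id = NULL, tier_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    raw <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             session_id = "c", actor = "c", code = "c",
                             onset_s = "d", offset_s = "d"))
    probs <- readr::problems(raw)
    if (nrow(probs) > 0) {
      stop("malformed CSV at line ", probs$row[1], ": ", probs$expected[1])
    }
    need <- c("session_id", "actor", "onset_s", "offset_s", "code")
    miss <- setdiff(need, names(raw))
    if (length(miss)) stop("CSV missing columns: ", paste(miss, collapse = ", "))
    bad <- which(!raw$code %in% DYAD_CODES)
    if (length(bad)) {
      stop("unknown code '", raw$code[bad[1]], "' at data row ", bad[1])
    }
    sid <- unique(raw$session_id)
    if (length(sid) > 1) stop("file contains multiple sessions: ", paste(sid, collapse = ", "))
    if (length(sid) == 0) sid <- "empty"
    ev <- tibble::tibble(actor = raw$actor, code = raw$code,
                         onset = raw$onset_s, offset = raw$offset_s)
  } else {
    doc <- tryCatch(xml2::read_xml(path), error = function(e) {
      stop("malformed EAF XML: ", conditionMessage(e))
    })
    if (is.null(tier_map)) stop("EAF input requires a tier_map (tier id -> actor)")
    slots <- xml2::xml_find_all(doc, ".//TIME_ORDER/TIME_SLOT")
    tvals <- stats::setNames(
      as.numeric(xml2::xml_attr(slots, "TIME_VALUE")) / 1000,
      xml2::xml_attr(slots, "TIME_SLOT_ID"))
    rows <- list()
    for (tier in xml2::xml_find_all(doc, ".//TIER")) {
      tid <- xml2::xml_attr(tier, "TIER_ID")
      if (!tid %in% names(tier_map)) next
      actor <- unname(tier_map[[tid]])
      anns <- xml2::xml_find_all(tier, ".//ALIGNABLE_ANNOTATION")
      if (length(anns) == 0) next
      rows <- c(rows, list(tibble::tibble(
        actor = actor,
        code = tolower(xml2::xml_text(xml2::xml_find_first(anns, ".//ANNOTATION_VALUE"))),
        onset = unname(tvals[xml2::xml_attr(anns, "TIME_SLOT_REF1")]),
        offset = unname(tvals[xml2::xml_attr(anns, "TIME_SLOT_REF2")])
      )))
    }
    ev <- dplyr::bind_rows(rows)
    if (nrow(ev) == 0) stop("no annotations found for the mapped tiers")
    bad <- which(!ev$code %in% DYAD_CODES)
    if (length(bad)) stop("unknown code '", ev$code[bad[1]], "' in EAF annotation ", bad[1])
    sid <- tools::file_path_sans_ext(basename(path))
  }
  if (is.null(duration)) duration <- if (nrow(ev)) ceiling(max(ev$offset)) else 0
  coded_session(ev, duration = duration, session_id = sid,
                participant_id = participant_id %||% sid)
}

#' Write behavioral annotations (CSV dialect)
#'
#' Lossless for the CSV dialect: a round-trip through
#' [write_annotations()] / [read_annotations()] reproduces the session.
#'
#' @param session A [coded_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(session, path) {
  v <- validate_session(session)
  if (nrow(v) > 0) stop("refusing to write invalid session (", v$rule[1], ")")
  out <- tibble::tibble(
    session_id = session$session_id,
    actor = session$events$actor,
    onset_s = session$events$onset,
    offset_s = session$events$offset,
    code = session$events$code
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Rasterize a coded session to 1-s frames
#'
#' Converts the event stream into per-frame states for both actors, stepping
#' through the session in `frame`-second steps. A frame takes an actor's state
#' when an event of that actor covers at least 50% of the frame (ties at
#' exactly 50% count); when several codes qualify for the same frame the
#' precedence is `engage > respond > bid > idle`. The passive codes
#' `no_response` and `unengaged` rasterize to `idle`.
#'
#' @param session A [coded_session()].
#' @param frame Frame length in seconds (default 1).
#' @return A `frame_stream`: a tibble with columns `frame` (0-based index),
#'   `child`, `caregiver` (states), with attributes `frame_s` and `duration`.
#' @examples
#' s <- coded_session(
#'   data.frame(actor = "child", code = "engage", onset = 0, offset = 10),
#'   duration = 10)
#' rasterize(s)
#' @export
rasterize <- function(session, frame = 1) {
  stopifnot(inherits(session, "coded_session"), frame > 0)
  n <- ceiling(session$duration / frame)
  states <- list(child = rep("idle", n), caregiver = rep("idle", n))
  if (n > 0 && nrow(session$events) > 0) {
    prec <- c(bid = 1, respond = 2, engage = 3)
    rank <- list(child = rep(0L, n), caregiver = rep(0L, n))
    for (actor in DYAD_ACTORS) {
      for (code in ACTIVE_STATES) {
        sel <- session$events$actor == actor & session$events$code == code
        if (!any(sel)) next
        cv <- numeric(n)
        ons <- session$events$onset[sel]
        offs <- session$events$offset[sel]
        for (k in seq_along(ons)) {
          i0 <- max(0L, floor(ons[k] / frame))
          i1 <- min(n - 1L, ceiling(offs[k] / frame) - 1L)
          if (i1 < i0) next
          idx <- i0:i1
          cv[idx + 1L] <- cv[idx + 1L] +
            pmin(offs[k], (idx + 1) * frame) - pmax(ons[k], idx * frame)
        }
        hit <- cv >= frame / 2
        take <- hit & prec[[code]] > rank[[actor]]
        states[[actor]][take] <- code
        rank[[actor]][take] <- prec[[code]]
      }
    }
  }
  out <- tibble::tibble(frame = seq_len(n) - 1L,
                        child = states$child, caregiver = states$caregiver)
  attr(out, "frame_s") <- frame
  attr(out, "duration") <- session$duration
  class(out) <- c("frame_stream", class(out))
  out
}
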