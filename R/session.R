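#' Participant characteristics
#'
#' Age, gender code, and four trait total scores. Gender uses the study's
#' coding 0 = male, 1 = female, 2 = non-binary. Traits are raw questionnaire
#' totals: social anxiety (12-60), depression (0-60), cognitive empathy
#' (19-95), affective empathy (12-60).
#'
#' @param age Age in years.
#' @param gender_code Integer in {0, 1, 2}.
#' @param social_anxiety,depression,cognitive_empathy,affective_empathy
#'   Raw trait scores.
#' @return A `participant_info` list.
#' @export
participant_info <- function(age, gender_code, social_anxiety, depression,
                             cognitive_empathy, affective_empathy) {
  if (!gender_code %in% c(0L, 1L, 2L)) {
    stop("`gender_code` must be 0 (male), 1 (female) or 2 (non-binary).",
         call. = FALSE)
  }
  structure(list(age = as.numeric(age), gender_code = as.integer(gender_code),
                 social_anxiety = as.numeric(social_anxiety),
                 depression = as.numeric(depression),
                 cognitive_empathy = as.numeric(cognitive_empathy),
                 affective_empathy = as.numeric(affective_empathy)),
            class = "participant_info")
}

CHANNELS <- c("ecg", "skin_conductance", "respiration", "skin_temperature")

#' Dyadic recording session
#'
#' Bundles both participants' four-channel recordings, the interval layout,
#' per-interval self-reported engagement (0-100) from both participants,
#' participant characteristics, and optional external-coder ratings.
#'
#' @param dyad_id Character or integer identifier.
#' @param signals List of two lists (participant 1, participant 2), each with
#'   the four named [channel_signal()]s `ecg`, `skin_conductance`,
#'   `respiration`, `skin_temperature`.
#' @param intervals An [interval_set()].
#' @param self_reports List of two numeric vectors (one per participant), one
#'   engagement value in \[0, 100\] per conversation interval.
#' @param info List of two [participant_info()] objects.
#' @param coder_ratings Optional numeric vector of per-interval external-coder
#'   engagement ratings in \[0, 100\], or `NULL`.
#' @return A `dyad_session` object.
#' @export
dyad_session <- function(dyad_id, signals, intervals, self_reports, info,
                         coder_ratings = NULL) {
  stopifnot(inherits(intervals, "interval_set"))
  if (length(signals) != 2L || length(self_reports) != 2L || length(info) != 2L) {
    stop("A dyad session needs exactly two participants.", call. = FALSE)
  }
  n_conv <- n_conversation(intervals)
  for (p in 1:2) {
    missing_ch <- setdiff(CHANNELS, names(signals[[p]]))
    if (length(missing_ch)) {
      stop("Participant ", p, " is missing channel(s): ",
           paste(missing_ch, collapse = ", "), call. = FALSE)
    }
    for (ch in CHANNELS) {
      if (!inherits(signals[[p]][[ch]], "channel_signal")) {
        stop("signals[[", p, "]]$", ch, " is not a channel_signal.", call. = FALSE)
      }
    }
    reps <- self_reports[[p]]
    if (length(reps) != n_conv) {
      stop("Participant ", p, " has ", length(reps), " self-reports but ",
           n_conv, " conversation intervals.", call. = FALSE)
    }
    if (any(reps < 0 | reps > 100)) {
      stop("Self-reports must lie in [0, 100]; participant ", p,
           " has value ", reps[which(reps < 0 | reps > 100)[1]], ".",
           call. = FALSE)
    }
    if (!inherits(info[[p]], "participant_info")) {
      stop("info[[", p, "]] is not a participant_info.", call. = FALSE)
    }
  }
  if (!is.null(coder_ratings)) {
    if (length(coder_ratings) != n_conv || any(coder_ratings < 0 | coder_ratings > 100)) {
      stop("coder_ratings must give one value in [0, 100] per conversation interval.",
           call. = FALSE)
    }
    coder_ratings <- as.numeric(coder_ratings)
  }
  structure(list(dyad_id = as.character(dyad_id), signals = signals,
                 intervals = intervals,
                 self_reports = lapply(self_reports, as.numeric),
                 info = info, coder_ratings = coder_ratings),
            class = "dyad_session")
}

#' @export
print.dyad_session <- function(x, ...) {
  cat(sprintf("<dyad_session> %s: 2 x %d channels, %d conversation intervals%s\n",
              x$dyad_id, length(CHANNELS), n_conversation(x$intervals),
              if (is.null(x$coder_ratings)) "" else ", coder ratings present"))
  invisible(x)
}

#' Per-interval dyad engagement
#'
#' The reference engagement of a conversation interval is the arithmetic mean
#' of the two participants' self-reports for that interval. Note the known
#' ambiguity of averaging: reports (0, 100) and (50, 50) both give 50.
#'
#' @param session A [dyad_session()].
#' @return Numeric vector, one value in \[0, 100\] per conversation interval.
#' @export
dyad_engagement <- function(session) {
  stopifnot(inherits(session, "dyad_session"))
  (session$self_reports[[1]] + session$self_reports[[2]]) / 2
}

#' Screen out dyads whose raters generally disagree
#'
#' A dyad's disagreement statistic is the median over conversation intervals
#' of the absolute difference between the two participants' engagement
#' reports. Dyads whose statistic exceeds `max_median_abs_diff` are excluded;
#' the reference (mean) engagement of such dyads is considered unreliable.
#' The default threshold of 30 engagement points is deliberately far above
#' ordinary disagreement so that typical rating noise survives screening.
#'
#' @param sessions List of [dyad_session()] objects.
#' @param max_median_abs_diff Exclusion threshold on the 0-100 scale.
#' @return List with elements `kept` and `excluded` (lists of sessions) and
#'   `stats`, a tibble with `dyad_id`, `median_abs_diff`, `excluded`.
#' @export
screen_dyads <- function(sessions, max_median_abs_diff = 30) {
  stopifnot(length(sessions) >= 1L)
  stats <- purrr::map_dfr(sessions, function(s) {
    tibble::tibble(
      dyad_id = s$dyad_id,
      median_abs_diff = stats::median(abs(s$self_reports[[1]] - s$self_reports[[2]]))
    )
  })
  stats$excluded <- stats$median_abs_diff > max_median_abs_diff
  list(kept = sessions[!stats$excluded],
       excluded = sessions[stats$excluded],
       stats = stats)
}

#' Validate a session's invariants
#'
#' Re-checks the `dyad_session` invariants (channel sets, report counts and
#' bounds, interval layout) and returns a small report tibble; useful after
#' hand-editing manifests.
#'
#' @param session A [dyad_session()].
#' @return A tibble with columns `check` and `ok`.
#' @export
validate_session <- function(session) {
  checks <- list(
    both_participants_full_channel_set =
      all(purrr::map_lgl(session$signals, ~ setequal(names(.x), CHANNELS))),
    reports_match_interval_count =
      all(lengths(session$self_reports) == n_conversation(session$intervals)),
    reports_in_bounds =
      all(unlist(session$self_reports) >= 0 & unlist(session$self_reports) <= 100),
    spans_within_signals =
      all(purrr::map_lgl(session$signals, function(pp) {
        all(purrr::map_lgl(pp, ~ max(session$intervals$end_s) <= duration(.x) + 1e-9))
      })),
    equal_fs_across_participants_per_channel =
      all(purrr::map_lgl(CHANNELS, function(ch) {
        session$signals[[1]][[ch]]$fs == session$signals[[2]][[ch]]$fs
      }))
  )
  tibble::tibble(check = names(checks), ok = unlist(checks, use.names = FALSE))
}
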