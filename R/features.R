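#' Feature names used by the estimation stage
#'
#' @return Character vectors: `individual_feature_names()` gives the 24
#'   per-interval individual columns (12 per participant),
#'   `synchrony_feature_names()` the 17 synchrony columns, and
#'   `characteristic_names()` the 12 participant-characteristic columns.
#' @export
individual_feature_names <- function() {
  as.vector(t(outer(INDIVIDUAL_FEATURES, c("_p1", "_p2"), paste0)))
}

#' @rdname individual_feature_names
#' @export
synchrony_feature_names <- function() SYNCHRONY_FEATURES

#' @rdname individual_feature_names
#' @export
characteristic_names <- function() {
  as.vector(t(outer(c("age", "gender_code", "social_anxiety", "depression",
                      "cognitive_empathy", "affective_empathy"),
                    c("_p1", "_p2"), paste0)))
}

# resample one channel span onto a uniform fs_out grid by linear interpolation
resample_span <- function(sig, start_s, end_s, fs_out) {
  seg <- cut_span(sig, start_s, end_s)
  t_in <- start_s + (seq_along(seg$samples) - 1) / seg$fs
  t_out <- seq(start_s, end_s - 1 / fs_out, by = 1 / fs_out)
  stats::approx(t_in, seg$samples, xout = t_out, rule = 2)$y
}

# the four synchrony substrates for one participant over one span, at fs_out
substrates_for_span <- function(session, prep, p, start_s, end_s) {
  fs_out <- prep$fs_out
  t_out <- seq(start_s, end_s - 1 / fs_out, by = 1 / fs_out)
  rate_on_grid <- function(events) {
    t <- events$times
    if (length(t) < 2L) stop("Too few events in span for a rate series.", call. = FALSE)
    ibi <- diff(t)
    mid <- t[-length(t)] + ibi / 2
    stats::approx(mid, 60 / ibi, xout = t_out, rule = 2)$y
  }
  list(
    hr = rate_on_grid(events_in_span(prep$beats[[p]], start_s - 2, end_s + 2)),
    resp = rate_on_grid(events_in_span(prep$breaths[[p]], start_s - 5, end_s + 5)),
    sc = resample_span(prep$filtered[[p]]$skin_conductance, start_s, end_s, fs_out),
    temp = resample_span(prep$filtered[[p]]$skin_temperature, start_s, end_s, fs_out)
  )
}

#' Extract the full feature table for one session
#'
#' Runs preprocessing (unless a preprocessed object is supplied) and builds
#' one row per interval — the baseline row (`interval == 0`) plus one row per
#' conversation interval — with 24 individual features (12 per participant),
#' 17 synchrony features, and the reference engagement (mean of the two
#' self-reports; `NA` for the baseline row).
#'
#' @param session A [dyad_session()].
#' @param prep Optional result of [preprocess_session()] for this session.
#' @param fs_out Substrate sampling rate in Hz (default 4).
#' @param bands Coherence bands (default [default_coherence_bands()]).
#' @return A tibble with columns `dyad_id`, `interval`, `kind`, features,
#'   `engagement`.
#' @export
extract_features <- function(session, prep = NULL, fs_out = 4,
                             bands = default_coherence_bands()) {
  stopifnot(inherits(session, "dyad_session"))
  if (is.null(prep)) prep <- preprocess_session(session, fs_out = fs_out)
  indiv <- individual_feature_rows(session, prep)
  sync <- purrr::pmap_dfr(session$intervals,
                          function(kind, interval, start_s, end_s, ...) {
    subs <- lapply(1:2, function(p) {
      substrates_for_span(session, prep, p, start_s, end_s)
    })
    vals <- extract_synchrony(subs, fs = prep$fs_out, bands = bands)
    tibble::as_tibble(as.list(vals))
  })
  eng <- c(NA_real_, dyad_engagement(session))
  dplyr::bind_cols(
    tibble::tibble(dyad_id = session$dyad_id),
    indiv, sync,
    tibble::tibble(engagement = eng)
  )
}

#' Feature table for a cohort of sessions
#'
#' Applies [extract_features()] to each session and appends the 12
#' participant-characteristic columns (constant within a dyad).
#'
#' @param sessions List of [dyad_session()] objects.
#' @param ... Passed to [extract_features()].
#' @return A tibble, one row per (dyad, interval) including baseline rows.
#' @export
cohort_features <- function(sessions, ...) {
  purrr::map_dfr(sessions, function(s) {
    ft <- extract_features(s, ...)
    chars <- unlist(lapply(1:2, function(p) {
      pi <- s$info[[p]]
      stats::setNames(
        c(pi$age, pi$gender_code, pi$social_anxiety, pi$depression,
          pi$cognitive_empathy, pi$affective_empathy),
        paste0(c("age", "gender_code", "social_anxiety", "depression",
                 "cognitive_empathy", "affective_empathy"), "_p", p))
    }))
    dplyr::bind_cols(ft, tibble::as_tibble(as.list(chars)))
  })
}
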