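#' Time-domain heart-rate-variability features
#'
#' Interbeat intervals (IBIs) are successive differences of the beat times
#' inside the interval. Features:
#' * `mean_hr` — 60 / mean(IBI), beats/min.
#' * `sdnn` — sample (n-1) standard deviation of IBIs, ms.
#' * `rmssd` — root-mean-square of successive IBI differences, ms.
#' * `pnn50` — percentage of successive IBI differences strictly greater
#'   than 50 ms in absolute value.
#'
#' `mean_hr` is defined as the rate of the mean interval, not the mean of
#' per-beat rates; the two differ for variable rhythms and the convention is
#' stated here for reproducibility.
#'
#' @param beats An [event_series()] restricted to the interval; >= 3 beats.
#' @return Named numeric vector `mean_hr`, `sdnn`, `rmssd`, `pnn50`.
#' @export
hrv_features <- function(beats) {
  stopifnot(inherits(beats, "event_series"))
  if (length(beats$times) < 3L) {
    stop("Need >= 3 beats in the interval for HRV features.", call. = FALSE)
  }
  ibi <- diff(beats$times)            # seconds
  dibi <- diff(ibi)
  c(mean_hr = 60 / mean(ibi),
    sdnn = stats::sd(ibi) * 1000,
    rmssd = sqrt(mean(dibi^2)) * 1000,
    pnn50 = 100 * mean(abs(dibi) * 1000 > 50))
}

#' Skin-conductance features
#'
#' Mean level, initial-to-final change (last minus first sample of the
#' filtered segment), SCR count and mean SCR amplitude. SCRs are attributed
#' to the interval containing their peak.
#'
#' @param sc_segment Filtered skin-conductance [channel_signal()] segment.
#' @param scrs Tibble of SCRs (from [detect_scrs()]) whose peaks fall inside
#'   the segment.
#' @return Named numeric vector `scl_mean`, `scl_delta`, `scr_count`,
#'   `scr_mean_amp` (0 when there are no SCRs).
#' @export
sc_features <- function(sc_segment, scrs = NULL) {
  stopifnot(inherits(sc_segment, "channel_signal"))
  x <- sc_segment$samples
  n_scr <- if (is.null(scrs)) 0L else nrow(scrs)
  c(scl_mean = mean(x),
    scl_delta = x[length(x)] - x[1],
    scr_count = as.numeric(n_scr),
    scr_mean_amp = if (n_scr > 0) mean(scrs$amplitude) else 0)
}

#' Respiration features
#'
#' Respiratory periods are successive differences of breath-peak times.
#'
#' @param breaths An [event_series()] of breaths inside the interval; >= 3.
#' @return Named numeric vector `resp_rate_mean` (60 / mean period,
#'   breaths/min) and `resp_period_sd` (sample SD of periods, s).
#' @export
resp_features <- function(breaths) {
  stopifnot(inherits(breaths, "event_series"))
  if (length(breaths$times) < 3L) {
    stop("Need >= 3 breaths in the interval for respiration features.",
         call. = FALSE)
  }
  per <- diff(breaths$times)
  c(resp_rate_mean = 60 / mean(per), resp_period_sd = stats::sd(per))
}

#' Skin-temperature features
#'
#' @param temp_segment Filtered skin-temperature [channel_signal()] segment.
#' @return Named numeric vector `temp_mean` and `temp_delta` (last minus
#'   first sample).
#' @export
temp_features <- function(temp_segment) {
  stopifnot(inherits(temp_segment, "channel_signal"))
  x <- temp_segment$samples
  c(temp_mean = mean(x), temp_delta = x[length(x)] - x[1])
}

INDIVIDUAL_FEATURES <- c("mean_hr", "sdnn", "rmssd", "pnn50",
                         "scl_mean", "scl_delta", "scr_count", "scr_mean_amp",
                         "resp_rate_mean", "resp_period_sd",
                         "temp_mean", "temp_delta")

# events within a half-open [start, end) span
events_in_span <- function(events, start_s, end_s) {
  keep <- events$times >= start_s & events$times < end_s
  event_series(events$times[keep], events$kind, events$interpolated[keep])
}

# Individual features for every (participant, interval) of a preprocessed
# session; one row per interval with <feature>_p1 / <feature>_p2 columns.
individual_feature_rows <- function(session, prep) {
  iv <- session$intervals
  rows <- purrr::pmap_dfr(iv, function(kind, interval, start_s, end_s, ...) {
    row <- list(interval = interval, kind = kind)
    for (p in 1:2) {
      beats <- events_in_span(prep$beats[[p]], start_s, end_s)
      breaths <- events_in_span(prep$breaths[[p]], start_s, end_s)
      scrs <- prep$scr_tables[[p]]
      scrs <- scrs[scrs$peak_s >= start_s & scrs$peak_s < end_s, , drop = FALSE]
      sc_seg <- cut_span(prep$filtered[[p]]$skin_conductance, start_s, end_s)
      temp_seg <- cut_span(prep$filtered[[p]]$skin_temperature, start_s, end_s)
      feats <- c(hrv_features(beats), sc_features(sc_seg, scrs),
                 resp_features(breaths), temp_features(temp_seg))
      names(feats) <- paste0(names(feats), "_p", p)
      row <- c(row, as.list(feats))
    }
    tibble::as_tibble(row)
  })
  rows
}

# cut a half-open [start, end) span out of one channel
cut_span <- function(sig, start_s, end_s) {
  fs <- sig$fs
  i0 <- ceiling(start_s * fs - 1e-9) + 1
  i1 <- ceiling(end_s * fs - 1e-9)
  channel_signal(sig$samples[i0:i1], fs = fs, channel = sig$channel,
                 units = sig$units)
}
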