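#' Detected physiological events
#'
#' Timestamps of R-waves or breath peaks, with a per-event flag marking
#' events that were inserted by [repair_beats()] rather than detected.
#'
#' @param times Strictly increasing event times in seconds.
#' @param kind `"r_wave"` or `"breath"`.
#' @param interpolated Logical vector, one flag per event (default all FALSE).
#' @return An `event_series` object.
#' @export
event_series <- function(times, kind = c("r_wave", "breath"),
                         interpolated = rep(FALSE, length(times))) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("Event times must be strictly increasing.", call. = FALSE)
  }
  if (length(interpolated) != length(times)) {
    stop("`interpolated` must have one flag per event.", call. = FALSE)
  }
  structure(list(times = times, kind = kind,
                 interpolated = as.logical(interpolated)),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d %s events, %.1f%% interpolated\n",
              length(x$times), x$kind,
              if (length(x$times)) 100 * mean(x$interpolated) else 0))
  invisible(x)
}

#' Zero-phase Butterworth lowpass filter
#'
#' Forward-backward (zero-phase) Butterworth lowpass. Applied by default at
#' 5 Hz, order 4, to skin conductance, respiration and skin temperature
#' before feature extraction. Zero-phase filtering is used so that filtering
#' introduces no lag that could bias lag-sensitive synchrony metrics.
#'
#' @param sig A [channel_signal()].
#' @param cutoff_hz Cutoff frequency in Hz; must be below Nyquist (`fs / 2`).
#' @param order Filter order of the underlying design (default 4); the
#'   forward-backward pass squares the magnitude response.
#' @return A filtered [channel_signal()] of identical length.
#' @export
lowpass <- function(sig, cutoff_hz = 5, order = 4) {
  stopifnot(inherits(sig, "channel_signal"))
  if (cutoff_hz >= sig$fs / 2) {
    stop(sprintf("Cutoff %g Hz must be below Nyquist (%g Hz).",
                 cutoff_hz, sig$fs / 2), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (sig$fs / 2), type = "low")
  # filtfilt is sensitive to large DC offsets at the edges; remove and restore
  mu <- mean(sig$samples)
  y <- filtfilt_padded(bf, sig$samples - mu, round(2 * sig$fs)) + mu
  channel_signal(y, fs = sig$fs, channel = sig$channel, units = sig$units)
}

# Zero-phase filtering with reflected end-padding to suppress the edge
# transients filtfilt leaves on finite records.
filtfilt_padded <- function(bf, x, pad_n) {
  n <- length(x)
  pad_n <- min(pad_n, n - 1L)
  head_pad <- 2 * x[1] - x[(pad_n + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad_n)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(pad_n + 1):(pad_n + n)]
}

# Local-maxima peak picker with refractory period and amplitude threshold.
# Returns sample indices of accepted peaks, greedily from highest amplitude.
find_peaks_refractory <- function(x, fs, refractory_s, min_height) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  is_max <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  is_max <- is_max[x[is_max] >= min_height]
  if (!length(is_max)) return(integer(0))
  ord <- is_max[order(x[is_max], decreasing = TRUE)]
  min_gap <- refractory_s * fs
  kept <- integer(0)
  for (idx in ord) {
    if (!length(kept) || all(abs(kept - idx) >= min_gap)) kept <- c(kept, idx)
  }
  sort(kept)
}

#' Detect R-waves in an ECG channel
#'
#' Emphasizes the QRS complex (bandpass 5-min(30, Nyquist*0.9) Hz, squared
#' magnitude), then picks local maxima above an adaptive threshold with a
#' 0.25-s refractory period. Each detection is refined to the extremum of the
#' raw ECG within +/- 40 ms.
#'
#' @param ecg ECG [channel_signal()], duration >= 2 s.
#' @param refractory_s Minimum spacing between detected beats (default 0.25 s).
#' @return An [event_series()] of R-wave times. A warning is issued and an
#'   empty series returned when no peaks are detectable (e.g. flat signal).
#' @export
detect_r_waves <- function(ecg, refractory_s = 0.25) {
  stopifnot(inherits(ecg, "channel_signal"))
  if (duration(ecg) < 2) stop("ECG segment shorter than 2 s.", call. = FALSE)
  x <- ecg$samples - stats::median(ecg$samples)
  if (stats::sd(x) < 1e-12) {
    warning("No detectable R-waves (flat ECG).")
    return(event_series(numeric(0), "r_wave"))
  }
  hi <- min(30, 0.9 * ecg$fs / 2)
  bf <- signal::butter(2, c(5, hi) / (ecg$fs / 2), type = "pass")
  e <- filtfilt_padded(bf, x, round(2 * ecg$fs))^2
  thr <- 0.2 * stats::quantile(e, 0.995)
  idx <- find_peaks_refractory(e, ecg$fs, refractory_s, thr)
  if (!length(idx)) {
    warning("No detectable R-waves.")
    return(event_series(numeric(0), "r_wave"))
  }
  # refine on the raw (rectified) ECG near each energy peak
  w <- max(1L, round(0.04 * ecg$fs))
  refined <- vapply(idx, function(i) {
    lo <- max(1L, i - w); hi2 <- min(length(x), i + w)
    as.integer(lo + which.max(abs(x[lo:hi2])) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # re-apply refractory after refinement
  keep <- c(TRUE, diff(refined) >= refractory_s * ecg$fs)
  refined <- refined[keep]
  event_series((refined - 1) / ecg$fs, "r_wave")
}

#' Repair missed or spurious beats
#'
#' Programmatic analog of manual R-wave correction: any interbeat gap between
#' 1.5x and 2.5x the local median interbeat interval is treated as one missed
#' beat and an event is inserted halfway between the two neighboring valid
#' beats, flagged as interpolated. Events closer than `ibi_bounds[1]` are
#' merged (the first is kept). The interpolated fraction is available from
#' the returned series; in practice it should be on the order of a few
#' percent of beats.
#'
#' @param beats An [event_series()] with >= 3 events.
#' @param ibi_bounds Physiological interbeat-interval bounds in seconds
#'   (default `c(0.25, 2)`); the lower bound drives the merge rule.
#' @param gap_range Multiples of the local median IBI that qualify a gap as a
#'   single missed beat (default `c(1.5, 2.5)`).
#' @return An [event_series()] with inserted events flagged.
#' @export
repair_beats <- function(beats, ibi_bounds = c(0.25, 2), gap_range = c(1.5, 2.5)) {
  stopifnot(inherits(beats, "event_series"))
  t <- beats$times
  if (length(t) < 3L) stop("Need >= 3 beats to repair.", call. = FALSE)
  # merge events closer than min IBI (keep the earlier event)
  keep <- c(TRUE, diff(t) >= ibi_bounds[1])
  t <- t[keep]
  flags <- beats$interpolated[keep]
  ibis <- diff(t)
  new_t <- t
  new_f <- flags
  half_w <- 5L  # local window (beats) for the running median IBI
  for (i in seq_along(ibis)) {
    lo <- max(1L, i - half_w); hi <- min(length(ibis), i + half_w)
    local_med <- stats::median(ibis[lo:hi])
    if (ibis[i] > gap_range[1] * local_med && ibis[i] < gap_range[2] * local_med) {
      new_t <- c(new_t, (t[i] + t[i + 1]) / 2)
      new_f <- c(new_f, TRUE)
    }
  }
  ord <- order(new_t)
  event_series(new_t[ord], beats$kind, new_f[ord])
}

#' Detect breath peaks in a respiration channel
#'
#' Lowpasses the airflow signal to the respiration band (1 Hz) and picks one
#' peak per breath cycle with a 1.5-s refractory period and a prominence
#' floor relative to the signal's amplitude spread.
#'
#' @param resp Respiration [channel_signal()], duration >= 10 s.
#' @param refractory_s Minimum spacing between breaths (default 1.5 s).
#' @return An [event_series()] of breath-peak times.
#' @export
detect_breaths <- function(resp, refractory_s = 1.5) {
  stopifnot(inherits(resp, "channel_signal"))
  if (duration(resp) < 10) stop("Respiration segment shorter than 10 s.", call. = FALSE)
  x <- resp$samples - mean(resp$samples)
  if (stats::sd(x) < 1e-12) return(event_series(numeric(0), "breath"))
  if (resp$fs / 2 > 1) {
    bf <- signal::butter(2, 1 / (resp$fs / 2), type = "low")
    x <- filtfilt_padded(bf, x, round(3 * resp$fs))
  }
  thr <- 0.2 * stats::quantile(abs(x), 0.95)
  idx <- find_peaks_refractory(x, resp$fs, refractory_s, thr)
  event_series((idx - 1) / resp$fs, "breath")
}

#' Detect skin conductance responses
#'
#' An SCR is a transient rise: the onset is the last sample before a
#' sustained increase (first derivative > 0 for at least `sustain_s`), the
#' peak is the local maximum ending the rise, and the amplitude is peak value
#' minus onset value. Events are kept when the rise time is under `max_rise`
#' seconds and the amplitude is at least `min_amp` microsiemens.
#'
#' @param sc Skin-conductance [channel_signal()], already lowpassed (see
#'   [lowpass()]).
#' @param min_amp Minimum onset-to-peak amplitude in microsiemens
#'   (default 0.05).
#' @param max_rise Maximum onset-to-peak rise time in seconds (default 5);
#'   the peak must occur in strictly less than `max_rise` s.
#' @param sustain_s Minimum duration of positive derivative defining a
#'   sustained rise (default 0.2 s).
#' @return A tibble with one row per SCR: `onset_s`, `peak_s`, `amplitude`.
#' @export
detect_scrs <- function(sc, min_amp = 0.05, max_rise = 5, sustain_s = 0.2) {
  stopifnot(inherits(sc, "channel_signal"))
  x <- sc$samples
  fs <- sc$fs
  d <- diff(x)
  rising <- d > 0
  empty <- tibble::tibble(onset_s = numeric(0), peak_s = numeric(0),
                          amplitude = numeric(0))
  if (!any(rising)) return(empty)
  r <- rle(rising)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_run <- max(1L, round(sustain_s * fs))
  out <- list()
  for (j in which(r$values & r$lengths >= min_run)) {
    onset_i <- starts[j]          # last sample before the rise
    peak_i <- ends[j] + 1L        # local max ending the rise
    rise <- (peak_i - onset_i) / fs
    amp <- x[peak_i] - x[onset_i]
    # tolerance keeps the >= threshold stable under float rounding
    if (rise < max_rise && amp >= min_amp - 1e-12) {
      out[[length(out) + 1L]] <- c((onset_i - 1) / fs, (peak_i - 1) / fs, amp)
    }
  }
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  tibble::tibble(onset_s = m[, 1], peak_s = m[, 2], amplitude = m[, 3])
}

#' Instantaneous rate series from event times
#'
#' Converts interbeat (or interbreath) intervals to a uniformly sampled
#' rate-as-a-function-of-time series: each interval contributes the rate
#' 60/IBI at the interval midpoint, and midpoint rates are linearly
#' interpolated onto a uniform grid at `fs_out` (endpoints held constant
#' beyond the first/last midpoint).
#'
#' @param events An [event_series()] with >= 2 events.
#' @param fs_out Output sampling rate in Hz (default 4).
#' @param t_start,t_end Optional grid limits in seconds; default to the first
#'   and last event time.
#' @return A list of class `rate_series`: `values` (beats- or breaths-per-
#'   minute), `fs`, `t0` (time of the first grid sample).
#' @export
instantaneous_rate <- function(events, fs_out = 4, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(events, "event_series"))
  t <- events$times
  if (length(t) < 2L) stop("Need >= 2 events for a rate series.", call. = FALSE)
  ibi <- diff(t)
  mid <- t[-length(t)] + ibi / 2
  rate <- 60 / ibi
  if (is.null(t_start)) t_start <- t[1]
  if (is.null(t_end)) t_end <- t[length(t)]
  grid <- seq(t_start, t_end, by = 1 / fs_out)
  vals <- if (length(mid) == 1L) rep(rate, length(grid)) else {
    stats::approx(mid, rate, xout = grid, rule = 2)$y
  }
  structure(list(values = vals, fs = fs_out, t0 = t_start), class = "rate_series")
}

#' Preprocess one session into events and synchrony substrates
#'
#' Runs the full per-session preprocessing: lowpass filtering of skin
#' conductance, respiration and temperature; R-wave and breath detection
#' (with missed-beat repair); SCR detection; and per-interval construction of
#' the four synchrony substrates (instantaneous heart rate, instantaneous
#' respiration rate, skin conductance and skin temperature, all resampled to
#' a common `fs_out`).
#'
#' @param session A [dyad_session()].
#' @param fs_out Common substrate sampling rate in Hz (default 4).
#' @return A list with `events` (tibble: dyad_id, participant, kind, time_s,
#'   interpolated), `scrs` (tibble: dyad_id, participant, onset_s, peak_s,
#'   amplitude), `filtered` (per participant: filtered sc/resp/temp
#'   channel_signals), `beats`/`breaths` (per participant event_series), and
#'   `fs_out`.
#' @export
preprocess_session <- function(session, fs_out = 4) {
  stopifnot(inherits(session, "dyad_session"))
  out <- list(fs_out = fs_out, filtered = list(), beats = list(),
              breaths = list(), scr_tables = list())
  ev_rows <- list()
  scr_rows <- list()
  for (p in 1:2) {
    sigs <- session$signals[[p]]
    filt <- list(
      skin_conductance = lowpass(sigs$skin_conductance),
      respiration = lowpass(sigs$respiration),
      skin_temperature = lowpass(sigs$skin_temperature)
    )
    beats <- repair_beats(detect_r_waves(sigs$ecg))
    breaths <- detect_breaths(filt$respiration)
    scrs <- detect_scrs(filt$skin_conductance)
    out$filtered[[p]] <- filt
    out$beats[[p]] <- beats
    out$breaths[[p]] <- breaths
    out$scr_tables[[p]] <- scrs
    ev_rows[[length(ev_rows) + 1L]] <- tibble::tibble(
      dyad_id = session$dyad_id, participant = p, kind = "r_wave",
      time_s = beats$times, interpolated = beats$interpolated)
    ev_rows[[length(ev_rows) + 1L]] <- tibble::tibble(
      dyad_id = session$dyad_id, participant = p, kind = "breath",
      time_s = breaths$times, interpolated = breaths$interpolated)
    scr_rows[[length(scr_rows) + 1L]] <- dplyr::mutate(
      scrs, dyad_id = session$dyad_id, participant = p, .before = 1)
  }
  out$events <- dplyr::bind_rows(ev_rows)
  out$scrs <- dplyr::bind_rows(scr_rows)
  out
}
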