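#' Physiological channel signal
#'
#' A uniformly sampled single-channel recording. Channels follow the study
#' montage: ECG (mV), skin conductance (microsiemens), respiration (a.u.,
#' airflow thermistor), and peripheral skin temperature (degC).
#'
#' @param samples Numeric vector of samples. Must be finite; recordings with
#'   NaN runs are rejected at construction so that downstream event detection
#'   never sees gaps.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel One of `"ecg"`, `"skin_conductance"`, `"respiration"`,
#'   `"skin_temperature"`.
#' @param units Unit string; defaults to the conventional unit per channel.
#'
#' @return An object of class `channel_signal`: a list with elements
#'   `samples`, `fs`, `channel`, `units`.
#' @examples
#' sig <- channel_signal(sin(2 * pi * 0.25 * seq(0, 60, by = 0.01)),
#'                       fs = 100, channel = "respiration")
#' duration(sig)
#' @export
channel_signal <- function(samples, fs, channel, units = NULL) {
  channel <- match.arg(channel, c("ecg", "skin_conductance", "respiration",
                                  "skin_temperature"))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz).", call. = FALSE)
  }
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("`samples` must contain at least one sample.", call. = FALSE)
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("`samples` contains NaN/Inf values; channel '", channel,
         "' must be gap-free at ingest.", call. = FALSE)
  }
  if (is.null(units)) {
    units <- switch(channel,
                    ecg = "mV",
                    skin_conductance = "microsiemens",
                    respiration = "a.u.",
                    skin_temperature = "degC")
  }
  structure(list(samples = samples, fs = fs, channel = channel, units = units),
            class = "channel_signal")
}

#' @export
print.channel_signal <- function(x, ...) {
  cat(sprintf("<channel_signal> %s: %d samples @ %g Hz (%.1f s), units %s\n",
              x$channel, length(x$samples), x$fs, duration(x), x$units))
  invisible(x)
}

#' Duration of a channel signal in seconds
#' @param x A [channel_signal()].
#' @return Duration in seconds (`length(samples) / fs`).
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "channel_signal"))
  length(x$samples) / x$fs
}

#' Sample times of a channel signal
#' @param x A [channel_signal()].
#' @return Numeric vector of sample times in seconds; sample i sits at
#'   `(i - 1) / fs` (time runs from recording start).
#' @export
sample_times <- function(x) {
  stopifnot(inherits(x, "channel_signal"))
  (seq_along(x$samples) - 1) / x$fs
}

#' Interval layout of a session
#'
#' One resting baseline span plus an ordered set of conversation spans, all
#' half-open `[start_s, end_s)` in seconds from recording start. The default
#' layout is a 2-min baseline followed by 15 contiguous 60-s conversation
#' intervals; self-report pauses between conversation intervals, when
#' present in real recordings, are represented simply as gaps between spans
#' and are excluded from all analysis.
#'
#' @param baseline Length-2 numeric `c(start_s, end_s)`.
#' @param conversation Two-column matrix or data frame of conversation spans
#'   (`start_s`, `end_s`), strictly increasing and non-overlapping.
#' @return An object of class `interval_set`: a tibble with columns `kind`
#'   (`"baseline"`/`"conversation"`), `interval` (0 for baseline, 1..n for
#'   conversation), `start_s`, `end_s`.
#' @examples
#' iv <- default_intervals()
#' n_conversation(iv)
#' @export
interval_set <- function(baseline, conversation) {
  baseline <- as.numeric(baseline)
  if (length(baseline) != 2L || anyNA(baseline)) {
    stop("`baseline` must be c(start_s, end_s).", call. = FALSE)
  }
  conversation <- as.matrix(as.data.frame(conversation))
  if (ncol(conversation) != 2L || nrow(conversation) < 1L) {
    stop("`conversation` must have columns start_s, end_s and >= 1 span.",
         call. = FALSE)
  }
  spans <- rbind(baseline, conversation)
  if (any(spans[, 2] <= spans[, 1])) {
    stop("All spans must satisfy end_s > start_s.", call. = FALSE)
  }
  starts <- spans[, 1]
  ends <- spans[, 2]
  ord <- order(starts)
  if (any(diff(starts[ord]) <= 0) || any(ends[ord][-nrow(spans)] > starts[ord][-1])) {
    stop("Spans must be non-overlapping and strictly increasing.", call. = FALSE)
  }
  out <- tibble::tibble(
    kind = c("baseline", rep("conversation", nrow(conversation))),
    interval = c(0L, seq_len(nrow(conversation))),
    start_s = as.numeric(spans[, 1]),
    end_s = as.numeric(spans[, 2])
  )
  class(out) <- c("interval_set", class(out))
  out
}

#' @rdname interval_set
#' @param n_conversation Number of conversation intervals (default 15).
#' @param baseline_dur Baseline duration in seconds (default 120).
#' @param conv_dur Conversation interval duration in seconds (default 60).
#' @param gap Pause between conversation intervals in seconds (default 0).
#' @export
default_intervals <- function(n_conversation = 15L, baseline_dur = 120,
                              conv_dur = 60, gap = 0) {
  starts <- baseline_dur + (seq_len(n_conversation) - 1) * (conv_dur + gap)
  interval_set(c(0, baseline_dur), cbind(starts, starts + conv_dur))
}

#' @rdname interval_set
#' @param x An `interval_set`.
#' @export
n_conversation <- function(x) {
  sum(x$kind == "conversation")
}

#' Segment a channel signal into interval pieces
#'
#' Cuts one channel into the baseline segment plus one segment per
#' conversation span. Spans are half-open `[start, end)`: the sample at time
#' `t = (i - 1) / fs` belongs to the span iff `start <= t < end`, so adjacent
#' spans share no sample. Samples between spans (self-report pauses) are
#' dropped.
#'
#' @param signal A [channel_signal()].
#' @param intervals An [interval_set()]. All spans must lie within the
#'   signal's duration.
#' @return A list of `channel_signal` segments, named `baseline`,
#'   `conversation_1`, ..., in interval order.
#' @export
segment <- function(signal, intervals) {
  stopifnot(inherits(signal, "channel_signal"), inherits(intervals, "interval_set"))
  dur <- duration(signal)
  if (any(intervals$end_s > dur + 1e-9)) {
    stop(sprintf("Interval span ends at %.3f s but signal lasts only %.3f s.",
                 max(intervals$end_s), dur), call. = FALSE)
  }
  fs <- signal$fs
  segs <- purrr::pmap(intervals, function(kind, interval, start_s, end_s, ...) {
    # sample i (1-based) is at (i-1)/fs; include start_s <= t < end_s
    i0 <- ceiling(start_s * fs - 1e-9) + 1
    i1 <- ceiling(end_s * fs - 1e-9)  # last index with t < end_s
    channel_signal(signal$samples[i0:i1], fs = fs, channel = signal$channel,
                   units = signal$units)
  })
  names(segs) <- ifelse(intervals$kind == "baseline", "baseline",
                        paste0("conversation_", intervals$interval))
  segs
}
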