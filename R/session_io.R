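#' Write a dyad session to a manifest directory
#'
#' Serializes a session as one YAML manifest plus one CSV per
#' participant-channel (`p<i>_<channel>.csv`, header `time_s,value`). The
#' layout is plain text throughout so fixtures stay diff-able.
#'
#' @param session A [dyad_session()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "dyad_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chan_files <- list()
  for (p in 1:2) {
    for (ch in CHANNELS) {
      sig <- session$signals[[p]][[ch]]
      fname <- sprintf("p%d_%s.csv", p, ch)
      # %.17g round-trips IEEE doubles exactly through read.csv
      df <- data.frame(time_s = sprintf("%.17g", sample_times(sig)),
                       value = sprintf("%.17g", sig$samples))
      utils::write.csv(df, file.path(dir, fname), row.names = FALSE, quote = FALSE)
      chan_files[[paste0("p", p)]][[ch]] <-
        list(file = fname, fs = sig$fs, units = sig$units)
    }
  }
  manifest <- list(
    dyad_id = session$dyad_id,
    channels = chan_files,
    intervals = list(
      baseline = as.numeric(unlist(
        session$intervals[session$intervals$kind == "baseline",
                          c("start_s", "end_s")])),
      conversation = unname(apply(
        session$intervals[session$intervals$kind == "conversation",
                          c("start_s", "end_s")], 1, as.list))
    ),
    self_reports = list(p1 = session$self_reports[[1]],
                        p2 = session$self_reports[[2]]),
    participants = lapply(session$info, unclass),
    coder_ratings = session$coder_ratings
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path, precision = 15)
  invisible(path)
}

#' Load a dyad session from a manifest
#'
#' Reads the YAML manifest written by [write_session()] (or authored by
#' hand), loads each referenced channel CSV, and validates every session
#' invariant. Any violation (missing channel file, self-report outside
#' \[0, 100\], overlapping interval spans, missing baseline) raises an error
#' naming the offending element.
#'
#' @param manifest_path Path to `manifest.yaml`.
#' @return A validated [dyad_session()].
#' @export
load_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("Manifest not found: ", manifest_path, call. = FALSE)
  }
  m <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  for (field in c("dyad_id", "channels", "intervals", "self_reports", "participants")) {
    if (is.null(m[[field]])) stop("Manifest missing field '", field, "'.", call. = FALSE)
  }
  if (is.null(m$intervals$baseline)) {
    stop("Manifest missing baseline interval span.", call. = FALSE)
  }
  signals <- lapply(c("p1", "p2"), function(p) {
    pch <- m$channels[[p]]
    out <- lapply(CHANNELS, function(ch) {
      entry <- pch[[ch]]
      if (is.null(entry)) {
        stop("Manifest missing channel '", ch, "' for participant ", p, ".",
             call. = FALSE)
      }
      fpath <- file.path(dir, entry$file)
      if (!file.exists(fpath)) {
        stop("Channel file not found for ", p, " ", ch, ": ", fpath, call. = FALSE)
      }
      df <- utils::read.csv(fpath)
      channel_signal(df$value, fs = entry$fs, channel = ch, units = entry$units)
    })
    names(out) <- CHANNELS
    out
  })
  conv <- do.call(rbind, lapply(m$intervals$conversation, function(sp) {
    as.numeric(unlist(sp))
  }))
  intervals <- interval_set(as.numeric(unlist(m$intervals$baseline)), conv)
  info <- lapply(m$participants, function(pi) {
    participant_info(pi$age, pi$gender_code, pi$social_anxiety, pi$depression,
                     pi$cognitive_empathy, pi$affective_empathy)
  })
  dyad_session(m$dyad_id, signals, intervals,
               list(as.numeric(m$self_reports$p1), as.numeric(m$self_reports$p2)),
               info, coder_ratings = m$coder_ratings)
}
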