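#' Parameters of the synthetic dyad-cohort generator
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 16 dyads, a 2-min resting baseline plus 15 x 60-s conversation intervals,
#' engagement self-reported on a 0-100 scale by both participants, and four
#' physiological channels per participant sampled at `fs` Hz.
#'
#' The engagement process is a per-dyad level (normal, mean 76, SD 7) plus a
#' smooth AR(1) within-dyad trajectory (stationary SD 11, lag-1 correlation
#' 0.7); each rater reports the latent value plus independent normal noise
#' (SD 14), clipped to \[0, 100\] and rounded to 0.1 (visual-analog-scale
#' digitization). These values are calibrated so the cohort reproduces the
#' observed rating-agreement statistics: with rater noise SD \eqn{\sigma}
#' the between-rater absolute difference has median
#' \eqn{0.954\,\sigma \approx 13.4}, and with latent variance
#' \eqn{V = 7^2 + 11^2 = 170} the one-way ICC is approximately
#' \eqn{V / (V + \sigma^2) \approx 0.46}.
#'
#' Coupling: a shared band-limited (0.05-0.3 Hz) drive is injected into both
#' participants' heart-rate and respiration-rate processes with amplitude
#' proportional to `coupling * engagement / 100`; a fraction of skin
#' conductance responses is shared between participants (co-occurring within
#' ~0.3 s) with probability growing the same way, and a heavily smoothed
#' copy of the drive enters skin temperature. `coupling = 0` yields an
#' uncoupled null cohort; 1 is the default and 2 a strongly coupled cohort.
#'
#' @param n_dyads Number of dyads (default 16).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   parameter list.
#' @param coupling Coupling gain `kappa` >= 0 (default 1).
#' @param fs Channel sampling rate in Hz (default 100).
#' @param ... Overrides for any default listed below.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_dyads = 16L, seed = 1L, coupling = 1, fs = 100,
                             ...) {
  p <- list(
    n_dyads = as.integer(n_dyads), seed = as.integer(seed),
    coupling = coupling, fs = fs,
    n_intervals = 15L, baseline_dur = 120, conv_dur = 60,
    # engagement / rating process
    level_mean = 76, level_sd = 7, walk_sd = 11, walk_phi = 0.7,
    rater_noise_sd = 14, baseline_engagement = 30,
    n_disagree = 0L, disagree_offset = 22,
    # hearts: baseline rate, engagement gain, coupling gain, personal noise,
    # respiratory sinus arrhythmia amplitude (all beats/min)
    hr_base_mean = 70, hr_base_sd = 6, hr_gain = 12, hr_drive_gain = 5,
    hr_personal_sd = 2, rsa_amp = 3,
    # respiration (breaths/min)
    resp_base_mean = 15, resp_base_sd = 1.5, resp_drive_gain = 3,
    resp_personal_sd = 0.5,
    # skin conductance (microsiemens)
    sc_base_mean = 5, sc_base_sd = 1.5, sc_drift_slope = -0.002,
    scr_rate_base = 1.5, scr_rate_gain = 4.5,   # SCRs per minute
    scr_amp_min = 0.1, scr_amp_max = 0.3, scr_amp_gain = 0.2,
    scr_rise = 2, scr_decay = 4, scr_min_gap = 8, scr_share_jitter = 0.3,
    # skin temperature (degC)
    temp_base_mean = 32, temp_base_sd = 1, temp_ar_sd = 0.02,
    temp_ar_phi = 0.999, temp_drive_gain = 0.1,
    # measurement noise
    ecg_noise_sd = 0.02, resp_noise_sd = 0.05, sc_noise_sd = 0,
    temp_noise_sd = 0,
    # coder ratings
    coder_n = 12L, coder_noise_sd = 12,
    # cohort characteristics (means/SDs of the emulated population)
    age_mean = 20.4, age_sd = 2.5,
    trait_moments = list(
      social_anxiety = c(36.9, 8.2, 12, 60),
      depression = c(17.0, 10.6, 0, 60),
      cognitive_empathy = c(55.5, 9.6, 19, 95),
      affective_empathy = c(32.3, 4.7, 12, 60)),
    dyad_gender_probs = c(mm = 9, ff = 2, mf = 4, nn = 1) / 16
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("Unknown generator parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  utils::modifyList(p, over)
}

# band-limited unit-variance Gaussian noise via FFT masking
band_limited_noise <- function(n, fs, f_lo, f_hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # two-sided frequency
  X[f < f_lo | f > f_hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s < 1e-12) return(rep(0, n))
  y / s
}

#' Generate one dyad's latent engagement and rater reports
#'
#' Latent engagement is a smooth bounded AR(1) trajectory around a per-dyad
#' level; each rater reports the latent value plus independent noise. For a
#' "disagreeing" dyad the two raters additionally receive opposite constant
#' offsets (+/- `disagree_offset`), pushing the median between-rater
#' absolute difference past any reasonable screening threshold.
#'
#' @param params A [generator_params()] list.
#' @param disagree Mark this dyad as a disagreeing dyad.
#' @return List with `latent` (length `n_intervals`, in \[0, 100\]) and
#'   `reports` (list of two numeric vectors, rounded to 0.1).
#' @export
gen_engagement <- function(params, disagree = FALSE) {
  n <- params$n_intervals
  level <- stats::rnorm(1, params$level_mean, params$level_sd)
  phi <- params$walk_phi
  innov_sd <- params$walk_sd * sqrt(1 - phi^2)
  dev <- numeric(n)
  dev[1] <- stats::rnorm(1, 0, params$walk_sd)
  for (i in seq_len(n - 1)) dev[i + 1] <- phi * dev[i] + stats::rnorm(1, 0, innov_sd)
  latent <- pmin(100, pmax(0, level + dev))
  offs <- if (disagree) c(params$disagree_offset, -params$disagree_offset) else c(0, 0)
  reports <- lapply(1:2, function(r) {
    round(pmin(100, pmax(0, latent + offs[r] +
                           stats::rnorm(n, 0, params$rater_noise_sd))), 1)
  })
  list(latent = latent, reports = reports)
}

# engagement as a per-sample step function over the whole session
engagement_steps <- function(latent, params) {
  fs <- params$fs
  n_base <- round(params$baseline_dur * fs)
  conv <- rep(latent, each = round(params$conv_dur * fs))
  c(rep(params$baseline_engagement, n_base), conv)
}

# place SCR onset times in [lo, hi) at `count` events with a minimum gap,
# also respecting `prev` (last onset before lo); returns sorted times
place_scr_times <- function(count, lo, hi, min_gap, prev = -Inf) {
  times <- numeric(0)
  last <- prev
  for (i in seq_len(count)) {
    earliest <- max(lo, last + min_gap)
    if (earliest >= hi - min_gap / 2) break
    t <- stats::runif(1, earliest, min(hi, earliest + 2 * min_gap))
    if (t >= hi) break
    times <- c(times, t)
    last <- t
  }
  times
}

#' Generate one dyad's physiological signals
#'
#' Builds both participants' four channels over the full session from the
#' latent engagement trajectory. Heart rate and respiration rate are slow
#' processes sharing a band-limited drive whose amplitude grows with
#' `coupling * engagement`; beats arise by integrate-and-fire on the heart
#' rate and are rendered as narrow pulses (sufficient for R-wave detection,
#' not a morphological PQRST); respiration is a unit sinusoid at the
#' instantaneous respiration rate; skin conductance is a declining tonic
#' level plus planted SCRs (rate and amplitude growing with engagement, a
#' coupling-dependent fraction shared between participants); temperature is
#' a slow AR(1) drift plus a heavily smoothed shared component. All planted
#' event times are snapped to the sampling grid and recorded as ground
#' truth.
#'
#' @param latent Numeric vector of per-interval latent engagement.
#' @param params A [generator_params()] list.
#' @return List `signals` (2 participants x 4 [channel_signal()]s) and
#'   `truth` (per participant: `beat_times`, `breath_times`, `scrs` tibble;
#'   plus `coupling_amplitude` per interval).
#' @export
gen_signals <- function(latent, params) {
  fs <- params$fs
  e_t <- engagement_steps(latent, params)
  n <- length(e_t)
  t_grid <- (seq_len(n) - 1) / fs
  amp_t <- params$coupling * e_t / 100
  drive <- band_limited_noise(n, fs, 0.05, 0.3)
  # smooth the step edges of amp_t a little so rates have no jumps
  k <- max(1L, round(2 * fs))
  amp_s <- stats::filter(c(rep(amp_t[1], k), amp_t, rep(amp_t[n], k)),
                         rep(1 / k, k), sides = 2)
  amp_s <- as.numeric(amp_s)[(k + 1):(k + n)]
  e_s <- stats::filter(c(rep(e_t[1], k), e_t, rep(e_t[n], k)),
                       rep(1 / k, k), sides = 2)
  e_s <- as.numeric(e_s)[(k + 1):(k + n)]

  # 10-s one-sided moving average of the drive, for the sluggish temperature
  ma_n <- round(10 * fs)
  drive_slow <- as.numeric(stats::filter(drive, rep(1 / ma_n, ma_n), sides = 1))
  drive_slow[is.na(drive_slow)] <- 0

  signals <- list(); truth <- list()
  shared_scrs <- NULL  # filled on p == 1, reused on p == 2
  for (p in 1:2) {
    hr_base <- stats::rnorm(1, params$hr_base_mean, params$hr_base_sd)
    resp_base <- stats::rnorm(1, params$resp_base_mean, params$resp_base_sd)
    sc_base <- max(1, stats::rnorm(1, params$sc_base_mean, params$sc_base_sd))
    temp_base <- stats::rnorm(1, params$temp_base_mean, params$temp_base_sd)

    resp_rate <- resp_base + params$resp_drive_gain * amp_s * drive +
      params$resp_personal_sd * band_limited_noise(n, fs, 0.01, 0.05)
    resp_rate <- pmax(6, resp_rate)
    resp_phase <- 2 * pi * cumsum(resp_rate / 60) / fs

    hr <- hr_base + params$hr_gain * e_s / 100 +
      params$hr_drive_gain * amp_s * drive +
      params$hr_personal_sd * band_limited_noise(n, fs, 0.05, 0.3) +
      params$rsa_amp * sin(resp_phase)
    hr <- pmax(40, hr)

    # integrate-and-fire beats, snapped to the grid
    beat_phase <- cumsum(hr / 60) / fs
    beat_idx <- which(diff(floor(c(0, beat_phase))) > 0)
    beat_times <- (beat_idx - 1) / fs
    ecg <- numeric(n)
    w <- round(0.02 * fs)
    pulse <- exp(-0.5 * ((-w:w) / (0.01 * fs))^2)
    for (bi in beat_idx) {
      lo <- max(1L, bi - w); hi <- min(n, bi + w)
      ecg[lo:hi] <- ecg[lo:hi] + pulse[(lo - bi + w + 1):(hi - bi + w + 1)]
    }
    if (params$ecg_noise_sd > 0) ecg <- ecg + stats::rnorm(n, 0, params$ecg_noise_sd)

    resp <- sin(resp_phase)
    # grid-snapped true breath-peak times (local maxima of the clean signal)
    d <- diff(resp)
    breath_idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
    breath_times <- (breath_idx - 1) / fs
    if (params$resp_noise_sd > 0) resp <- resp + stats::rnorm(n, 0, params$resp_noise_sd)

    # skin conductance: declining tonic + planted SCRs
    sc <- sc_base + params$sc_drift_slope * t_grid
    bounds <- c(0, params$baseline_dur,
                params$baseline_dur + seq_len(params$n_intervals) * params$conv_dur)
    iv_eng <- c(params$baseline_engagement, latent)
    onsets <- numeric(0); amps <- numeric(0); shared_flag <- logical(0)
    if (p == 1L) shared_scrs <- list()
    prev <- -Inf
    for (j in seq_along(iv_eng)) {
      lo <- bounds[j]; hi <- bounds[j + 1]
      rate <- params$scr_rate_base + params$scr_rate_gain * iv_eng[j] / 100
      count <- stats::rpois(1, rate * (hi - lo) / 60)
      share_p <- min(0.8, params$coupling * iv_eng[j] / 100)
      if (p == 1L) {
        ts <- place_scr_times(count, lo + 2, hi - 6, params$scr_min_gap, prev)
        sh <- stats::runif(length(ts)) < share_p
        shared_scrs[[j]] <- ts[sh]
        flag <- sh
      } else {
        sh_ts <- shared_scrs[[j]] +
          stats::rnorm(length(shared_scrs[[j]]), 0, params$scr_share_jitter)
        n_priv <- max(0L, count - length(sh_ts))
        ts_priv <- place_scr_times(n_priv, lo + 2, hi - 6, params$scr_min_gap, prev)
        ts <- sort(c(sh_ts, ts_priv))
        # enforce the minimum gap after merging (drop later offenders)
        if (length(ts) > 1L) {
          keep <- c(TRUE, diff(ts) >= params$scr_min_gap)
          ts <- ts[keep]
        }
        ts <- ts[ts >= lo + 2 & ts <= hi - 6]
        flag <- rep(NA, length(ts))
      }
      if (length(ts)) {
        prev <- max(ts)
        onsets <- c(onsets, ts)
        amps <- c(amps, stats::runif(length(ts), params$scr_amp_min,
                                     params$scr_amp_max) +
                    params$scr_amp_gain * iv_eng[j] / 100)
        shared_flag <- c(shared_flag, flag)
      }
    }
    onsets <- round(onsets * fs) / fs  # snap to grid
    rise_n <- round(params$scr_rise * fs)
    for (i in seq_along(onsets)) {
      o_i <- round(onsets[i] * fs) + 1L
      if (o_i + rise_n > n) next
      ramp_idx <- o_i:(o_i + rise_n)
      sc[ramp_idx] <- sc[ramp_idx] + amps[i] * seq(0, 1, length.out = rise_n + 1L)
      tail_idx <- (o_i + rise_n + 1L):n
      if (length(tail_idx) && tail_idx[1] <= n) {
        dt <- (seq_along(tail_idx)) / fs
        sc[tail_idx] <- sc[tail_idx] + amps[i] * exp(-dt / params$scr_decay)
      }
    }
    if (params$sc_noise_sd > 0) sc <- sc + stats::rnorm(n, 0, params$sc_noise_sd)

    ar <- as.numeric(stats::filter(stats::rnorm(n, 0, params$temp_ar_sd),
                                   params$temp_ar_phi, method = "recursive"))
    temp <- temp_base + ar + params$temp_drive_gain * amp_s * drive_slow
    if (params$temp_noise_sd > 0) temp <- temp + stats::rnorm(n, 0, params$temp_noise_sd)

    signals[[p]] <- list(
      ecg = channel_signal(ecg, fs, "ecg"),
      skin_conductance = channel_signal(sc, fs, "skin_conductance"),
      respiration = channel_signal(resp, fs, "respiration"),
      skin_temperature = channel_signal(temp, fs, "skin_temperature"))
    truth[[p]] <- list(
      beat_times = beat_times, breath_times = breath_times,
      scrs = tibble::tibble(onset_s = onsets, amplitude = amps))
  }
  list(signals = signals,
       truth = list(participants = truth,
                    coupling_amplitude = params$coupling * latent / 100))
}

draw_participant_info <- function(params, gender_code) {
  tm <- params$trait_moments
  draw <- function(nm) {
    v <- stats::rnorm(1, tm[[nm]][1], tm[[nm]][2])
    round(min(tm[[nm]][4], max(tm[[nm]][3], v)))
  }
  participant_info(
    age = round(min(28, max(18, stats::rnorm(1, params$age_mean, params$age_sd)))),
    gender_code = gender_code,
    social_anxiety = draw("social_anxiety"),
    depression = draw("depression"),
    cognitive_empathy = draw("cognitive_empathy"),
    affective_empathy = draw("affective_empathy"))
}

#' Generate a synthetic dyad cohort
#'
#' Deterministic given `params` (all randomness flows from `params$seed`).
#' The first `n_disagree` dyads are generated as disagreeing dyads (opposite
#' rater offsets) so that screening tests know exactly which dyads must be
#' excluded; coder ratings are attached to the first `coder_n` dyads.
#'
#' @param params A [generator_params()] list.
#' @return A list with `sessions` (list of [dyad_session()]) and `truth`
#'   (per dyad: `latent`, `coupling_amplitude`, per-participant event ground
#'   truth, `disagree` flag).
#' @export
gen_cohort <- function(params = generator_params()) {
  set.seed(params$seed)
  intervals <- default_intervals(params$n_intervals, params$baseline_dur,
                                 params$conv_dur)
  gender_types <- list(mm = c(0L, 0L), ff = c(1L, 1L), mf = c(0L, 1L),
                       nn = c(2L, 2L))
  sessions <- vector("list", params$n_dyads)
  truth <- vector("list", params$n_dyads)
  for (d in seq_len(params$n_dyads)) {
    disagree <- d <= params$n_disagree
    eng <- gen_engagement(params, disagree = disagree)
    sig <- gen_signals(eng$latent, params)
    gt <- sample(names(gender_types), 1, prob = params$dyad_gender_probs)
    info <- lapply(gender_types[[gt]], function(g) draw_participant_info(params, g))
    coder <- NULL
    if (d <= params$coder_n) {
      coder <- round(pmin(100, pmax(0, eng$latent +
                       stats::rnorm(params$n_intervals, 0, params$coder_noise_sd))), 1)
    }
    id <- sprintf("dyad_%02d", d)
    sessions[[d]] <- dyad_session(id, sig$signals, intervals, eng$reports,
                                  info, coder_ratings = coder)
    truth[[d]] <- list(dyad_id = id, latent = eng$latent,
                       disagree = disagree,
                       coupling_amplitude = sig$truth$coupling_amplitude,
                       participants = sig$truth$participants)
  }
  list(sessions = sessions, truth = truth, params = params)
}
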