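# Shared fixtures, built once per test run and cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small default-parameter cohort with features, reused across test files
test_cohort <- function() {
  cached("cohort4", {
    coh <- gen_cohort(generator_params(n_dyads = 4, seed = 42))
    coh$features <- cohort_features(coh$sessions)
    coh
  })
}

# a minimal session with trivial signals, for report-level operations
mini_session <- function(reports1, reports2, dyad_id = "mini",
                         coder = NULL) {
  n <- length(reports1)
  iv <- default_intervals(n_conversation = n, baseline_dur = 2, conv_dur = 2)
  dur <- 2 + 2 * n
  fs <- 10
  sig <- function(ch) channel_signal(rep(1, dur * fs) + seq_len(dur * fs) * 1e-6,
                                     fs, ch)
  chans <- list(ecg = sig("ecg"), skin_conductance = sig("skin_conductance"),
                respiration = sig("respiration"),
                skin_temperature = sig("skin_temperature"))
  info <- participant_info(21, 0L, 35, 15, 55, 32)
  dyad_session(dyad_id, list(chans, chans), iv, list(reports1, reports2),
               list(info, info), coder_ratings = coder)
}

# synthetic ECG pulse train with known beat times (seconds, on the fs grid)
synth_ecg <- function(beat_times, fs = 100, dur = NULL, noise_sd = 0) {
  if (is.null(dur)) dur <- max(beat_times) + 1
  n <- round(dur * fs)
  x <- numeric(n)
  w <- round(0.02 * fs)
  pulse <- exp(-0.5 * ((-w:w) / (0.01 * fs))^2)
  for (bt in beat_times) {
    bi <- round(bt * fs) + 1L
    lo <- max(1L, bi - w); hi <- min(n, bi + w)
    x[lo:hi] <- x[lo:hi] + pulse[(lo - bi + w + 1):(hi - bi + w + 1)]
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  channel_signal(x, fs, "ecg")
}

# independently coded brute-force DTW (memoized recursion, symmetric2 steps)
dtw_brute <- function(x, y) {
  n <- length(x); m <- length(y)
  memo <- array(NA_real_, dim = c(n, m))
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    if (i == 0 || j == 0) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    c_ij <- abs(x[i] - y[j])
    v <- min(rec(i - 1, j - 1) + 2 * c_ij,
             rec(i - 1, j) + c_ij,
             rec(i, j - 1) + c_ij)
    memo[i, j] <<- v
    v
  }
  rec(n, m) / (n + m)
}
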