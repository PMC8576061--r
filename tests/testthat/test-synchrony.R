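test_that("DTW identities and warping behavior", {
  set.seed(1)
  x <- rnorm(50)
  expect_equal(dtw_distance(x, x), 0)
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 2, 3), normalize = FALSE), 0)
  expect_gt(dtw_distance(c(1, 2, 3), c(3, 2, 1), normalize = FALSE), 0)
})

test_that("DTW equals an independent brute-force recursion on short pairs", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(2:20, 1); m <- sample(2:20, 1)
    x <- rnorm(n); y <- rnorm(m)
    expect_identical(dtw_distance(x, y, normalize = FALSE), dtw_brute(x, y))
  }
})

test_that("nonlinear interdependence is 1 for identical series and discriminates coupling", {
  set.seed(3)
  x <- sin(seq(0, 20, length.out = 240)) + rnorm(240, 0, 0.1)
  expect_lt(abs(nonlinear_interdependence(x, x) - 1), 1e-6)

  # coupled pair (shared drive) always beats an independent pair
  wins <- 0L
  for (s in 1:50) {
    set.seed(100 + s)
    drive <- as.numeric(stats::filter(rnorm(260), rep(1 / 8, 8), sides = 1))
    drive[is.na(drive)] <- 0
    a <- drive[1:240] + 0.3 * rnorm(240)
    b <- drive[1:240] + 0.3 * rnorm(240)
    u <- as.numeric(stats::filter(rnorm(240), rep(1 / 8, 8), sides = 1))
    u[is.na(u)] <- 0
    coupled <- nonlinear_interdependence(a, b)
    indep <- nonlinear_interdependence(a, u)
    wins <- wins + (coupled > indep)
  }
  expect_gte(wins, 45)
})

test_that("nonlinear interdependence of white noise sits below its surrogate null", {
  set.seed(4)
  ok <- 0L
  n_trials <- 12
  for (trial in 1:n_trials) {
    x <- rnorm(240); y <- rnorm(240)
    observed <- nonlinear_interdependence(x, y)
    shifts <- round(seq(30, 210, length.out = 15))
    null_vals <- vapply(shifts, function(s) {
      ys <- c(y[(s + 1):240], y[1:s])
      nonlinear_interdependence(x, ys)
    }, numeric(1))
    ok <- ok + (observed < stats::quantile(null_vals, 0.95))
  }
  expect_gte(ok / n_trials, 0.9)
})

test_that("band coherence identities, band selectivity, and error cases", {
  set.seed(5)
  fs <- 4
  x <- rnorm(240)
  for (band in list(c(0, 2), c(0.1, 0.15), c(0.15, 0.4))) {
    expect_lt(abs(band_coherence(x, x, band, fs) - 1), 1e-9)
  }

  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  shared <- sin(2 * pi * 0.12 * t)
  a <- shared + 0.5 * rnorm(length(t))
  b <- shared + 0.5 * rnorm(length(t))
  expect_gt(band_coherence(a, b, c(0.1, 0.15), fs),
            band_coherence(a, b, c(0.15, 0.4), fs))

  expect_error(band_coherence(x, x, c(0, 3), fs), "Nyquist")
})

test_that("independent-noise coherence sits below a phase-randomized surrogate null", {
  set.seed(6)
  fs <- 4
  phase_surrogate <- function(y) {
    n <- length(y)
    Y <- stats::fft(y)
    half <- 2:ceiling(n / 2)
    ph <- runif(length(half), 0, 2 * pi)
    Y[half] <- Mod(Y[half]) * exp(1i * ph)
    Y[n + 2 - half] <- Conj(Y[half])
    Re(stats::fft(Y, inverse = TRUE)) / n
  }
  ok <- 0L
  n_trials <- 12
  for (trial in 1:n_trials) {
    x <- rnorm(240); y <- rnorm(240)
    obs <- band_coherence(x, y, c(0.1, 0.5), fs)
    null_vals <- replicate(19, band_coherence(x, phase_surrogate(y), c(0.1, 0.5), fs))
    ok <- ok + (obs < stats::quantile(null_vals, 0.95))
  }
  expect_gte(ok / n_trials, 0.9)
})

test_that("cross-correlation is Pearson at zero lag with affine invariance", {
  set.seed(7)
  x <- rnorm(100)
  expect_equal(cross_correlation(x, x), 1)
  expect_equal(cross_correlation(x, -x), -1)
  expect_equal(cross_correlation(x, 2 * x + 3), 1)
  expect_error(cross_correlation(x, rep(1, 100)), "variance")
})

test_that("the 17-feature synchrony vector behaves on identical, independent and swapped input", {
  set.seed(8)
  mk <- function() list(hr = 70 + rnorm(240), resp = 15 + rnorm(240),
                        sc = 5 + cumsum(rnorm(240, 0, 0.02)),
                        temp = 32 + cumsum(rnorm(240, 0, 0.005)))
  a <- mk()
  same <- extract_synchrony(list(a, a))
  expect_length(same, 17)
  expect_true(all(same[startsWith(names(same), "dtw_")] == 0))
  expect_true(all(abs(same[startsWith(names(same), "xcorr_")] - 1) < 1e-12))
  expect_true(all(abs(same[startsWith(names(same), "coh_")] - 1) < 1e-9))
  expect_true(all(abs(same[startsWith(names(same), "nli_")] - 1) < 1e-6))

  b <- mk()
  ab <- extract_synchrony(list(a, b))
  ba <- extract_synchrony(list(b, a))
  expect_equal(ab, ba, tolerance = 1e-12)
  expect_true(all(ab[startsWith(names(ab), "coh_")] >= 0 &
                    ab[startsWith(names(ab), "coh_")] <= 1))
  expect_true(all(abs(ab[startsWith(names(ab), "xcorr_")]) <= 1))
  expect_true(all(ab[startsWith(names(ab), "dtw_")] >= 0))

  xc <- replicate(100, abs(cross_correlation(rnorm(240), rnorm(240))))
  expect_lt(median(xc), 0.2)
})

test_that("generator coupling does not decrease respiration coherence or HR correlation", {
  med_sync <- function(coupling, seed) {
    p <- generator_params(n_dyads = 1, seed = seed, coupling = coupling)
    set.seed(seed)
    eng <- gen_engagement(p)
    sig <- gen_signals(eng$latent, p)
    tr <- sig$truth$participants
    fs_out <- 4
    vals <- vapply(seq_len(p$n_intervals), function(i) {
      lo <- p$baseline_dur + (i - 1) * p$conv_dur
      hi <- lo + p$conv_dur
      subs <- lapply(1:2, function(pp) {
        hr_ev <- event_series(tr[[pp]]$beat_times, "r_wave")
        re_ev <- event_series(tr[[pp]]$breath_times, "breath")
        grid <- seq(lo, hi - 1 / fs_out, by = 1 / fs_out)
        rate_on <- function(ev) {
          t <- ev$times; ibi <- diff(t)
          stats::approx(t[-length(t)] + ibi / 2, 60 / ibi, xout = grid, rule = 2)$y
        }
        list(hr = rate_on(hr_ev), resp = rate_on(re_ev))
      })
      c(band_coherence(subs[[1]]$resp, subs[[2]]$resp, c(0, 2), fs_out),
        cross_correlation(subs[[1]]$hr, subs[[2]]$hr))
    }, numeric(2))
    c(coh = median(vals[1, ]), xcorr = median(vals[2, ]))
  }
  seeds <- 301:305
  res <- lapply(c(0, 2), function(k) {
    rowMeans(vapply(seeds, function(s) med_sync(k, s), numeric(2)))
  })
  expect_gt(res[[2]][["coh"]], res[[1]][["coh"]])
  expect_gt(res[[2]][["xcorr"]], res[[1]][["xcorr"]])
})
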