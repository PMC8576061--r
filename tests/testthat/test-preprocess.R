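test_that("lowpass is identity in the deep passband and attenuates the stopband", {
  fs <- 100
  t <- seq(0, 30, by = 1 / fs)
  dc <- channel_signal(rep(3.5, length(t)), fs, "skin_conductance")
  expect_lt(max(abs(lowpass(dc)$samples - 3.5)), 1e-9)

  slow <- channel_signal(sin(2 * pi * 0.1 * t), fs, "skin_conductance")
  y <- lowpass(slow)$samples
  mid <- 500:2500
  expect_lt(max(abs(y[mid] - slow$samples[mid])), 0.01)

  fast <- channel_signal(sin(2 * pi * 20 * t), fs, "skin_conductance")
  yf <- lowpass(fast)$samples
  expect_lt(sqrt(mean(yf[mid]^2)) / sqrt(mean(fast$samples[mid]^2)), 0.05)

  expect_error(lowpass(channel_signal(t, 8, "respiration"), cutoff_hz = 5),
               "Nyquist")
})

test_that("zero-phase filtering introduces no lag", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 0.5 * t)
  y <- lowpass(channel_signal(x, fs, "respiration"), 5)$samples
  cc <- stats::ccf(y, x, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("R-wave detection recovers pulse trains, handles flat input, tolerates noise", {
  beats <- seq(0.5, 59.5, by = 1)   # 60 bpm for 60 s
  ecg <- synth_ecg(beats, fs = 100, dur = 60)
  ev <- detect_r_waves(ecg)
  expect_true(abs(length(ev$times) - 60) <= 1)

  flat <- channel_signal(rep(0.3, 1000), 100, "ecg")
  expect_warning(ev0 <- detect_r_waves(flat), "No detectable")
  expect_length(ev0$times, 0)

  # additive noise at 10 dB SNR relative to the pulse-train power
  set.seed(7)
  clean <- synth_ecg(beats, fs = 100, dur = 60)
  p_sig <- mean(clean$samples^2)
  noisy <- channel_signal(clean$samples + rnorm(length(clean$samples),
                                                sd = sqrt(p_sig / 10)),
                          100, "ecg")
  evn <- detect_r_waves(noisy)
  matched <- vapply(beats, function(b) any(abs(evn$times - b) <= 0.05), logical(1))
  expect_gte(mean(matched), 0.99)
})

test_that("repair_beats inserts midpoints for single missed beats and restores deletions", {
  ev <- event_series(c(0, 1, 2, 4, 5), "r_wave")
  rep1 <- repair_beats(ev)
  expect_equal(rep1$times, c(0, 1, 2, 3, 4, 5))
  expect_identical(rep1$interpolated, c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))

  clean <- event_series(0:59, "r_wave")
  expect_equal(repair_beats(clean)$times, as.numeric(0:59))
  expect_equal(sum(repair_beats(clean)$interpolated), 0)

  # 2% random deletions from a long, slightly irregular train
  set.seed(11)
  ibis <- 0.9 + 0.1 * runif(1500)
  t_true <- cumsum(ibis)
  del <- sort(sample(seq(5, length(t_true) - 5), round(0.02 * length(t_true))))
  del <- del[c(TRUE, diff(del) > 1)]  # single (not consecutive) deletions
  rep2 <- repair_beats(event_series(t_true[-del], "r_wave"))
  restored <- vapply(t_true[del], function(tt) {
    ins <- rep2$times[rep2$interpolated]
    any(abs(ins - tt) <= 0.1 * 1.0)
  }, logical(1))
  expect_gte(mean(restored), 0.95)
})

test_that("breath detection counts cycles, including under frequency drift", {
  fs <- 25
  t <- seq(0, 60, by = 1 / fs)
  resp <- channel_signal(sin(2 * pi * 0.25 * t), fs, "respiration")
  expect_equal(length(detect_breaths(resp)$times), 15)

  expect_length(detect_breaths(channel_signal(rep(1, 600), 10, "respiration"))$times, 0)

  # linear chirp 0.2 -> 0.4 Hz: cycle count = integral of f(t) dt = 18
  f0 <- 0.2; f1 <- 0.4
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * 60))
  chirp <- channel_signal(sin(phase), fs, "respiration")
  n_expected <- (f0 + f1) / 2 * 60
  expect_lte(abs(length(detect_breaths(chirp)$times) - n_expected), 1)
})

test_that("SCR detection honors the amplitude and rise-time rules exactly", {
  fs <- 20
  base <- rep(5, 20 * fs)
  add_ramp <- function(x, at_s, amp, rise_s) {
    i0 <- at_s * fs + 1
    n_r <- rise_s * fs
    x[i0:(i0 + n_r)] <- x[i0:(i0 + n_r)] + amp * seq(0, 1, length.out = n_r + 1)
    if (i0 + n_r < length(x)) {
      x[(i0 + n_r + 1):length(x)] <- x[(i0 + n_r + 1):length(x)] + amp
    }
    x
  }
  x <- base
  for (at in c(2, 8, 14)) x <- add_ramp(x, at, 0.10, 2)
  scrs <- detect_scrs(channel_signal(x, fs, "skin_conductance"))
  expect_equal(nrow(scrs), 3)
  expect_equal(mean(scrs$amplitude), 0.10, tolerance = 1e-9)
  expect_equal(scrs$peak_s - scrs$onset_s, rep(2, 3))

  low <- add_ramp(base, 5, 0.049, 2)
  expect_equal(nrow(detect_scrs(channel_signal(low, fs, "skin_conductance"))), 0)
  at_thr <- add_ramp(base, 5, 0.050, 2)
  expect_equal(nrow(detect_scrs(channel_signal(at_thr, fs, "skin_conductance"))), 1)

  slow <- add_ramp(base, 5, 0.2, 6)
  expect_equal(nrow(detect_scrs(channel_signal(slow, fs, "skin_conductance"))), 0)
})

test_that("SCR outputs always satisfy the threshold rules on random inputs", {
  set.seed(3)
  for (i in 1:20) {
    x <- cumsum(rnorm(2000, 0, 0.01)) + 5
    scrs <- detect_scrs(channel_signal(x, 20, "skin_conductance"))
    if (nrow(scrs)) {
      expect_true(all(scrs$amplitude >= 0.05))
      expect_true(all(scrs$peak_s - scrs$onset_s < 5))
    }
  }
})

test_that("instantaneous rate reproduces periodic trains and bounded interpolation", {
  ev1 <- event_series(seq(0, 30, by = 1), "r_wave")
  r1 <- instantaneous_rate(ev1)
  expect_lt(max(abs(r1$values - 60)), 1e-9)

  ev2 <- event_series(seq(0, 30, by = 0.5), "r_wave")
  expect_lt(max(abs(instantaneous_rate(ev2)$values - 120)), 1e-9)

  ibis <- rep(c(0.9, 1.1), 30)
  ev3 <- event_series(cumsum(c(0, ibis)), "r_wave")
  r3 <- instantaneous_rate(ev3)
  expect_true(all(r3$values >= 60 / 1.1 - 1e-9))
  expect_true(all(r3$values <= 60 / 0.9 + 1e-9))
  expect_gt(mean(r3$values), 59)
  expect_lt(mean(r3$values), 61)

  expect_error(instantaneous_rate(event_series(1, "r_wave")), ">= 2 events")
})
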