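#' @useDynLib dyadsync, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# z-normalize a series; constant series map to all zeros
znorm <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Dynamic time warping distance
#'
#' Classic DTW with absolute-difference local cost and the symmetric step
#' pattern whose diagonal step is weighted twice (so the accumulated cost is
#' normalizable); the returned distance is the accumulated cost divided by
#' `length(x) + length(y)`. Both series are z-normalized before alignment by
#' default so that amplitude-scale differences between participants do not
#' dominate shape similarity.
#'
#' @param x,y Numeric series of length >= 2 at a common sampling rate.
#' @param normalize Z-normalize before alignment (default TRUE).
#' @return Non-negative distance; 0 for identical (post-normalization)
#'   series.
#' @export
dtw_distance <- function(x, y, normalize = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("DTW needs series of length >= 2.", call. = FALSE)
  }
  if (normalize) {
    x <- znorm(x); y <- znorm(y)
  }
  .dtw_cost(x, y) / (length(x) + length(y))
}

# time-delay embedding: rows are embedded points
embed_delay <- function(x, m, tau) {
  n_pts <- length(x) - (m - 1) * tau
  if (n_pts < 1L) stop("Series too short for embedding.", call. = FALSE)
  idx <- outer(seq_len(n_pts) - 1L, (0:(m - 1)) * tau, "+") + 1L
  matrix(x[idx], nrow = n_pts)
}

#' Nonlinear interdependence between two series
#'
#' State-space similarity statistic: both series are time-delay embedded
#' (dimension `m`, delay `tau`); for each embedded point the mean squared
#' distance to its `k` nearest neighbors in its own trajectory,
#' \eqn{R_n^{(k)}(X)}, is compared with the mean squared distance to the
#' points of X at the *time indices* of the corresponding point's neighbors
#' in Y, \eqn{R_n^{(k)}(X|Y)}. The directed measure is
#' \eqn{S(X|Y) = \frac{1}{N}\sum_n R_n^{(k)}(X) / R_n^{(k)}(X|Y)} and the
#' returned value is the symmetrized mean of \eqn{S(X|Y)} and \eqn{S(Y|X)},
#' in (0, 1]: identical dynamics give 1, independent dynamics values near
#' k / N. Temporally adjacent points (|index difference| <= `theiler`) are
#' excluded as neighbor candidates to suppress autocorrelation artifacts.
#'
#' @param x,y Numeric series of equal length, z-normalized internally.
#' @param m Embedding dimension (default 3).
#' @param tau Embedding delay in samples (default 2, i.e. 0.5 s at 4 Hz).
#' @param k Number of nearest neighbors (default 4).
#' @param theiler Theiler exclusion window in samples (default 8).
#' @return Symmetrized interdependence in (0, 1].
#' @export
nonlinear_interdependence <- function(x, y, m = 3, tau = 2, k = 4, theiler = 8) {
  x <- znorm(as.numeric(x)); y <- znorm(as.numeric(y))
  if (length(x) != length(y)) stop("Series must have equal length.", call. = FALSE)
  X <- embed_delay(x, m, tau)
  Y <- embed_delay(y, m, tau)
  n <- nrow(X)
  if (n < 2 * k + theiler + 1) {
    stop("Series too short for the requested embedding/neighborhood.",
         call. = FALSE)
  }
  dX <- as.matrix(stats::dist(X))^2
  dY <- as.matrix(stats::dist(Y))^2
  idx_diff <- abs(outer(seq_len(n), seq_len(n), "-"))
  excl <- idx_diff <= theiler  # includes self
  dXe <- dX; dXe[excl] <- Inf
  dYe <- dY; dYe[excl] <- Inf
  s_directed <- function(dSelf, dSelfExcl, dOtherExcl) {
    ratios <- vapply(seq_len(n), function(i) {
      nn_self <- order(dSelfExcl[i, ])[seq_len(k)]
      nn_other <- order(dOtherExcl[i, ])[seq_len(k)]
      r_self <- mean(dSelf[i, nn_self])
      r_cond <- mean(dSelf[i, nn_other])
      if (r_cond < 1e-300) 1 else r_self / r_cond
    }, numeric(1))
    mean(pmin(ratios, 1))
  }
  (s_directed(dX, dXe, dYe) + s_directed(dY, dYe, dXe)) / 2
}

#' Band-averaged magnitude-squared coherence (Welch)
#'
#' Welch estimate of magnitude-squared coherence
#' \eqn{C_{xy}(f) = |P_{xy}(f)|^2 / (P_{xx}(f) P_{yy}(f))}, averaged over
#' the frequency bins inside `band`. Segments (default 30 s, 50% overlap)
#' are mean-detrended and Hann-windowed. The DC bin is excluded from band
#' averages because detrending makes it meaningless. With the defaults a
#' 60-s interval yields 3 segments and a 1/30 Hz bin spacing — coarse but
#' sufficient for the narrow 0.1–0.15 Hz heart-rate band.
#'
#' @param x,y Numeric series of equal length sampled at `fs`.
#' @param band Length-2 numeric `c(f_lo, f_hi)` in Hz, within (0, fs/2\].
#' @param fs Sampling rate in Hz.
#' @param window_s Welch segment length in seconds (default 30).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return Band-averaged coherence in \[0, 1\].
#' @export
band_coherence <- function(x, y, band, fs, window_s = 30, overlap = 0.5) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("Series must have equal length.", call. = FALSE)
  if (band[2] > fs / 2 + 1e-12) {
    stop(sprintf("Band upper edge %g Hz exceeds Nyquist (%g Hz).",
                 band[2], fs / 2), call. = FALSE)
  }
  nper <- round(window_s * fs)
  if (nper > length(x)) nper <- length(x)
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  if (length(starts) < 2L) {
    # a single segment gives coherence identically 1; require >= 2 by
    # shrinking the window if the series is short
    nper <- floor(length(x) / 2)
    step <- max(1L, round(nper * (1 - overlap)))
    starts <- seq(1L, length(x) - nper + 1L, by = step)
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))  # Hann
  pxx <- pyy <- numeric(nper)
  pxy <- complex(real = numeric(nper), imaginary = numeric(nper))
  for (s0 in starts) {
    xs <- x[s0:(s0 + nper - 1L)]; ys <- y[s0:(s0 + nper - 1L)]
    X <- stats::fft((xs - mean(xs)) * w)
    Y <- stats::fft((ys - mean(ys)) * w)
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  freqs <- (seq_len(nper) - 1) * fs / nper
  half <- seq_len(floor(nper / 2) + 1L)
  in_band <- freqs[half] >= band[1] & freqs[half] <= band[2] & freqs[half] > 0
  if (!any(in_band)) {
    stop("No frequency bins inside the requested band.", call. = FALSE)
  }
  coh <- Mod(pxy[half])^2 / (pxx[half] * pyy[half])
  coh[!is.finite(coh)] <- 0
  mean(coh[in_band])
}

#' Zero-lag cross-correlation
#'
#' Pearson correlation between the two participants' series at lag zero. No
#' lag search is performed: the statistic is intentionally the simplest
#' synchrony measure and is known to be vulnerable to temporal delays.
#'
#' @param x,y Numeric series of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
cross_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("Need equal-length series of length >= 3.", call. = FALSE)
  }
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    stop("Zero-variance series: correlation undefined.", call. = FALSE)
  }
  stats::cor(x, y)
}

SYNCHRONY_FEATURES <- c(
  "dtw_hr", "dtw_resp", "dtw_sc", "dtw_temp",
  "nli_hr", "nli_resp", "nli_sc", "nli_temp",
  "coh_resp_0_2", "coh_hr_0.1_0.15", "coh_hr_0.15_0.4", "coh_sc", "coh_temp",
  "xcorr_hr", "xcorr_resp", "xcorr_sc", "xcorr_temp")

#' Default coherence bands per substrate
#'
#' Respiration 0–2 Hz; heart rate 0.1–0.15 Hz and 0.15–0.4 Hz; skin
#' conductance 0–0.5 Hz and skin temperature 0–0.1 Hz (tonic dynamics; no
#' published band exists for these two channels, so the choices are exposed
#' here and configurable everywhere they are used).
#'
#' @return Named list of `c(f_lo, f_hi)` bands in Hz.
#' @export
default_coherence_bands <- function() {
  list(resp = c(0, 2), hr_low = c(0.1, 0.15), hr_high = c(0.15, 0.4),
       sc = c(0, 0.5), temp = c(0, 0.1))
}

#' Synchrony features for one interval
#'
#' Applies the four synchrony metrics to the four substrate pairs
#' (instantaneous heart rate, instantaneous respiration rate, skin
#' conductance, skin temperature), all sampled at a common rate. DTW and
#' nonlinear interdependence run on z-normalized series; coherence uses the
#' per-substrate bands from [default_coherence_bands()] (heart rate gets two
#' bands), giving 17 features in total. All 17 are symmetric under swapping
#' the participants.
#'
#' @param substrates List of two lists (one per participant), each with
#'   numeric vectors `hr`, `resp`, `sc`, `temp` of equal length.
#' @param fs Common substrate sampling rate in Hz (default 4).
#' @param bands Coherence bands (default [default_coherence_bands()]).
#' @param nli_params List of nonlinear-interdependence parameters `m`, `tau`,
#'   `k`, `theiler`.
#' @return Named numeric vector of the 17 synchrony features.
#' @export
extract_synchrony <- function(substrates, fs = 4,
                              bands = default_coherence_bands(),
                              nli_params = list(m = 3, tau = 2, k = 4, theiler = 8)) {
  a <- substrates[[1]]; b <- substrates[[2]]
  stopifnot(all(c("hr", "resp", "sc", "temp") %in% names(a)),
            all(c("hr", "resp", "sc", "temp") %in% names(b)))
  out <- numeric(0)
  wrap <- function(feature, expr) {
    val <- tryCatch(expr, error = function(e) {
      stop("Synchrony feature '", feature, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    out[[feature]] <<- val
  }
  for (ch in c("hr", "resp", "sc", "temp")) {
    wrap(paste0("dtw_", ch), dtw_distance(a[[ch]], b[[ch]]))
    wrap(paste0("nli_", ch),
         nonlinear_interdependence(a[[ch]], b[[ch]], m = nli_params$m,
                                   tau = nli_params$tau, k = nli_params$k,
                                   theiler = nli_params$theiler))
  }
  wrap("coh_resp_0_2", band_coherence(a$resp, b$resp, bands$resp, fs))
  wrap("coh_hr_0.1_0.15", band_coherence(a$hr, b$hr, bands$hr_low, fs))
  wrap("coh_hr_0.15_0.4", band_coherence(a$hr, b$hr, bands$hr_high, fs))
  wrap("coh_sc", band_coherence(a$sc, b$sc, bands$sc, fs))
  wrap("coh_temp", band_coherence(a$temp, b$temp, bands$temp, fs))
  for (ch in c("hr", "resp", "sc", "temp")) {
    wrap(paste0("xcorr_", ch), cross_correlation(a[[ch]], b[[ch]]))
  }
  out[SYNCHRONY_FEATURES]
}
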