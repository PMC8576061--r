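#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' Single-rater, absolute-agreement ICC from a one-way random-effects ANOVA
#' over row effects:
#' \deqn{ICC(1,1) = \frac{MS_B - MS_W}{MS_B + (k - 1) MS_W}}
#' with `k` raters per row (here k = 2). Rows are rating targets (here each
#' dyad-interval, pooled over dyads); columns are the two raters. Negative
#' values are reported as computed.
#'
#' @param ratings Numeric matrix or data frame, rows = targets, 2 columns =
#'   raters; >= 2 rows.
#' @return The ICC(1,1) estimate.
#' @export
icc_oneway <- function(ratings) {
  m <- as.matrix(ratings)
  if (nrow(m) < 2L || ncol(m) != 2L) {
    stop("Need an n x 2 rating matrix with n >= 2.", call. = FALSE)
  }
  if (stats::var(as.vector(m)) < 1e-24) {
    stop("Zero total variance: ICC undefined.", call. = FALSE)
  }
  n <- nrow(m); k <- ncol(m)
  row_means <- rowMeans(m)
  grand <- mean(m)
  ss_between <- k * sum((row_means - grand)^2)
  ss_within <- sum((m - row_means)^2)
  ms_between <- ss_between / (n - 1)
  ms_within <- ss_within / (n * (k - 1))
  (ms_between - ms_within) / (ms_between + (k - 1) * ms_within)
}

#' External-coder error per dyad
#'
#' Computes the same RMS and MA errors used for the estimators, but between
#' the external coder's per-interval ratings and the reference (mean
#' self-reported) engagement. Dyads without coder ratings are skipped and
#' counted.
#'
#' @param sessions List of [dyad_session()] objects.
#' @return A list: `per_dyad` tibble (`dyad_id`, `rms_error`, `ma_error`),
#'   `summary` (median/quartiles across dyads with coder data), `n_skipped`.
#' @export
coder_errors <- function(sessions) {
  have <- purrr::keep(sessions, ~ !is.null(.x$coder_ratings))
  per_dyad <- purrr::map_dfr(have, function(s) {
    e <- rms_ma_errors(s$coder_ratings, dyad_engagement(s))
    tibble::tibble(dyad_id = s$dyad_id, rms_error = e[["rms"]],
                   ma_error = e[["ma"]])
  })
  summary <- if (nrow(per_dyad)) tibble::tibble(
    n_dyads = nrow(per_dyad),
    rms_median = stats::median(per_dyad$rms_error),
    rms_p25 = stats::quantile(per_dyad$rms_error, 0.25, names = FALSE),
    rms_p75 = stats::quantile(per_dyad$rms_error, 0.75, names = FALSE),
    ma_median = stats::median(per_dyad$ma_error),
    ma_p25 = stats::quantile(per_dyad$ma_error, 0.25, names = FALSE),
    ma_p75 = stats::quantile(per_dyad$ma_error, 0.75, names = FALSE)
  ) else tibble::tibble()
  list(per_dyad = per_dyad, summary = summary,
       n_skipped = length(sessions) - nrow(per_dyad))
}

#' Per-dyad trait summaries
#'
#' For each of the four traits, the mean across the two dyad members and the
#' absolute within-dyad difference.
#'
#' @param sessions List of [dyad_session()] objects.
#' @return A tibble with `dyad_id` and `<trait>_mean` / `<trait>_diff`
#'   columns for social_anxiety, depression, cognitive_empathy,
#'   affective_empathy.
#' @export
trait_summary <- function(sessions) {
  traits <- c("social_anxiety", "depression", "cognitive_empathy",
              "affective_empathy")
  purrr::map_dfr(sessions, function(s) {
    row <- list(dyad_id = s$dyad_id)
    for (tr in traits) {
      v1 <- s$info[[1]][[tr]]; v2 <- s$info[[2]][[tr]]
      row[[paste0(tr, "_mean")]] <- (v1 + v2) / 2
      row[[paste0(tr, "_diff")]] <- abs(v1 - v2)
    }
    tibble::as_tibble(row)
  })
}

#' Spearman correlations between trait summaries and estimation errors
#'
#' For each of the 8 trait statistics (4 traits x mean/diff) and each error
#' metric (RMS, MA), the Spearman rank correlation and its two-sided p-value
#' across dyads (midranks for ties; p-values uncorrected, as is conventional
#' for this descriptive table — note that 16 tests are run simultaneously).
#' Optionally also correlates trait statistics with each dyad's median
#' engagement and engagement range (a confound check).
#'
#' @param traits Tibble from [trait_summary()].
#' @param errors Tibble with `dyad_id`, `rms_error`, `ma_error` (e.g.
#'   `tidy()` of an `estimation_result`).
#' @param engagement Optional tibble with `dyad_id`, `median_engagement`,
#'   `engagement_range`.
#' @return A tibble `trait_stat`, `outcome`, `rho`, `p_value`; `rho` is `NA`
#'   when an input column is constant.
#' @export
trait_error_correlations <- function(traits, errors, engagement = NULL) {
  df <- dplyr::inner_join(traits, errors, by = "dyad_id")
  if (nrow(df) < 5L) stop("Need >= 5 dyads for trait correlations.", call. = FALSE)
  outcomes <- list(rms_error = df$rms_error, ma_error = df$ma_error)
  if (!is.null(engagement)) {
    df2 <- dplyr::inner_join(df, engagement, by = "dyad_id")
    outcomes$median_engagement <- df2$median_engagement
    outcomes$engagement_range <- df2$engagement_range
  }
  stat_cols <- setdiff(names(traits), "dyad_id")
  purrr::map_dfr(stat_cols, function(sc) {
    purrr::map_dfr(names(outcomes), function(oc) {
      x <- df[[sc]]; y <- outcomes[[oc]]
      if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
        return(tibble::tibble(trait_stat = sc, outcome = oc,
                              rho = NA_real_, p_value = NA_real_))
      }
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      tibble::tibble(trait_stat = sc, outcome = oc,
                     rho = unname(ct$estimate), p_value = ct$p.value)
    })
  })
}

#' Median (p25-p75) summary
#'
#' The reporting convention used throughout: sample median with 25th and
#' 75th percentiles, quartiles by linear interpolation between order
#' statistics (R quantile type 7).
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `median`, `p25`, `p75`.
#' @export
summarize_iqr <- function(values) {
  stopifnot(length(values) >= 1L)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], p25 = q[2], p75 = q[3])
}

#' Cohort-level engagement agreement statistics
#'
#' Pools all conversation intervals across dyads and reports the descriptive
#' statistics used to characterize rating agreement: median (IQR) of
#' reference engagement, of the within-dyad engagement range, and of the
#' between-rater absolute difference, plus the one-way random-effects
#' ICC(1,1) of the two raters.
#'
#' @param sessions List of [dyad_session()] objects.
#' @return A one-row tibble with `engagement_median`, `engagement_p25/p75`,
#'   `range_median`, `absdiff_median`, `absdiff_p25/p75`, `icc`.
#' @export
cohort_agreement <- function(sessions) {
  eng <- unlist(lapply(sessions, dyad_engagement))
  absdiff <- unlist(lapply(sessions, function(s) {
    abs(s$self_reports[[1]] - s$self_reports[[2]])
  }))
  rng <- vapply(sessions, function(s) {
    e <- dyad_engagement(s); max(e) - min(e)
  }, numeric(1))
  ratings <- do.call(rbind, lapply(sessions, function(s) {
    cbind(s$self_reports[[1]], s$self_reports[[2]])
  }))
  e_q <- summarize_iqr(eng); d_q <- summarize_iqr(absdiff); r_q <- summarize_iqr(rng)
  tibble::tibble(
    engagement_median = e_q[["median"]], engagement_p25 = e_q[["p25"]],
    engagement_p75 = e_q[["p75"]],
    range_median = r_q[["median"]],
    absdiff_median = d_q[["median"]], absdiff_p25 = d_q[["p25"]],
    absdiff_p75 = d_q[["p75"]],
    icc = icc_oneway(ratings))
}
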