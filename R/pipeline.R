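#' Run configuration
#'
#' Gathers every tunable of the pipeline with its default: interval/feature
#' parameters (substrate rate, coherence bands, SCR thresholds,
#' nonlinear-interdependence embedding), the dyad-screening threshold,
#' estimation modes/methods and ablation flags, and the root seed from which
#' all randomness flows.
#'
#' @param seed Root seed (default 1).
#' @param modes Estimation modes to run: subset of `c("loio", "ldo")`.
#' @param methods Estimators: subset of
#'   `c("tree", "boost", "forest", "median_baseline")`.
#' @param use_sync,use_chars Ablation flags passed to the estimators.
#' @param fs_out Synchrony substrate rate, Hz.
#' @param bands Coherence bands; see [default_coherence_bands()].
#' @param scr_min_amp,scr_max_rise SCR detection thresholds (microsiemens,
#'   seconds).
#' @param screen_threshold Dyad-screening threshold on the median
#'   between-rater absolute difference.
#' @param nli_params Nonlinear-interdependence parameters.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, modes = c("loio", "ldo"),
                       methods = c("forest", "tree", "boost", "median_baseline"),
                       use_sync = TRUE, use_chars = TRUE, fs_out = 4,
                       bands = default_coherence_bands(),
                       scr_min_amp = 0.05, scr_max_rise = 5,
                       screen_threshold = 30,
                       nli_params = list(m = 3, tau = 2, k = 4, theiler = 8)) {
  structure(list(seed = as.integer(seed), modes = modes, methods = methods,
                 use_sync = use_sync, use_chars = use_chars, fs_out = fs_out,
                 bands = bands, scr_min_amp = scr_min_amp,
                 scr_max_rise = scr_max_rise,
                 screen_threshold = screen_threshold,
                 nli_params = nli_params),
            class = "run_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' Validation and screening, preprocessing, feature extraction, crossvalidated
#' engagement estimation for every requested mode/method combination, and the
#' descriptive statistics, as one reproducible call. Deterministic given the
#' sessions and the config.
#'
#' @param sessions List of [dyad_session()] objects (or a `gen_cohort()`
#'   result, whose `$sessions` is used).
#' @param config A [run_config()].
#' @return A list of class `pipeline_result`: `screen` (screening report),
#'   `features` (cohort feature table), `results` (named list of
#'   `estimation_result`s, names `<mode>_<method>`), `agreement`
#'   (cohort agreement statistics incl. ICC), `coder` (external-coder
#'   errors), `importance` (leave-dyad-out forest predictor importance, when
#'   available), and `config`.
#' @export
run_pipeline <- function(sessions, config = run_config()) {
  if (!is.null(sessions$sessions)) sessions <- sessions$sessions
  stopifnot(length(sessions) >= 1L, inherits(config, "run_config"))
  screen <- screen_dyads(sessions, config$screen_threshold)
  kept <- screen$kept
  features <- cohort_features(kept, fs_out = config$fs_out,
                              bands = config$bands)
  if (!config$use_sync) {
    features <- features[, setdiff(names(features), synchrony_feature_names())]
  }
  results <- list()
  for (mode in config$modes) {
    for (method in config$methods) {
      key <- paste(mode, method, sep = "_")
      if (mode == "loio") {
        per_dyad <- lapply(unique(features$dyad_id), function(d) {
          loio_cv(features[features$dyad_id == d, , drop = FALSE],
                  method = method, use_sync = config$use_sync,
                  seed = config$seed)
        })
        preds <- dplyr::bind_rows(lapply(per_dyad, function(r) r$predictions))
        results[[key]] <- new_estimation_result(preds, "loio", method)
      } else {
        results[[key]] <- ldo_cv(features, method = method,
                                 use_sync = config$use_sync,
                                 use_chars = config$use_chars,
                                 seed = config$seed)
      }
    }
  }
  importance <- NULL
  if ("ldo_forest" %in% names(results) &&
      length(results$ldo_forest$models)) {
    importance <- predictor_importance(results$ldo_forest)
  }
  structure(list(screen = screen$stats, features = features,
                 results = results, agreement = cohort_agreement(kept),
                 coder = coder_errors(kept), importance = importance,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d dyads kept (%d screened out)\n",
              sum(!x$screen$excluded), sum(x$screen$excluded)))
  cat(sprintf("  agreement: engagement %.1f (%.1f-%.1f), |diff| %.1f, ICC %.2f\n",
              x$agreement$engagement_median, x$agreement$engagement_p25,
              x$agreement$engagement_p75, x$agreement$absdiff_median,
              x$agreement$icc))
  for (r in x$results) print(r)
  invisible(x)
}

#' Method-comparison summary of a pipeline result
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return A tibble with one row per (mode, method): median and quartiles of
#'   per-dyad RMS and MA errors.
#' @export
tidy.pipeline_result <- function(x, ...) {
  dplyr::bind_rows(lapply(x$results, function(r) r$summary))
}
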