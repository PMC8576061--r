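#' RMS and mean-absolute error
#'
#' @param pred,ref Equal-length numeric vectors of predicted and reference
#'   engagement.
#' @return Named numeric vector `rms`, `ma`. RMS >= MA always.
#' @export
rms_ma_errors <- function(pred, ref) {
  if (length(pred) != length(ref) || length(pred) < 1L) {
    stop("Need equal-length, non-empty prediction and reference vectors.",
         call. = FALSE)
  }
  r <- pred - ref
  c(rms = sqrt(mean(r^2)), ma = mean(abs(r)))
}

#' Median baselines
#'
#' Non-physiological reference estimators: the interval-wise baseline
#' predicts the held-out interval as the median reference engagement of the
#' dyad's other intervals; the dyad-wise baseline predicts every interval of
#' a held-out dyad as the median reference engagement pooled over all other
#' dyads' intervals. Medians use the standard convention (mean of the middle
#' two for even counts).
#'
#' @param train_refs Numeric vector of training reference engagements.
#' @return The median engagement.
#' @export
median_baseline_interval <- function(train_refs) {
  stopifnot(length(train_refs) >= 1L)
  stats::median(train_refs)
}

#' @rdname median_baseline_interval
#' @export
median_baseline_dyad <- function(train_refs) {
  stopifnot(length(train_refs) >= 1L)
  stats::median(train_refs)
}

#' Baseline-normalize a feature table
#'
#' Subtracts each dyad's resting-baseline feature value from that dyad's
#' conversation-interval values, for every physiological feature column
#' (individual and synchrony). Characteristic columns and the reference
#' engagement are untouched. Reduces between-dyad physiological offsets for
#' dyad-non-specific estimation. The operation is not idempotent; the
#' returned table carries attribute `baseline_normalized = TRUE` and calling
#' it twice raises an error.
#'
#' @param table A cohort feature table with one `interval == 0` baseline row
#'   per dyad (see [cohort_features()]).
#' @return The normalized table (baseline rows become all-zero features).
#' @export
baseline_normalize <- function(table) {
  if (isTRUE(attr(table, "baseline_normalized"))) {
    stop("Feature table is already baseline-normalized.", call. = FALSE)
  }
  feat_cols <- intersect(c(individual_feature_names(), synchrony_feature_names()),
                         names(table))
  out <- dplyr::group_modify(dplyr::group_by(table, .data$dyad_id),
                             function(df, key) {
    base <- df[df$interval == 0L, , drop = FALSE]
    if (nrow(base) != 1L) {
      stop("Dyad ", key$dyad_id, " lacks a baseline row (interval == 0).",
           call. = FALSE)
    }
    for (fc in feat_cols) df[[fc]] <- df[[fc]] - base[[fc]]
    df
  })
  out <- dplyr::ungroup(out)
  out <- dplyr::relocate(out, "dyad_id")
  attr(out, "baseline_normalized") <- TRUE
  out
}

#' Fit a tree-based engagement regressor
#'
#' The three estimators are a single CART regression tree (rpart, min leaf
#' size 3), stagewise least-squares gradient boosting of shallow trees
#' (xgboost, 100 rounds, depth 2, learning rate 0.1, squared-error loss),
#' and a random forest (randomForest, 100 trees). All are deterministic
#' given `seed`. A degenerate constant response yields a constant predictor.
#'
#' @param X Data frame / tibble of feature columns (>= 5 rows).
#' @param y Numeric response (engagement, 0-100).
#' @param method One of `"tree"`, `"boost"`, `"forest"`.
#' @param seed Integer seed.
#' @param params Optional list overriding hyperparameters (`min_leaf`, `cp`,
#'   `n_rounds`, `max_depth`, `eta`, `n_trees`).
#' @return An object of class `engagement_model` with a `predict` method;
#'   predictions are clipped to \[0, 100\].
#' @export
fit_regressor <- function(X, y, method = c("tree", "boost", "forest"),
                          seed = 1L, params = list()) {
  method <- match.arg(method)
  X <- as.data.frame(X)
  if (nrow(X) < 5L) stop("Need >= 5 training rows.", call. = FALSE)
  if (nrow(X) != length(y)) stop("X and y disagree in length.", call. = FALSE)
  p <- utils::modifyList(list(min_leaf = 3L, cp = 1e-4, n_rounds = 100L,
                              max_depth = 2L, eta = 0.1, n_trees = 100L),
                         params)
  features <- names(X)
  if (stats::var(y) < 1e-24) {
    fit <- list(kind = "constant", value = y[1])
  } else {
    set.seed(seed)
    fit <- switch(method,
      tree = list(kind = "tree", model = rpart::rpart(
        y ~ ., data = cbind(X, y = y),
        control = rpart::rpart.control(minbucket = p$min_leaf,
                                       minsplit = 2L * p$min_leaf,
                                       cp = p$cp, xval = 0))),
      boost = list(kind = "boost", model = xgboost::xgb.train(
        params = list(max_depth = p$max_depth, eta = p$eta,
                      objective = "reg:squarederror", nthread = 1,
                      seed = seed),
        data = xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1),
        nrounds = p$n_rounds, verbose = 0)),
      forest = list(kind = "forest", model = randomForest::randomForest(
        x = X, y = y, ntree = p$n_trees)))
  }
  structure(list(fit = fit, method = method, features = features, seed = seed),
            class = "engagement_model")
}

#' @export
predict.engagement_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)[, object$features, drop = FALSE]
  fit <- object$fit
  pred <- switch(fit$kind,
    constant = rep(fit$value, nrow(newdata)),
    tree = unname(stats::predict(fit$model, newdata)),
    boost = stats::predict(fit$model, as.matrix(newdata)),
    forest = unname(stats::predict(fit$model, newdata)))
  pmin(100, pmax(0, pred))
}

# impurity-based importance, normalized to sum 1 over all feature columns
model_importance <- function(object) {
  fit <- object$fit
  imp <- stats::setNames(rep(0, length(object$features)), object$features)
  raw <- switch(fit$kind,
    constant = imp,
    tree = fit$model$variable.importance,
    boost = {
      it <- xgboost::xgb.importance(model = fit$model)
      stats::setNames(it$Gain, it$Feature)
    },
    forest = {
      m <- randomForest::importance(fit$model)
      stats::setNames(m[, "IncNodePurity"], rownames(m))
    })
  raw <- raw[!is.na(raw)]
  imp[names(raw)] <- raw
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp
}

new_estimation_result <- function(predictions, mode, method) {
  per_dyad <- dplyr::summarise(
    dplyr::group_by(predictions, .data$dyad_id),
    rms_error = rms_ma_errors(.data$predicted, .data$reference)[["rms"]],
    ma_error = rms_ma_errors(.data$predicted, .data$reference)[["ma"]],
    .groups = "drop")
  summary <- tibble::tibble(
    mode = mode, method = method, n_dyads = nrow(per_dyad),
    rms_median = stats::median(per_dyad$rms_error),
    rms_p25 = stats::quantile(per_dyad$rms_error, 0.25, names = FALSE),
    rms_p75 = stats::quantile(per_dyad$rms_error, 0.75, names = FALSE),
    ma_median = stats::median(per_dyad$ma_error),
    ma_p25 = stats::quantile(per_dyad$ma_error, 0.25, names = FALSE),
    ma_p75 = stats::quantile(per_dyad$ma_error, 0.75, names = FALSE))
  structure(list(predictions = predictions, per_dyad = per_dyad,
                 summary = summary, mode = mode, method = method),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result> %s / %s over %d dyads\n", x$mode, x$method,
              nrow(x$per_dyad)))
  cat(sprintf("  RMS error: %.1f (%.1f-%.1f)   MA error: %.1f (%.1f-%.1f)  [median (p25-p75)]\n",
              x$summary$rms_median, x$summary$rms_p25, x$summary$rms_p75,
              x$summary$ma_median, x$summary$ma_p25, x$summary$ma_p75))
  invisible(x)
}

#' Leave-interval-out (dyad-specific) crossvalidation
#'
#' Trains a dyad-specific estimator on 14 of the dyad's 15 conversation
#' intervals and predicts the held-out interval, repeated so each interval
#' is the test interval once. Only that dyad's rows are used; participant
#' characteristics are excluded (constant within a dyad) and no baseline
#' normalization is applied. `method = "median_baseline"` predicts the
#' median reference engagement of the 14 training intervals.
#'
#' @param dyad_table Feature-table rows of one dyad (conversation rows;
#'   a baseline row, if present, is ignored).
#' @param method `"tree"`, `"boost"`, `"forest"`, or `"median_baseline"`.
#' @param use_sync Include the 17 synchrony features (default TRUE).
#' @param seed Integer seed for the tree-based methods.
#' @return An `estimation_result` with one out-of-fold prediction per
#'   interval.
#' @export
loio_cv <- function(dyad_table, method = c("forest", "tree", "boost",
                                           "median_baseline"),
                    use_sync = TRUE, seed = 1L) {
  method <- match.arg(method)
  tab <- dplyr::filter(dyad_table, .data$interval > 0L)
  if (length(unique(tab$dyad_id)) != 1L) {
    stop("loio_cv expects exactly one dyad's rows.", call. = FALSE)
  }
  if (anyNA(tab$engagement)) stop("Missing reference engagement.", call. = FALSE)
  feat_cols <- intersect(individual_feature_names(), names(tab))
  if (use_sync) feat_cols <- c(feat_cols,
                               intersect(synchrony_feature_names(), names(tab)))
  n <- nrow(tab)
  preds <- vapply(seq_len(n), function(i) {
    train <- tab[-i, , drop = FALSE]
    if (method == "median_baseline") {
      median_baseline_interval(train$engagement)
    } else {
      mod <- fit_regressor(train[, feat_cols, drop = FALSE], train$engagement,
                           method = method, seed = seed)
      predict(mod, tab[i, feat_cols, drop = FALSE])
    }
  }, numeric(1))
  predictions <- tibble::tibble(dyad_id = tab$dyad_id, interval = tab$interval,
                                predicted = pmin(100, pmax(0, preds)),
                                reference = tab$engagement)
  new_estimation_result(predictions, "loio", method)
}

#' Leave-dyad-out (dyad-non-specific) crossvalidation
#'
#' Holds out each dyad in turn, trains on all other dyads' conversation
#' rows, and predicts the held-out dyad's 15 intervals. Physiological
#' features are baseline-normalized first (each dyad's resting-baseline
#' value subtracted); participant characteristics are appended as inputs
#' when `use_chars` is TRUE. `method = "median_baseline"` predicts the
#' pooled median reference engagement of all training dyads' intervals.
#' The ablation flags implement the secondary analyses: `use_sync = FALSE`
#' removes the 17 synchrony columns, `use_chars = FALSE` the 12
#' characteristic columns.
#'
#' @param table Cohort feature table (see [cohort_features()]), with one
#'   baseline row per dyad unless already normalized.
#' @param method `"tree"`, `"boost"`, `"forest"`, or `"median_baseline"`.
#' @param use_sync Include synchrony features (default TRUE).
#' @param use_chars Include participant characteristics (default TRUE).
#' @param seed Integer seed.
#' @return An `estimation_result`; also carries the fitted per-fold models
#'   in `$models` for [predictor_importance()].
#' @export
ldo_cv <- function(table, method = c("forest", "tree", "boost",
                                     "median_baseline"),
                   use_sync = TRUE, use_chars = TRUE, seed = 1L) {
  method <- match.arg(method)
  dyads <- unique(table$dyad_id)
  if (length(dyads) < 2L) stop("Need >= 2 dyads for leave-dyad-out CV.", call. = FALSE)
  if (!isTRUE(attr(table, "baseline_normalized"))) {
    table <- baseline_normalize(table)
  }
  conv <- dplyr::filter(table, .data$interval > 0L)
  if (anyNA(conv$engagement)) stop("Missing reference engagement.", call. = FALSE)
  feat_cols <- intersect(individual_feature_names(), names(conv))
  if (use_sync) feat_cols <- c(feat_cols,
                               intersect(synchrony_feature_names(), names(conv)))
  if (use_chars) feat_cols <- c(feat_cols,
                                intersect(characteristic_names(), names(conv)))
  models <- list()
  pred_rows <- lapply(dyads, function(d) {
    train <- conv[conv$dyad_id != d, , drop = FALSE]
    test <- conv[conv$dyad_id == d, , drop = FALSE]
    if (method == "median_baseline") {
      p <- rep(median_baseline_dyad(train$engagement), nrow(test))
    } else {
      mod <- fit_regressor(train[, feat_cols, drop = FALSE], train$engagement,
                           method = method, seed = seed)
      models[[as.character(d)]] <<- mod
      p <- predict(mod, test[, feat_cols, drop = FALSE])
    }
    tibble::tibble(dyad_id = test$dyad_id, interval = test$interval,
                   predicted = pmin(100, pmax(0, p)),
                   reference = test$engagement)
  })
  res <- new_estimation_result(dplyr::bind_rows(pred_rows), "ldo", method)
  res$models <- models
  res
}

#' Average predictor importance across leave-dyad-out models
#'
#' Impurity-based importances of each per-fold model are normalized to sum
#' one and averaged across folds. Ties are broken lexicographically by
#' feature name.
#'
#' @param result An `estimation_result` from [ldo_cv()] with a tree-based
#'   method.
#' @param top_n Number of top features to flag (default 5).
#' @return A tibble `feature`, `importance`, `rank`, `top` sorted by rank.
#' @export
predictor_importance <- function(result, top_n = 5L) {
  stopifnot(inherits(result, "estimation_result"))
  if (!length(result$models)) {
    stop("Result carries no fitted models (median baseline has no importance).",
         call. = FALSE)
  }
  imps <- do.call(rbind, lapply(result$models, model_importance))
  avg <- colMeans(imps)
  ord <- order(-avg, names(avg))
  out <- tibble::tibble(feature = names(avg)[ord],
                        importance = unname(avg[ord]))
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= top_n
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an estimation result
#'
#' @param x An `estimation_result`.
#' @param ... Unused.
#' @return `tidy()`: per-dyad error tibble (`dyad_id`, `rms_error`,
#'   `ma_error`); `glance()`: one-row summary with median and quartiles of
#'   both errors.
#' @export
tidy.estimation_result <- function(x, ...) x$per_dyad

#' @rdname tidy.estimation_result
#' @export
glance.estimation_result <- function(x, ...) x$summary
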