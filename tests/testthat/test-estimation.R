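test_that("error metrics match closed forms and obey rms >= ma", {
  expect_equal(unname(rms_ma_errors(c(1, 2), c(1, 2))), c(0, 0))
  e <- rms_ma_errors(c(3, 4), c(0, 0))
  expect_equal(e[["ma"]], 3.5)
  expect_equal(e[["rms"]], sqrt(12.5), tolerance = 1e-9)
  set.seed(1)
  for (i in 1:20) {
    r <- rms_ma_errors(rnorm(15, 50, 10), rnorm(15, 50, 10))
    expect_gte(r[["rms"]], r[["ma"]])
  }
  expect_error(rms_ma_errors(numeric(0), numeric(0)), "non-empty")
})

test_that("median baselines use the even-count convention and match a sort oracle", {
  expect_equal(median_baseline_interval(rep(70, 14)), 70)
  expect_equal(median_baseline_interval(c(rep(60, 7), rep(80, 7))), 70)
  set.seed(2)
  for (i in 1:20) {
    v <- runif(sample(5:30, 1), 0, 100)
    s <- sort(v); n <- length(s)
    oracle <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(median_baseline_interval(v), oracle)
    expect_equal(median_baseline_dyad(v), oracle)
  }
})

test_that("baseline normalization subtracts the resting row and refuses double application", {
  ft <- test_cohort()$features
  norm <- baseline_normalize(ft)
  d1 <- ft$dyad_id[1]
  base_raw <- ft[ft$dyad_id == d1 & ft$interval == 0, ]
  row5 <- ft[ft$dyad_id == d1 & ft$interval == 5, ]
  row5n <- norm[norm$dyad_id == d1 & norm$interval == 5, ]
  expect_equal(row5n$mean_hr_p1, row5$mean_hr_p1 - base_raw$mean_hr_p1)
  expect_equal(row5n$coh_resp_0_2, row5$coh_resp_0_2 - base_raw$coh_resp_0_2)
  # baseline rows become zero; characteristics and engagement untouched
  base_n <- norm[norm$interval == 0, ]
  expect_true(all(abs(base_n$mean_hr_p1) < 1e-12))
  expect_identical(norm$age_p1, ft$age_p1)
  expect_identical(norm$engagement, ft$engagement)
  expect_error(baseline_normalize(norm), "already")
  # a table missing its baseline row errors
  expect_error(baseline_normalize(ft[ft$interval > 0, ]), "baseline row")
})

test_that("regressors memorize, return constants for degenerate y, and are seed-deterministic", {
  set.seed(3)
  X <- tibble::tibble(a = runif(30, 0, 100), b = rnorm(30))
  const <- fit_regressor(X, rep(42, 30), "forest", seed = 1)
  expect_equal(predict(const, X), rep(42, 30))

  tree <- fit_regressor(X, X$a, "tree", seed = 1,
                        params = list(min_leaf = 1, cp = 0))
  expect_lt(rms_ma_errors(predict(tree, X), X$a)[["rms"]], 1e-6)

  y <- X$a + rnorm(30)
  for (m in c("tree", "boost", "forest")) {
    m1 <- fit_regressor(X, y, m, seed = 9)
    m2 <- fit_regressor(X, y, m, seed = 9)
    expect_identical(predict(m1, X), predict(m2, X))
  }
  expect_error(fit_regressor(X[1:3, ], y[1:3], "tree"), ">= 5")
})

test_that("leave-interval-out CV bookkeeping, baseline behavior and leakage", {
  ft <- test_cohort()$features
  d1 <- ft$dyad_id[1]
  tab <- ft[ft$dyad_id == d1, ]

  res <- loio_cv(tab, "median_baseline")
  expect_equal(nrow(res$predictions), 15)
  expect_equal(sort(res$predictions$interval), 1:15)

  # constant references give zero error for the median baseline
  tab0 <- tab; tab0$engagement[tab0$interval > 0] <- 70
  res0 <- loio_cv(tab0, "median_baseline")
  expect_equal(res0$per_dyad$rms_error, 0)

  # sentinel poisoning: the held-out reference must not change its prediction
  res_f <- loio_cv(tab, "forest", seed = 5)
  tab_p <- tab
  tab_p$engagement[tab_p$interval == 7] <- 0
  res_p <- loio_cv(tab_p, "forest", seed = 5)
  expect_identical(res_f$predictions$predicted[res_f$predictions$interval == 7],
                   res_p$predictions$predicted[res_p$predictions$interval == 7])
  expect_error(loio_cv(ft, "forest"), "one dyad")
})

test_that("leave-dyad-out CV bookkeeping, clipping and leakage", {
  ft <- test_cohort()$features
  n_dyads <- length(unique(ft$dyad_id))

  # identical engagement everywhere -> zero error for the dyad-median baseline
  ft0 <- ft; ft0$engagement[ft0$interval > 0] <- 55
  res0 <- ldo_cv(ft0, "median_baseline")
  expect_true(all(res0$per_dyad$rms_error == 0))

  res <- ldo_cv(ft, "forest", seed = 4)
  expect_equal(nrow(res$predictions), 15 * n_dyads)
  expect_equal(dplyr::count(res$predictions, dyad_id)$n, rep(15, n_dyads))
  expect_true(all(res$predictions$predicted >= 0 & res$predictions$predicted <= 100))

  # poisoning every reference of the held-out dyad leaves its predictions alone
  d2 <- unique(ft$dyad_id)[2]
  ft_p <- ft
  ft_p$engagement[ft_p$dyad_id == d2 & ft_p$interval > 0] <- 0
  res_p <- ldo_cv(ft_p, "forest", seed = 4)
  expect_identical(res$predictions$predicted[res$predictions$dyad_id == d2],
                   res_p$predictions$predicted[res_p$predictions$dyad_id == d2])
  expect_error(ldo_cv(ft[ft$dyad_id == ft$dyad_id[1], ], "forest"), ">= 2 dyads")
})

test_that("predictor importance finds the informative feature and is normalized", {
  set.seed(6)
  n_dyads <- 6
  rows <- do.call(rbind, lapply(seq_len(n_dyads), function(d) {
    eng <- runif(16, 20, 95)
    tibble::tibble(dyad_id = sprintf("d%02d", d), interval = 0:15,
                   signal_feat = eng + rnorm(16, 0, 2),
                   noise_feat1 = rnorm(16), noise_feat2 = rnorm(16),
                   engagement = c(NA, eng[-1]))
  }))
  rows$engagement[rows$interval == 0] <- NA
  # mimic the feature-table contract with a fake individual-feature name
  names(rows)[names(rows) == "signal_feat"] <- "mean_hr_p1"
  names(rows)[names(rows) == "noise_feat1"] <- "sdnn_p1"
  names(rows)[names(rows) == "noise_feat2"] <- "rmssd_p1"
  res <- ldo_cv(rows, "forest", seed = 2, use_chars = FALSE)
  imp <- predictor_importance(res)
  expect_equal(imp$feature[1], "mean_hr_p1")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(sum(imp$top), 3)  # only 3 features present
})

test_that("tidy and glance expose per-dyad errors and the median (IQR) summary", {
  ft <- test_cohort()$features
  res <- ldo_cv(ft, "median_baseline")
  td <- tidy(res)
  expect_true(all(c("dyad_id", "rms_error", "ma_error") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$rms_median, median(td$rms_error))
  expect_equal(gl$rms_p25, unname(quantile(td$rms_error, 0.25)))
})
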