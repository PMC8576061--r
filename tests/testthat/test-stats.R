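test_that("ICC(1,1) has its analytic fixed points and matches an ANOVA oracle", {
  set.seed(1)
  v <- runif(10, 40, 90)
  expect_equal(icc_oneway(cbind(v, v)), 1)

  # no between-row variance: expectation <= 0, reported as computed
  m <- cbind(50 + rnorm(40), 50 + rnorm(40))
  expect_lt(icc_oneway(m), 0.3)

  # 6-row table against an independent one-way ANOVA decomposition
  tab <- cbind(c(70, 55, 88, 61, 74, 80), c(64, 58, 91, 50, 70, 85))
  df <- data.frame(y = as.vector(tab),
                   row = factor(rep(seq_len(nrow(tab)), times = 2)))
  aov_tab <- summary(stats::aov(y ~ row, data = df))[[1]]
  msb <- aov_tab["row", "Mean Sq"]
  msw <- aov_tab["Residuals", "Mean Sq"]
  expect_equal(icc_oneway(tab), (msb - msw) / (msb + msw), tolerance = 1e-9)

  expect_error(icc_oneway(cbind(rep(1, 5), rep(1, 5))), "variance")
})

test_that("ICC decreases monotonically as rater noise grows", {
  set.seed(2)
  latent <- runif(200, 30, 95)
  iccs <- vapply(c(0, 5, 10, 20, 40), function(s) {
    icc_oneway(cbind(latent + rnorm(200, 0, s), latent + rnorm(200, 0, s)))
  }, numeric(1))
  expect_equal(iccs[1], 1)
  expect_true(all(diff(iccs) < 0))
})

test_that("external-coder errors mirror the estimator error metrics", {
  s_exact <- mini_session(c(70, 60, 80), c(70, 60, 80), "cd1",
                          coder = c(70, 60, 80))
  s_off <- mini_session(c(60, 50, 70), c(60, 50, 70), "cd2",
                        coder = c(70, 60, 80))
  s_none <- mini_session(c(50, 50, 50), c(50, 50, 50), "cd3")
  res <- coder_errors(list(s_exact, s_off, s_none))
  expect_equal(res$n_skipped, 1)
  expect_equal(res$per_dyad$rms_error, c(0, 10))
  expect_equal(res$per_dyad$ma_error, c(0, 10))

  set.seed(3)
  coder <- round(runif(3, 0, 100), 1)
  s_rand <- mini_session(c(40, 60, 80), c(50, 70, 90), "cd4", coder = coder)
  res2 <- coder_errors(list(s_rand))
  oracle <- rms_ma_errors(coder, c(45, 65, 85))
  expect_equal(res2$per_dyad$rms_error, oracle[["rms"]])
  expect_equal(res2$per_dyad$ma_error, oracle[["ma"]])
})

test_that("trait-error Spearman correlations match midrank oracles and handle ties", {
  n <- 8
  traits <- tibble::tibble(
    dyad_id = sprintf("d%d", 1:n),
    social_anxiety_mean = c(3, 1, 4, 2, 8, 6, 5, 7),
    social_anxiety_diff = rep(1, n),        # constant -> NA
    depression_mean = c(2, 2, 4, 4, 6, 6, 8, 8),  # ties
    depression_diff = 1:n,
    cognitive_empathy_mean = 1:n, cognitive_empathy_diff = n:1,
    affective_empathy_mean = runif(n), affective_empathy_diff = runif(n))
  errors <- tibble::tibble(dyad_id = sprintf("d%d", 1:n),
                           rms_error = traits$social_anxiety_mean * 2 + 10,
                           ma_error = rnorm(n))
  rep <- trait_error_correlations(traits, errors)
  r1 <- rep[rep$trait_stat == "social_anxiety_mean" & rep$outcome == "rms_error", ]
  expect_equal(r1$rho, 1)
  expect_true(is.na(rep$rho[rep$trait_stat == "social_anxiety_diff" &
                              rep$outcome == "rms_error"]))
  # midrank oracle for the tied column
  r2 <- rep[rep$trait_stat == "depression_mean" & rep$outcome == "rms_error", ]
  oracle <- stats::cor(rank(traits$depression_mean), rank(errors$rms_error))
  expect_equal(r2$rho, oracle, tolerance = 1e-12)
  expect_error(trait_error_correlations(traits[1:3, ], errors[1:3, ]), ">= 5")
})

test_that("Spearman null behaves correctly at n = 16", {
  set.seed(4)
  pvals <- replicate(1000, {
    ct <- suppressWarnings(stats::cor.test(rnorm(16), rnorm(16),
                                           method = "spearman", exact = FALSE))
    ct$p.value
  })
  expect_gt(mean(pvals < 0.05), 0.025)
  expect_lt(mean(pvals < 0.05), 0.08)
})

test_that("median (p25-p75) summaries match the sort-based oracle", {
  expect_equal(unname(summarize_iqr(c(1, 2, 3))), c(2, 1.5, 2.5))
  expect_equal(unname(summarize_iqr(rep(7, 5))), c(7, 7, 7))
  set.seed(5)
  v <- runif(37, 0, 100)
  s <- summarize_iqr(v)
  expect_equal(s[["median"]], unname(quantile(v, 0.5)))
  expect_equal(s[["p25"]], unname(quantile(v, 0.25)))
  expect_equal(s[["p75"]], unname(quantile(v, 0.75)))
})

test_that("correlation report is invariant to dyad ordering", {
  coh <- test_cohort()
  traits <- trait_summary(coh$sessions)
  res <- ldo_cv(coh$features, "median_baseline")
  errors <- tidy(res)
  # need >= 5 dyads: pad by duplicating with new ids
  traits2 <- dplyr::bind_rows(traits, dplyr::mutate(traits, dyad_id = paste0(dyad_id, "x")))
  errors2 <- dplyr::bind_rows(errors, dplyr::mutate(errors, dyad_id = paste0(dyad_id, "x")))
  a <- trait_error_correlations(traits2, errors2)
  perm <- sample(nrow(traits2))
  b <- trait_error_correlations(traits2[perm, ], errors2)
  expect_equal(a, b)
})
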