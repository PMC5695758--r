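test_that("exact linear data recover coefficients with zero variance components", {
  u <- simulate_unit_data(n_countries = 4, surveys_per_country = 3,
                          intercept = 2.10, slope = -0.20,
                          sd_country = 0, sd_survey_intercept = 0,
                          sd_survey_slope = 0, sd_residual = 0, seed = 2)
  fit <- fit_three_level(u, "sd")
  expect_equal(fit$slope, -0.20, tolerance = 1e-10)
  expect_equal(fit$intercept, 2.10, tolerance = 1e-10)
  expect_equal(unname(fit$varcomp), rep(0, 5))
  expect_true(fit$converged)
  expect_equal(fit$slope_ci[1], fit$slope_ci[2])
  expect_true(all(blup_survey_slopes(fit)$blup_slope == fit$slope))
})

test_that("estimates are invariant to unit order", {
  u <- simulate_unit_data(n_countries = 6, surveys_per_country = 4, seed = 5)
  fit1 <- fit_three_level(u, "sd")
  set.seed(1)
  fit2 <- fit_three_level(u[sample.int(nrow(u)), ], "sd")
  expect_equal(fit1$slope, fit2$slope, tolerance = 1e-6)
  expect_equal(fit1$intercept, fit2$intercept, tolerance = 1e-6)
  expect_equal(fit1$varcomp, fit2$varcomp, tolerance = 1e-4)
})

test_that("sign reversal of the predictor negates the slope exactly", {
  u <- simulate_unit_data(n_countries = 6, surveys_per_country = 4, seed = 9)
  fit <- fit_three_level(u, "sd")
  u_flip <- u
  u_flip$mean <- -u$mean    # so the internal x = -mean flips sign
  fit_flip <- fit_three_level(u_flip, "sd")
  expect_equal(fit_flip$slope, -fit$slope, tolerance = 1e-6)
})

test_that("three-level REML recovers generating parameters", {
  u <- simulate_unit_data(n_countries = 20, surveys_per_country = 5,
                          intercept = 2.10, slope = -0.20,
                          sd_country = 0.1, sd_survey_intercept = 0.1,
                          sd_survey_slope = 0.05, sd_residual = 0.1, seed = 101)
  fit <- fit_three_level(u, "sd")
  expect_true(fit$converged)
  expect_lt(abs(fit$slope - (-0.20)), 3 * fit$slope_se)
  expect_lt(abs(fit$intercept - 2.10), 3 * fit$intercept_se)
  expect_gt(sqrt(fit$varcomp[["var_survey_slope"]]), 0.025)
  expect_lt(sqrt(fit$varcomp[["var_survey_slope"]]), 0.075)
  expect_equal(sqrt(fit$varcomp[["var_residual"]]), 0.1, tolerance = 0.02)
})

test_that("predicted values follow the sign-reversal convention", {
  fit <- list(intercept = 2.10, slope = -0.20, intercept_se = 0, slope_se = 0)
  expect_equal(predict_at(fit, -2)[["estimate"]], 1.70)
  expect_equal(predict_at(fit, 0)[["estimate"]], 2.10)
  fit_med <- list(intercept = -0.046, slope = -0.98,
                  intercept_se = 0, slope_se = 0)
  expect_equal(predict_at(fit_med, -2)[["estimate"]], -2.006)
  # with a real fit, the CI at the data centre is narrower than the slope CI
  u <- simulate_unit_data(n_countries = 8, surveys_per_country = 4, seed = 3)
  f <- fit_three_level(u, "sd")
  p <- predict_at(f, -2)
  expect_true(p[["ci_low"]] < p[["estimate"]] && p[["estimate"]] < p[["ci_high"]])
  expect_equal(p[["estimate"]], f$intercept + 2 * f$slope)
})

test_that("ICCs are variance-component ratios with the documented conventions", {
  vc <- c(var_country = 1, var_survey_intercept = 3, var_survey_slope = 0.2,
          cov_survey = 0, var_residual = 1)
  iccs <- compute_iccs(vc)
  expect_equal(iccs[["icc_country"]], 0.2)
  expect_equal(iccs[["icc_survey_in_country"]], 0.8)
  expect_equal(unname(compute_iccs(c(var_country = 0, var_survey_intercept = 0,
                                     var_survey_slope = 0, cov_survey = 0,
                                     var_residual = 2))), c(0, 0))
  expect_equal(compute_iccs(c(var_country = 0.5, var_survey_intercept = 0.5,
                              var_survey_slope = 0, cov_survey = 0,
                              var_residual = 0))[["icc_survey_in_country"]], 1)
  expect_true(all(is.na(compute_iccs(c(var_country = 0, var_survey_intercept = 0,
                                       var_survey_slope = 0, cov_survey = 0,
                                       var_residual = 0)))))
  # ordering invariant on real fits
  for (seed in c(4, 8)) {
    u <- simulate_unit_data(n_countries = 8, surveys_per_country = 4, seed = seed)
    f <- fit_three_level(u, "sd")
    expect_lte(f$icc_country, f$icc_survey_in_country)
    expect_gte(f$icc_country, 0)
    expect_lte(f$icc_survey_in_country, 1)
  }
})

test_that("stratified interaction models recover stratum-specific slopes", {
  uA <- simulate_unit_data(n_countries = 8, surveys_per_country = 4,
                           slope = -0.1, seed = 61)
  uB <- simulate_unit_data(n_countries = 8, surveys_per_country = 4,
                           slope = -0.3, seed = 62)
  uB$country_id <- sub("^C0", "D0", uB$country_id)
  uB$survey_id <- sub("^C0", "D0", uB$survey_id)
  u <- rbind(uA, uB)
  stratum <- rep(c("A", "B"), times = c(nrow(uA), nrow(uB)))
  s <- fit_stratified(u, "sd", stratum = stratum)
  expect_identical(s$stratum, c("A", "B"))
  se <- (s$ci_high - s$ci_low) / (2 * qnorm(0.975))
  expect_lt(abs(s$slope[1] - (-0.1)), 3 * se[1])
  expect_lt(abs(s$slope[2] - (-0.3)), 3 * se[2])
  expect_lt(s$slope[2], s$slope[1])

  # consistent relabeling leaves slopes unchanged
  s2 <- fit_stratified(u, "sd", stratum = ifelse(stratum == "A", "g2", "g1"))
  expect_equal(sort(s2$slope), sort(s$slope), tolerance = 1e-6)

  # degenerate stratification equals the unstratified fit
  s1 <- fit_stratified(uA, "sd", stratum = rep("all", nrow(uA)))
  f1 <- fit_three_level(uA, "sd")
  expect_equal(s1$slope, f1$slope)

  # a stratum with a single survey is excluded and flagged
  tinyB <- uB[uB$survey_id == uB$survey_id[1], ]
  s3 <- fit_stratified(rbind(uA, tinyB), "sd",
                       stratum = rep(c("A", "lonely"),
                                     c(nrow(uA), nrow(tinyB))))
  expect_identical(attr(s3, "excluded_strata"), "lonely")
  expect_identical(s3$stratum, "A")
})

test_that("stratifiers derived from survey covariates partition the units", {
  d <- tiny_dataset(children = 300, seed = 29)
  u <- build_survey_age_units(d$children, d$surveys)
  for (sf in c("region", "year_period", "income", "size_class",
               "baseline_mean_haz_tertile")) {
    st <- derive_stratum(u, sf)
    expect_identical(length(st), nrow(u))
    expect_false(anyNA(st))
    # stratum constant within survey
    expect_true(all(tapply(as.character(st), u$survey_id,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("per-survey OLS slopes match exact lines and flag degenerate surveys", {
  x <- seq(0.4, 2.0, length.out = 6)
  u_exact <- data.frame(survey_id = "S1", country_id = "C1",
                        mean = -x, sd = 1 + 0.04 * x)
  s <- survey_fixed_effects_slopes(u_exact, "sd")
  expect_equal(s$slope, 0.04, tolerance = 1e-12)
  expect_equal(s$ci_high - s$ci_low, 0, tolerance = 1e-9)
  expect_identical(s$flag, "ok")

  u_flat <- data.frame(survey_id = "S2", country_id = "C1",
                       mean = rep(-1, 4), sd = rnorm(4))
  s2 <- survey_fixed_effects_slopes(u_flat, "sd")
  expect_identical(s2$flag, "no_predictor_variation")
  expect_true(is.na(s2$slope))
})

test_that("opposite survey slopes are recovered with the right signs", {
  set.seed(77)
  x <- seq(0.4, 2.0, length.out = 12)
  correct <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    y1 <- 1 + 0.2 * x + rnorm(12, 0, 0.05)
    y2 <- 1 - 0.2 * x + rnorm(12, 0, 0.05)
    u <- data.frame(survey_id = rep(c("S1", "S2"), each = 12),
                    country_id = "C1", mean = c(-x, -x), sd = c(y1, y2))
    s <- survey_fixed_effects_slopes(u, "sd")
    if (s$slope[s$survey_id == "S1"] > 0 && s$slope[s$survey_id == "S2"] < 0) {
      correct <- correct + 1L
    }
  }
  expect_gte(correct / n_rep, 0.95)
})

test_that("BLUP slopes shrink towards the fixed slope", {
  u <- simulate_unit_data(n_countries = 15, surveys_per_country = 4,
                          sd_survey_slope = 0.05, sd_residual = 0.1, seed = 55)
  fit <- fit_three_level(u, "sd")
  blup <- blup_survey_slopes(fit)
  ols <- survey_fixed_effects_slopes(u, "sd")
  m <- match(blup$survey_id, ols$survey_id)
  expect_lte(sd(blup$blup_slope), sd(ols$slope[m]))

  # zero random-slope variance collapses every BLUP onto the fixed slope
  u0 <- simulate_unit_data(n_countries = 6, surveys_per_country = 4,
                           sd_survey_slope = 0, sd_residual = 0.1, seed = 56)
  fit0 <- fit_three_level(u0, "sd")
  if (fit0$varcomp[["var_survey_slope"]] == 0) {
    expect_equal(blup_survey_slopes(fit0)$blup_slope,
                 rep(fit0$slope, fit0$n_surveys), tolerance = 1e-8)
  } else {
    # small estimated slope variance: BLUPs still shrink below the OLS spread
    ols0 <- survey_fixed_effects_slopes(u0, "sd")
    expect_lte(sd(blup_survey_slopes(fit0)$blup_slope), sd(ols0$slope))
  }

  # a single survey carries no between-survey information
  u1 <- u[u$survey_id == u$survey_id[1], ]
  fit1 <- fit_three_level(u1, "sd")
  expect_equal(blup_survey_slopes(fit1)$blup_slope, fit1$slope)
})

test_that("bootstrap ICC intervals bracket the point estimates", {
  u <- simulate_unit_data(n_countries = 8, surveys_per_country = 3,
                          sd_country = 0.15, sd_survey_intercept = 0.1,
                          sd_survey_slope = 0.02, sd_residual = 0.1, seed = 71)
  fit <- fit_three_level(u, "sd")
  ci <- icc_bootstrap_ci(fit, nsim = 20, seed = 2)
  expect_identical(rownames(ci), c("icc_country", "icc_survey_in_country"))
  expect_true(all(ci[, "ci_low"] <= ci[, "ci_high"]))
  expect_true(all(ci >= 0 & ci <= 1))
})
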