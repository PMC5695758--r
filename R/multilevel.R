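## Three-level models --------------------------------------------------------
##
## The central analysis relates each distributional parameter (SD, median,
## dp5, dp95) of the survey-age units to the sign-reversed unit mean HAZ
## (x = -mean), so a positive slope means the outcome rises as mean HAZ
## falls. The hierarchy is: survey-age units within surveys within countries,
## fitted by REML as
##
##   y ~ x + (1 | country) + (1 + x | survey)
##
## with an unstructured 2x2 covariance for the survey-level intercept and
## slope. Fixed-effect CIs use the normal approximation.

MODEL_OUTCOMES <- c("sd", "median", "dp5", "dp95")

lmer_control_default <- function() {
  lme4::lmerControl(optimizer = "bobyqa",
                    optCtrl = list(maxfun = 100000L),
                    check.conv.singular = "ignore")
}

#' Fit the three-level model for one distributional parameter
#'
#' Fits `outcome ~ x + (1 | country_id) + (1 + x | survey_id)` by REML, where
#' `x = -mean` is the sign-reversed unit mean HAZ. Degenerate inputs are
#' handled explicitly: if the outcome is an exact linear function of `x` the
#' OLS coefficients are returned with all variance components zero, and a
#' single-survey dataset falls back to OLS (no between-survey information).
#'
#' @param units a `survey_age_units` data frame (or any data frame with
#'   `country_id`, `survey_id`, `mean` and the outcome column).
#' @param outcome outcome column, one of `"sd"`, `"median"`, `"dp5"`, `"dp95"`
#'   (any numeric column is accepted).
#' @param conf_level confidence level for fixed-effect CIs.
#' @param icc_model how ICCs are computed: `"intercept_components"` (default)
#'   uses the intercept-relevant variance components of the random-slope model
#'   (i.e. evaluated at predictor 0); `"random_intercepts_refit"` refits a
#'   random-intercepts-only model and takes its components.
#' @param control an [lme4::lmerControl()] object.
#' @return Object of class `haz_threelevel_fit`: fixed slope and intercept
#'   with SEs and CIs, variance components (`var_country`,
#'   `var_survey_intercept`, `var_survey_slope`, `cov_survey`,
#'   `var_residual`), ICCs, per-survey BLUP slopes, convergence flags and the
#'   underlying model object.
#' @export
fit_three_level <- function(units, outcome = "sd", conf_level = 0.95,
                            icc_model = c("intercept_components",
                                          "random_intercepts_refit"),
                            control = lmer_control_default()) {
  icc_model <- match.arg(icc_model)
  stopifnot(outcome %in% names(units), is.numeric(units[[outcome]]),
            all(c("country_id", "survey_id", "mean") %in% names(units)))
  df <- data.frame(y = units[[outcome]],
                   x = -units$mean,
                   survey_id = factor(units$survey_id),
                   country_id = factor(units$country_id))
  if (anyNA(df$y) || any(!is.finite(df$y))) {
    stop("outcome column contains non-finite values", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n_surveys <- nlevels(df$survey_id)
  n_countries <- nlevels(df$country_id)

  ols <- stats::lm(y ~ x, data = df)
  exact <- stats::sigma(ols) < 1e-8 * max(1, stats::sd(df$y))
  if (exact || n_surveys < 2L) {
    # perfect fits make lm's summary warn; the zero SEs are intended here
    co <- suppressWarnings(summary(ols))$coefficients
    slope <- co["x", "Estimate"]
    slope_se <- if (exact) 0 else co["x", "Std. Error"]
    intercept <- co["(Intercept)", "Estimate"]
    intercept_se <- if (exact) 0 else co["(Intercept)", "Std. Error"]
    vc <- c(var_country = 0, var_survey_intercept = 0, var_survey_slope = 0,
            cov_survey = 0,
            var_residual = if (exact) 0 else stats::sigma(ols)^2)
    fit <- structure(list(
      outcome = outcome,
      slope = slope, slope_se = slope_se,
      slope_ci = c(slope - z * slope_se, slope + z * slope_se),
      intercept = intercept, intercept_se = intercept_se,
      intercept_ci = c(intercept - z * intercept_se, intercept + z * intercept_se),
      varcomp = vc,
      icc_country = if (sum(vc[c(1, 2, 5)]) == 0) NA_real_ else 0,
      icc_survey_in_country = if (sum(vc[c(1, 2, 5)]) == 0) NA_real_ else 0,
      blup_slopes = data.frame(survey_id = levels(df$survey_id),
                               blup_slope = slope, stringsAsFactors = FALSE),
      converged = TRUE, singular = TRUE, degenerate = TRUE,
      n_units = nrow(df), n_surveys = n_surveys, n_countries = n_countries,
      conf_level = conf_level, model = ols), class = "haz_threelevel_fit")
    return(fit)
  }

  warnings_seen <- character()
  model <- withCallingHandlers(
    lme4::lmer(y ~ x + (1 | country_id) + (1 + x | survey_id),
               data = df, REML = TRUE, control = control),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- length(warnings_seen) == 0 ||
    !any(grepl("converge", warnings_seen, ignore.case = TRUE))
  singular <- lme4::isSingular(model)

  fe <- lme4::fixef(model)
  vcv <- as.matrix(stats::vcov(model))
  slope <- fe[["x"]]
  slope_se <- sqrt(vcv["x", "x"])
  intercept <- fe[["(Intercept)"]]
  intercept_se <- sqrt(vcv["(Intercept)", "(Intercept)"])

  vc_df <- as.data.frame(lme4::VarCorr(model))
  get_vc <- function(grp, v1, v2 = NA) {
    r <- vc_df$grp == grp & vc_df$var1 %in% v1 &
      (if (is.na(v2)) is.na(vc_df$var2) else vc_df$var2 %in% v2)
    if (any(r)) vc_df$vcov[r][1] else 0
  }
  vc <- c(var_country = get_vc("country_id", "(Intercept)"),
          var_survey_intercept = get_vc("survey_id", "(Intercept)"),
          var_survey_slope = get_vc("survey_id", "x"),
          cov_survey = get_vc("survey_id", "(Intercept)", "x"),
          var_residual = vc_df$vcov[vc_df$grp == "Residual"][1])

  iccs <- if (icc_model == "intercept_components") {
    icc_from_components(vc)
  } else {
    ri <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ x + (1 | country_id) + (1 | survey_id),
                 data = df, REML = TRUE, control = control)))
    ri_df <- as.data.frame(lme4::VarCorr(ri))
    vc_ri <- c(var_country = ri_df$vcov[ri_df$grp == "country_id"][1],
               var_survey_intercept = ri_df$vcov[ri_df$grp == "survey_id"][1],
               var_survey_slope = 0, cov_survey = 0,
               var_residual = ri_df$vcov[ri_df$grp == "Residual"][1])
    icc_from_components(vc_ri)
  }

  re_survey <- lme4::ranef(model)$survey_id
  blups <- data.frame(survey_id = rownames(re_survey),
                      blup_slope = slope + re_survey[["x"]],
                      stringsAsFactors = FALSE)

  structure(list(
    outcome = outcome,
    slope = slope, slope_se = slope_se,
    slope_ci = c(slope - z * slope_se, slope + z * slope_se),
    intercept = intercept, intercept_se = intercept_se,
    intercept_ci = c(intercept - z * intercept_se, intercept + z * intercept_se),
    varcomp = vc,
    icc_country = iccs[["icc_country"]],
    icc_survey_in_country = iccs[["icc_survey_in_country"]],
    blup_slopes = blups,
    converged = converged, singular = singular, degenerate = FALSE,
    n_units = nrow(df), n_surveys = n_surveys, n_countries = n_countries,
    conf_level = conf_level, model = model), class = "haz_threelevel_fit")
}

icc_from_components <- function(vc) {
  total <- vc[["var_country"]] + vc[["var_survey_intercept"]] +
    vc[["var_residual"]]
  if (total <= 0) {
    return(c(icc_country = NA_real_, icc_survey_in_country = NA_real_))
  }
  c(icc_country = vc[["var_country"]] / total,
    icc_survey_in_country =
      (vc[["var_country"]] + vc[["var_survey_intercept"]]) / total)
}

#' @export
print.haz_threelevel_fit <- function(x, ...) {
  cat(sprintf("Three-level model: %s ~ -(mean HAZ)\n", x$outcome))
  cat(sprintf("  %d units, %d surveys, %d countries%s%s\n",
              x$n_units, x$n_surveys, x$n_countries,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$singular) " [singular]" else ""))
  cat(sprintf("  slope     %7.3f (%.3f to %.3f)  per 1-unit decline in mean HAZ\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  intercept %7.3f (%.3f to %.3f)  at mean HAZ = 0\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  ICC country %.3f; ICC survey-in-country %.3f\n",
              x$icc_country, x$icc_survey_in_country))
  invisible(x)
}

#' Variance-component ICCs of a three-level fit
#'
#' Proportion of unit-level variance attributable to country clustering and
#' to country-plus-survey clustering, computed from the intercept-relevant
#' components (the between-cluster variance evaluated at predictor value 0,
#' since under a random-slope model the ICC varies with the predictor).
#'
#' @param fit a `haz_threelevel_fit`, or a named variance-component vector
#'   with elements `var_country`, `var_survey_intercept`, `var_residual`.
#' @return Named vector `c(icc_country, icc_survey_in_country)`; `NA` when
#'   the total variance is zero.
#' @export
compute_iccs <- function(fit) {
  vc <- if (inherits(fit, "haz_threelevel_fit")) fit$varcomp else fit
  stopifnot(all(c("var_country", "var_survey_intercept", "var_residual") %in%
                  names(vc)))
  if (any(vc[c("var_country", "var_survey_intercept", "var_residual")] < 0)) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  icc_from_components(vc)
}

#' Fixed-effects prediction at a given mean HAZ
#'
#' Applies the sign-reversal convention: the predicted outcome at population
#' mean HAZ `m` is `intercept + slope * (-m)`.
#'
#' @param fit a `haz_threelevel_fit` (or any list with `intercept`, `slope`,
#'   and their SEs).
#' @param mean_haz population mean HAZ at which to predict.
#' @return Named vector `c(estimate, ci_low, ci_high)`; the CI propagates the
#'   fixed-effect covariance when a model object is available.
#' @export
predict_at <- function(fit, mean_haz) {
  if (inherits(fit, "haz_threelevel_fit") && !isTRUE(fit$converged)) {
    stop("model did not converge; prediction not available", call. = FALSE)
  }
  x <- -mean_haz
  est <- fit$intercept + fit$slope * x
  se <- NA_real_
  if (!is.null(fit$model)) {
    vcv <- as.matrix(stats::vcov(fit$model))
    cn <- colnames(vcv)
    iidx <- match("(Intercept)", cn)
    xidx <- match("x", cn)
    if (!is.na(iidx) && !is.na(xidx)) {
      se <- sqrt(vcv[iidx, iidx] + x^2 * vcv[xidx, xidx] +
                   2 * x * vcv[iidx, xidx])
    }
  }
  if (is.na(se)) se <- sqrt(fit$intercept_se^2 + x^2 * fit$slope_se^2)
  z <- stats::qnorm(1 - (1 - (fit$conf_level %||% 0.95)) / 2)
  c(estimate = est, ci_low = est - z * se, ci_high = est + z * se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Survey-level stratifiers
#'
#' Derives the stratifying factor used in the interaction models: world
#' region, survey calendar period, national income class, survey-size
#' tertile, or tertile of the survey's mean HAZ in the 0-3 month band.
#' Tertiles are computed across surveys (not units).
#'
#' @param units a `survey_age_units` data frame.
#' @param stratifier one of `"region"`, `"year_period"`, `"income"`,
#'   `"size_class"`, `"baseline_mean_haz_tertile"`.
#' @return Factor of length `nrow(units)`.
#' @export
derive_stratum <- function(units, stratifier = c("region", "year_period",
                                                 "income", "size_class",
                                                 "baseline_mean_haz_tertile")) {
  stratifier <- match.arg(stratifier)
  survey_tertile <- function(value_by_unit) {
    per_survey <- tapply(value_by_unit, units$survey_id, function(v) v[1])
    br <- stats::quantile(per_survey, c(0, 1 / 3, 2 / 3, 1), na.rm = TRUE,
                          names = FALSE)
    br <- unique(br)
    if (length(br) < 2) {
      return(factor(rep("T1", length(value_by_unit))))
    }
    cut(value_by_unit, breaks = br, include.lowest = TRUE,
        labels = paste0("T", seq_len(length(br) - 1)))
  }
  switch(stratifier,
         region = factor(units$region),
         income = factor(units$income_class),
         year_period = cut(units$survey_year,
                           breaks = c(-Inf, 1994, 1999, 2004, 2009, Inf),
                           labels = c("1993-94", "1995-99", "2000-04",
                                      "2005-09", "2010-15")),
         size_class = survey_tertile(units$n_children),
         baseline_mean_haz_tertile = survey_tertile(units$baseline_mean_haz))
}

#' Stratum-specific slopes from a single interaction model
#'
#' Fits one model per stratifier with stratum main effects and
#' stratum-by-predictor interactions (`y ~ 0 + stratum + x:stratum + random
#' terms`), sharing the random structure and residual variance across strata.
#' Strata contributing fewer than two surveys are excluded and flagged.
#'
#' @param units a `survey_age_units` data frame.
#' @param outcome outcome column.
#' @param stratifier see [derive_stratum()]; alternatively supply a factor
#'   via `stratum`.
#' @param stratum optional explicit factor (length `nrow(units)`) overriding
#'   `stratifier`.
#' @param conf_level confidence level.
#' @param control an [lme4::lmerControl()].
#' @return Data frame with one row per stratum: `stratum`, `n_surveys`,
#'   `slope`, `ci_low`, `ci_high`; excluded strata are recorded in the
#'   `"excluded_strata"` attribute.
#' @export
fit_stratified <- function(units, outcome = "sd", stratifier = "region",
                           stratum = NULL, conf_level = 0.95,
                           control = lmer_control_default()) {
  stopifnot(outcome %in% names(units))
  if (is.null(stratum)) stratum <- derive_stratum(units, stratifier)
  stratum <- factor(stratum)
  stopifnot(length(stratum) == nrow(units))
  surveys_per_stratum <- tapply(units$survey_id, stratum,
                                function(s) length(unique(s)))
  surveys_per_stratum[is.na(surveys_per_stratum)] <- 0
  ok <- names(surveys_per_stratum)[surveys_per_stratum >= 2]
  excluded <- setdiff(levels(stratum), ok)
  keep <- stratum %in% ok
  df <- data.frame(y = units[[outcome]][keep],
                   x = -units$mean[keep],
                   stratum = droplevels(stratum[keep]),
                   survey_id = factor(units$survey_id[keep]),
                   country_id = factor(units$country_id[keep]))
  if (nlevels(df$stratum) == 0L) stop("no stratum has >= 2 surveys", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  if (nlevels(df$stratum) == 1L) {
    fit <- fit_three_level(cbind(units[keep, c("country_id", "survey_id")],
                                 mean = units$mean[keep],
                                 stats::setNames(data.frame(units[[outcome]][keep]),
                                                 outcome)),
                           outcome = outcome, conf_level = conf_level,
                           control = control)
    out <- data.frame(stratum = levels(df$stratum),
                      n_surveys = length(unique(df$survey_id)),
                      slope = fit$slope, ci_low = fit$slope_ci[1],
                      ci_high = fit$slope_ci[2], stringsAsFactors = FALSE)
  } else {
    model <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ 0 + stratum + stratum:x + (1 | country_id) +
                   (1 + x | survey_id),
                 data = df, REML = TRUE, control = control)))
    fe <- lme4::fixef(model)
    vcv <- as.matrix(stats::vcov(model))
    lev <- levels(df$stratum)
    nm <- paste0("stratum", lev, ":x")
    slopes <- fe[nm]
    ses <- sqrt(diag(vcv)[nm])
    out <- data.frame(stratum = lev,
                      n_surveys = as.integer(surveys_per_stratum[lev]),
                      slope = as.numeric(slopes),
                      ci_low = as.numeric(slopes - z * ses),
                      ci_high = as.numeric(slopes + z * ses),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "excluded_strata") <- excluded
  out
}

#' Per-survey ordinary-least-squares slopes
#'
#' Within-survey OLS of the outcome on `x = -mean`, equivalent to the
#' saturated survey-by-predictor interaction model; used for forest plots of
#' survey-specific associations. Surveys without predictor variation get an
#' `NA` slope with a flag; CIs use the within-survey t distribution and
#' require at least 3 units.
#'
#' @param units a `survey_age_units` data frame.
#' @param outcome outcome column.
#' @param conf_level confidence level.
#' @return Data frame: `survey_id`, `n_units`, `slope`, `ci_low`, `ci_high`,
#'   `flag` (`"ok"`, `"no_predictor_variation"`, or `"too_few_units"`).
#' @export
survey_fixed_effects_slopes <- function(units, outcome = "sd",
                                        conf_level = 0.95) {
  stopifnot(outcome %in% names(units))
  idx <- split(seq_len(nrow(units)), units$survey_id)
  rows <- lapply(names(idx), function(sid) {
    i <- idx[[sid]]
    x <- -units$mean[i]
    y <- units[[outcome]][i]
    n <- length(i)
    if (n < 2L) {
      return(data.frame(survey_id = sid, n_units = n, slope = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        flag = "too_few_units", stringsAsFactors = FALSE))
    }
    if (stats::sd(x) == 0) {
      return(data.frame(survey_id = sid, n_units = n, slope = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        flag = "no_predictor_variation", stringsAsFactors = FALSE))
    }
    f <- stats::lm(y ~ x)
    sl <- stats::coef(f)[["x"]]
    if (n >= 3L) {
      se <- suppressWarnings(summary(f))$coefficients["x", "Std. Error"]
      crit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
      lo <- sl - crit * se
      hi <- sl + crit * se
    } else {
      lo <- hi <- NA_real_
    }
    data.frame(survey_id = sid, n_units = n, slope = sl, ci_low = lo,
               ci_high = hi, flag = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' BLUP (shrinkage) survey slopes from a three-level fit
#'
#' Each survey's predicted slope is the fixed slope plus the best linear
#' unbiased prediction of its random slope deviation. When the random-slope
#' variance is singular (zero) every survey's BLUP equals the fixed slope;
#' in general BLUP slopes are shrunk towards the fixed slope and have no
#' larger spread than per-survey OLS slopes.
#'
#' @param fit a `haz_threelevel_fit`.
#' @return Data frame: `survey_id`, `blup_slope`.
#' @export
blup_survey_slopes <- function(fit) {
  stopifnot(inherits(fit, "haz_threelevel_fit"))
  if (!isTRUE(fit$converged)) {
    stop("model did not converge; BLUPs not available", call. = FALSE)
  }
  fit$blup_slopes
}

#' Parametric-bootstrap CIs for the ICCs
#'
#' Refits the model on `nsim` parametric simulations from the fitted model
#' and returns percentile intervals for both ICCs. Bootstrap is an
#' implementation choice for interval estimation of variance-ratio
#' quantities, whose Wald intervals behave poorly.
#'
#' @param fit a non-degenerate `haz_threelevel_fit`.
#' @param nsim number of parametric simulations.
#' @param conf_level confidence level.
#' @param seed integer seed.
#' @return Matrix with rows `icc_country`, `icc_survey_in_country` and
#'   columns `estimate`, `ci_low`, `ci_high`.
#' @export
icc_bootstrap_ci <- function(fit, nsim = 200, conf_level = 0.95, seed = 1L) {
  stopifnot(inherits(fit, "haz_threelevel_fit"))
  if (fit$degenerate) stop("degenerate fit: no model to bootstrap", call. = FALSE)
  set.seed(seed)
  model <- fit$model
  sims <- stats::simulate(model, nsim = nsim)
  draws <- vapply(seq_len(nsim), function(j) {
    m <- tryCatch(suppressMessages(suppressWarnings(
      lme4::refit(model, newresp = sims[[j]]))), error = function(e) NULL)
    if (is.null(m)) return(c(NA_real_, NA_real_))
    vc_df <- as.data.frame(lme4::VarCorr(m))
    vc <- c(var_country = sum(vc_df$vcov[vc_df$grp == "country_id" &
                                           vc_df$var1 == "(Intercept)"]),
            var_survey_intercept = sum(vc_df$vcov[vc_df$grp == "survey_id" &
                                                    vc_df$var1 == "(Intercept)" &
                                                    is.na(vc_df$var2)]),
            var_residual = vc_df$vcov[vc_df$grp == "Residual"][1])
    unname(icc_from_components(c(vc, var_survey_slope = 0, cov_survey = 0)))
  }, numeric(2))
  a <- (1 - conf_level) / 2
  qs <- apply(draws, 1, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  out <- cbind(estimate = c(fit$icc_country, fit$icc_survey_in_country),
               ci_low = qs[1, ], ci_high = qs[2, ])
  rownames(out) <- c("icc_country", "icc_survey_in_country")
  out
}

#' Simulate survey-age units directly from the three-level model
#'
#' Generates unit-level data from the generative counterpart of the fitted
#' model -- country intercepts, correlated survey intercepts and slopes, and
#' unit residuals around a linear trend in `x = -mean` -- for parameter
#' recovery and CI-coverage studies at unit level without the expense of
#' child-level simulation.
#'
#' @param n_countries,surveys_per_country,n_bands design dimensions.
#' @param intercept,slope fixed effects (outcome at mean HAZ 0; change per
#'   1-unit decline in mean HAZ).
#' @param sd_country,sd_survey_intercept,sd_survey_slope,sd_residual SDs of
#'   the random terms.
#' @param slope_intercept_corr correlation of survey intercepts and slopes.
#' @param x_values predictor values (sign-reversed mean HAZ) per band;
#'   default an even grid from 0.4 to 2.0 mimicking the age-related decline
#'   of mean HAZ from -0.4 to -2.
#' @param outcome name of the generated outcome column.
#' @param seed integer seed.
#' @return Data frame usable by [fit_three_level()]: `country_id`,
#'   `survey_id`, `band_index`, `mean` (= `-x`), the outcome column, and the
#'   true per-survey slopes in the `"true_survey_slopes"` attribute.
#' @export
simulate_unit_data <- function(n_countries = 20, surveys_per_country = 5,
                               n_bands = 12, intercept = 2.10, slope = -0.20,
                               sd_country = 0.10, sd_survey_intercept = 0.10,
                               sd_survey_slope = 0.05,
                               slope_intercept_corr = 0, sd_residual = 0.10,
                               x_values = seq(0.4, 2.0, length.out = n_bands),
                               outcome = "sd", seed = 1L) {
  stopifnot(n_countries >= 1, surveys_per_country >= 1, n_bands >= 1,
            length(x_values) == n_bands, abs(slope_intercept_corr) <= 1)
  set.seed(seed)
  n_s <- n_countries * surveys_per_country
  country <- rep(seq_len(n_countries), each = surveys_per_country)
  b_c <- stats::rnorm(n_countries, 0, sd_country)
  z1 <- stats::rnorm(n_s)
  z2 <- stats::rnorm(n_s)
  b_s <- sd_survey_intercept * z1
  u_s <- sd_survey_slope * (slope_intercept_corr * z1 +
                              sqrt(1 - slope_intercept_corr^2) * z2)
  survey_id <- sprintf("C%03d-S%02d", country,
                       rep(seq_len(surveys_per_country), n_countries))
  idx <- rep(seq_len(n_s), each = n_bands)
  x <- rep(x_values, n_s)
  y <- intercept + b_c[country][idx] + b_s[idx] + (slope + u_s[idx]) * x +
    stats::rnorm(n_s * n_bands, 0, sd_residual)
  out <- data.frame(country_id = sprintf("C%03d", country[idx]),
                    survey_id = survey_id[idx],
                    band_index = rep(seq_len(n_bands) - 1L, n_s),
                    mean = -x, stringsAsFactors = FALSE)
  out[[outcome]] <- y
  attr(out, "true_survey_slopes") <-
    data.frame(survey_id = survey_id, true_slope = slope + u_s,
               stringsAsFactors = FALSE)
  out
}
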