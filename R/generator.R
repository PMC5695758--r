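## Synthetic multi-survey generator -----------------------------------------
##
## Emulates the hierarchical structure of multi-country household surveys of
## child anthropometry: countries contain surveys, surveys contain measured
## children with an age in days, an observed HAZ and a probability sampling
## weight. The generator is fully parameterised by age curves (true mean HAZ,
## true biological SD, measurement-error SD) so downstream estimators can be
## validated against a configured truth.

CHILD_COLUMNS <- c("country_id", "survey_id", "survey_year", "age_days",
                   "haz", "weight")
META_COLUMNS <- c("survey_id", "country_id", "survey_year", "region",
                  "income_class", "n_children", "baseline_mean_haz")

#' Default survey-level covariate scheme
#'
#' Categorical distributions used to label surveys with a world region, a
#' national income class and a survey year. The default probabilities follow
#' the composition of a large multi-country compilation of household surveys
#' (1993-2015): sub-Saharan Africa dominates, most surveys are from low-income
#' countries, and later calendar periods contribute more surveys.
#'
#' @return A list with elements `region_levels`, `region_probs`,
#'   `income_levels`, `income_probs`, `year_breaks` (period boundaries) and
#'   `year_probs` (probability of each period; years are uniform within the
#'   sampled period).
#' @export
default_covariate_scheme <- function() {
  list(
    region_levels = c("East Asia & Pacific", "Europe & Central Asia",
                      "Latin America & Caribbean", "Middle East & North Africa",
                      "South Asia", "Sub-Saharan Africa"),
    region_probs = c(5, 15, 33, 10, 14, 102) / 179,
    income_levels = c("Low income", "Lower middle income", "Upper middle income"),
    income_probs = c(107, 59, 13) / 179,
    year_breaks = list(c(1993, 1994), c(1995, 1999), c(2000, 2004),
                       c(2005, 2009), c(2010, 2015)),
    year_probs = c(8, 39, 34, 45, 53) / 179
  )
}

#' Configuration of the synthetic multi-survey generator
#'
#' Defaults reproduce the scale and shape of the survey compilation the
#' package emulates: 179 surveys in 64 countries, right-skewed survey sizes
#' (median near 3159 children, clipped to 351-27352), children aged 0-36
#' months, a population mean HAZ that starts below zero at birth and declines
#' through infancy, and measurement error that is larger at younger ages.
#'
#' @param n_countries number of countries.
#' @param n_surveys total number of surveys; allocated across countries with a
#'   right-skewed default allocation (a quarter of countries contribute one
#'   survey, a fifth two, the rest more) unless `surveys_per_country` is given.
#' @param surveys_per_country optional integer vector (length `n_countries`)
#'   or scalar overriding the default allocation.
#' @param children_per_survey either a single count, a vector of counts (one
#'   per survey), or a list `list(meanlog, sdlog, min, max)` describing a
#'   clipped log-normal draw. The default log-normal (meanlog = log(3159),
#'   sdlog = 0.571) matches a median of 3159 and an IQR near 2495.
#' @param age_range_days half-open interval of ages in days, default `[0, 1096)`
#'   (0-36 months); ages are sampled uniformly as integer days.
#' @param mean_haz_curve function: age in days -> true population mean HAZ.
#' @param sd_curve function: age -> true biological SD of HAZ (>= 0).
#' @param measurement_error_curve function: age -> SD of zero-mean
#'   age-specific measurement error added to the true HAZ (>= 0).
#' @param country_intercept_sd,survey_intercept_sd SDs of zero-mean Gaussian
#'   shifts of the mean curve at country and survey level; zero-mean, so the
#'   configured curve remains the truth in expectation.
#' @param survey_slope_mult_sd SD of a per-survey multiplier on the age-related
#'   change of the mean curve (multiplier has mean 1), creating between-survey
#'   heterogeneity in faltering rate.
#' @param weight_scheme `"uniform"` or `"lognormal-dispersed"` design weights.
#' @param weight_dispersion log-scale SD of log-normal weights.
#' @param covariate_scheme see [default_covariate_scheme()].
#' @param seed integer seed; identical config + seed gives identical output.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_countries = 64L,
                             n_surveys = 179L,
                             surveys_per_country = NULL,
                             children_per_survey = list(meanlog = log(3159),
                                                        sdlog = 0.571,
                                                        min = 351L, max = 27352L),
                             age_range_days = c(0L, 1096L),
                             mean_haz_curve = haz_curve_piecewise(
                               c(0, 730, 1095), c(-0.4, -1.9, -1.85)),
                             sd_curve = haz_curve_constant(1.1),
                             measurement_error_curve = haz_curve_piecewise(
                               c(0, 1095), c(0.5, 0.2)),
                             country_intercept_sd = 0.45,
                             survey_intercept_sd = 0.25,
                             survey_slope_mult_sd = 0.15,
                             weight_scheme = c("lognormal-dispersed", "uniform"),
                             weight_dispersion = 0.5,
                             covariate_scheme = default_covariate_scheme(),
                             seed = 1L) {
  weight_scheme <- match.arg(weight_scheme)
  stopifnot(n_countries >= 0, n_surveys >= 0,
            length(age_range_days) == 2L,
            age_range_days[1] >= 0, age_range_days[2] <= 1096,
            age_range_days[2] > age_range_days[1],
            country_intercept_sd >= 0, survey_intercept_sd >= 0,
            survey_slope_mult_sd >= 0, weight_dispersion >= 0,
            is.numeric(seed), length(seed) == 1L)
  if (!is.null(surveys_per_country)) {
    if (length(surveys_per_country) == 1L) {
      surveys_per_country <- rep_len(as.integer(surveys_per_country), n_countries)
    }
    stopifnot(length(surveys_per_country) == n_countries,
              all(surveys_per_country >= 0))
    n_surveys <- sum(surveys_per_country)
  }
  if (is.list(children_per_survey)) {
    stopifnot(all(c("meanlog", "sdlog", "min", "max") %in%
                    names(children_per_survey)),
              children_per_survey$sdlog >= 0,
              children_per_survey$min >= 0,
              children_per_survey$max >= children_per_survey$min)
  } else {
    stopifnot(is.numeric(children_per_survey), all(children_per_survey >= 0))
  }
  cfg <- list(
    n_countries = as.integer(n_countries),
    n_surveys = as.integer(n_surveys),
    surveys_per_country = surveys_per_country,
    children_per_survey = children_per_survey,
    age_range_days = as.integer(age_range_days),
    mean_haz_curve = as_haz_curve(mean_haz_curve, "mean_haz_curve"),
    sd_curve = as_haz_curve(sd_curve, "sd_curve", nonnegative = TRUE),
    measurement_error_curve = as_haz_curve(measurement_error_curve,
                                           "measurement_error_curve",
                                           nonnegative = TRUE),
    country_intercept_sd = country_intercept_sd,
    survey_intercept_sd = survey_intercept_sd,
    survey_slope_mult_sd = survey_slope_mult_sd,
    weight_scheme = weight_scheme,
    weight_dispersion = weight_dispersion,
    covariate_scheme = covariate_scheme,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic multi-survey generator configuration\n")
  cat(sprintf("  %d surveys in %d countries; ages [%d, %d) days\n",
              x$n_surveys, x$n_countries, x$age_range_days[1], x$age_range_days[2]))
  if (is.list(x$children_per_survey)) {
    cat(sprintf("  children/survey ~ clipped log-normal (median %.0f, range [%d, %d])\n",
                exp(x$children_per_survey$meanlog),
                x$children_per_survey$min, x$children_per_survey$max))
  } else {
    cat(sprintf("  children/survey: %s\n",
                paste(utils::head(x$children_per_survey, 5), collapse = ", ")))
  }
  cat(sprintf("  weight scheme: %s; seed: %d\n", x$weight_scheme, x$seed))
  invisible(x)
}

## Right-skewed allocation of surveys to countries: ~25% of countries get one
## survey, ~20% two, the remainder share the rest as evenly as possible.
allocate_surveys <- function(n_countries, n_surveys) {
  if (n_countries == 0L || n_surveys == 0L) return(integer(n_countries))
  if (n_surveys < n_countries) {
    stop("n_surveys must be >= n_countries unless surveys_per_country is given",
         call. = FALSE)
  }
  n1 <- floor(0.25 * n_countries)
  n2 <- floor(0.20 * n_countries)
  n_rest <- n_countries - n1 - n2
  remaining <- n_surveys - n1 - 2L * n2
  if (n_rest == 0L || remaining < 3L * n_rest) {
    # too few surveys for the skewed shape; spread evenly instead
    alloc <- rep(n_surveys %/% n_countries, n_countries)
    extra <- n_surveys %% n_countries
    if (extra > 0) alloc[seq_len(extra)] <- alloc[seq_len(extra)] + 1L
    return(as.integer(alloc))
  }
  base <- remaining %/% n_rest
  extra <- remaining %% n_rest
  rest <- rep(base, n_rest)
  if (extra > 0) rest[seq_len(extra)] <- rest[seq_len(extra)] + 1L
  as.integer(c(rep(1L, n1), rep(2L, n2), rest))
}

empty_child_table <- function() {
  data.frame(country_id = character(), survey_id = character(),
             survey_year = integer(), age_days = integer(),
             haz = numeric(), weight = numeric(), stringsAsFactors = FALSE)
}

#' Generate a synthetic hierarchical multi-survey dataset
#'
#' Draws a full child-level dataset (one row per measured child) together with
#' a survey-level metadata table. Per-survey true mean and SD at any age equal
#' the configured curves in expectation: country- and survey-level shifts are
#' zero-mean and the per-survey slope multiplier has mean one.
#'
#' @param config a [generator_config()].
#' @return A list with elements `children` (columns `country_id`, `survey_id`,
#'   `survey_year`, `age_days`, `haz`, `weight`) and `surveys` (columns
#'   `survey_id`, `country_id`, `survey_year`, `region`, `income_class`,
#'   `n_children`, `baseline_mean_haz` -- the weighted mean observed HAZ of
#'   that survey's 0-3 month children, `NA` if none).
#' @export
generate_multisurvey_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n_c <- config$n_countries
  alloc <- if (!is.null(config$surveys_per_country)) {
    as.integer(config$surveys_per_country)
  } else {
    allocate_surveys(n_c, config$n_surveys)
  }
  n_s <- sum(alloc)
  if (n_c == 0L || n_s == 0L) {
    surveys <- data.frame(survey_id = character(), country_id = character(),
                          survey_year = integer(), region = character(),
                          income_class = character(), n_children = integer(),
                          baseline_mean_haz = numeric(), stringsAsFactors = FALSE)
    return(list(children = empty_child_table(), surveys = surveys))
  }

  cs <- config$covariate_scheme
  country_id <- sprintf("C%03d", seq_len(n_c))
  region_c <- sample(cs$region_levels, n_c, replace = TRUE, prob = cs$region_probs)
  income_c <- sample(cs$income_levels, n_c, replace = TRUE, prob = cs$income_probs)
  b_country <- stats::rnorm(n_c, 0, config$country_intercept_sd)

  svy_country <- rep(seq_len(n_c), alloc)
  svy_seq <- unlist(lapply(alloc, seq_len), use.names = FALSE)
  survey_id <- sprintf("%s-S%02d", country_id[svy_country], svy_seq)
  period <- sample(seq_along(cs$year_probs), n_s, replace = TRUE,
                   prob = cs$year_probs)
  survey_year <- vapply(period, function(p) {
    rng <- cs$year_breaks[[p]]
    as.integer(sample(seq(rng[1], rng[2]), 1L))
  }, integer(1))
  b_survey <- stats::rnorm(n_s, 0, config$survey_intercept_sd)
  slope_mult <- 1 + stats::rnorm(n_s, 0, config$survey_slope_mult_sd)

  cps <- config$children_per_survey
  n_k <- if (is.list(cps)) {
    pmin(pmax(round(stats::rlnorm(n_s, cps$meanlog, cps$sdlog)), cps$min), cps$max)
  } else {
    rep_len(as.integer(round(cps)), n_s)
  }
  n_k <- as.integer(n_k)

  n_total <- sum(n_k)
  child_svy <- rep(seq_len(n_s), n_k)
  a0 <- config$age_range_days[1]
  a1 <- config$age_range_days[2]
  age_days <- a0 + as.integer(floor(stats::runif(n_total) * (a1 - a0)))
  mu0 <- config$mean_haz_curve(0)
  drop_age <- config$mean_haz_curve(age_days) - mu0
  true_mean <- b_country[svy_country][child_svy] + b_survey[child_svy] +
    mu0 + slope_mult[child_svy] * drop_age
  haz <- true_mean + stats::rnorm(n_total, 0, config$sd_curve(age_days))

  children <- data.frame(
    country_id = country_id[svy_country][child_svy],
    survey_id = survey_id[child_svy],
    survey_year = survey_year[child_svy],
    age_days = age_days,
    haz = haz,
    weight = rep(1, n_total),
    stringsAsFactors = FALSE
  )
  children <- inject_measurement_error(children, config$measurement_error_curve)
  children <- simulate_design_weights(children, config$weight_scheme,
                                      dispersion = config$weight_dispersion)

  baseline <- rep(NA_real_, n_s)
  in_band0 <- children$age_days < 91.3
  if (any(in_band0)) {
    idx0 <- which(in_band0)
    sums <- tapply(children$haz[idx0] * children$weight[idx0],
                   children$survey_id[idx0], sum)
    wsum <- tapply(children$weight[idx0], children$survey_id[idx0], sum)
    baseline[match(names(sums), survey_id)] <- as.numeric(sums / wsum)
  }

  surveys <- data.frame(
    survey_id = survey_id,
    country_id = country_id[svy_country],
    survey_year = survey_year,
    region = region_c[svy_country],
    income_class = income_c[svy_country],
    n_children = n_k,
    baseline_mean_haz = baseline,
    stringsAsFactors = FALSE
  )
  list(children = children, surveys = surveys)
}

#' Add age-specific measurement error to observed HAZ
#'
#' Adds independent zero-mean Gaussian noise whose SD is a function of child
#' age, emulating age-differential measurement error (larger errors in young
#' infants from length measurement, birth-date recall and unaccounted
#' gestational age). The input table is not modified.
#'
#' @param records child-record data frame with `age_days` and `haz` columns.
#' @param error_curve function: age in days -> error SD (>= 0), or a single
#'   number for a constant SD.
#' @param seed optional integer seed; if `NULL` the current RNG stream is used.
#' @return A copy of `records` with noise added to `haz`.
#' @export
inject_measurement_error <- function(records, error_curve, seed = NULL) {
  error_curve <- as_haz_curve(error_curve, "error_curve", nonnegative = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  if (n == 0L) return(records)
  sds <- error_curve(records$age_days)
  if (any(sds < 0)) stop("error_curve must be non-negative", call. = FALSE)
  records$haz <- records$haz + stats::rnorm(n, 0, sds)
  records
}

#' Simulate design (probability sampling) weights
#'
#' @param records child-record data frame.
#' @param scheme `"uniform"` (all weights 1) or `"lognormal-dispersed"`
#'   (log-normal weights with log-scale SD `dispersion`).
#' @param dispersion log-scale SD for the log-normal scheme; 0 degenerates to
#'   equal weights.
#' @param haz_correlation optional correlation in \[-1, 1\] between log-weight
#'   and HAZ, for stress-testing weighted estimators; the default 0 keeps
#'   weights independent of HAZ so weighted estimators are unbiased for the
#'   configured truth.
#' @param seed optional integer seed.
#' @return `records` with the `weight` column replaced.
#' @export
simulate_design_weights <- function(records,
                                    scheme = c("uniform", "lognormal-dispersed"),
                                    dispersion = 0.5, haz_correlation = 0,
                                    seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(dispersion >= 0, abs(haz_correlation) <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(records)
  if (n == 0L) return(records)
  if (scheme == "uniform" || dispersion == 0) {
    records$weight <- rep(1, n)
    return(records)
  }
  z <- stats::rnorm(n)
  if (haz_correlation != 0) {
    hz <- as.numeric(scale(records$haz))
    hz[is.na(hz)] <- 0
    z <- haz_correlation * hz + sqrt(1 - haz_correlation^2) * z
  }
  records$weight <- exp(dispersion * z)
  records
}
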