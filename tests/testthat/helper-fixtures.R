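# Shared fixture builders; all synthetic, built in code at test time.

# Small hierarchical dataset: 2 countries x 2 surveys x `children` children.
tiny_dataset <- function(children = 400, seed = 11, ...) {
  cfg <- generator_config(n_countries = 2, n_surveys = 4,
                          children_per_survey = children, seed = seed, ...)
  generate_multisurvey_dataset(cfg)
}

# Generator config with all between-survey heterogeneity and measurement
# error switched off, so child HAZ ~ N(mean_curve(age), sd_curve(age)).
flat_config <- function(n_surveys = 1, n_countries = 1, children = 1000,
                        mean = -0.5, sd = 1, seed = 5) {
  generator_config(
    n_countries = n_countries, n_surveys = n_surveys,
    surveys_per_country = rep(ceiling(n_surveys / n_countries), n_countries),
    children_per_survey = children,
    mean_haz_curve = haz_curve_constant(mean),
    sd_curve = haz_curve_constant(sd),
    measurement_error_curve = haz_curve_constant(0),
    country_intercept_sd = 0, survey_intercept_sd = 0,
    survey_slope_mult_sd = 0, weight_scheme = "uniform", seed = seed)
}

# Minimal survey-age-unit table from explicit parameter values.
units_from_values <- function(values, country, survey = NULL, band = 0L,
                              parameter = "sd") {
  if (is.null(survey)) survey <- paste0(country, "-S", seq_along(values))
  df <- data.frame(survey_id = survey, country_id = country,
                   band_index = band, mean = -1, stringsAsFactors = FALSE)
  df[[parameter]] <- values
  df
}

# Unweighted analogues used as independent oracles for the weighted
# estimators: population-form SD and the ECDF-interpolation (type 4) quantile.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
q4 <- function(x, p) unname(stats::quantile(x, p, type = 4))
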