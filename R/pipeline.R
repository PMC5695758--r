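## End-to-end pipeline -------------------------------------------------------
##
## generate -> band/filter -> survey-age units -> pooled band summaries ->
## three-level models -> faltering simulations, from a single configuration,
## with per-stage seeds derived from one global seed and every stage output
## written as CSV so each step stays inspectable.

#' Pipeline configuration
#'
#' @param generator a [generator_config()].
#' @param banding a [banding_config()].
#' @param model_outcomes distributional parameters to model (subset of
#'   `"sd"`, `"median"`, `"dp5"`, `"dp95"`).
#' @param stratifiers stratifiers for interaction models (see
#'   [derive_stratum()]); empty to skip.
#' @param sensitivity optional single switch applied to the banding/filter
#'   stage: `"age_lt_24m"` (restrict to under 24 months), `"limit_6"`
#'   (plausibility bound 6), `"bands_1m"` (30.44-day bands), `"bands_6m"`
#'   (182.6-day bands), or `NULL` for the primary analysis.
#' @param scenarios list of [sim_scenario()] objects; the default runs the
#'   four exposure fractions 25/50/75/100%.
#' @param output_dir directory for stage outputs.
#' @param global_seed single integer; per-stage seeds are derived as
#'   `(global_seed * 7 + stage_index * 1000003) mod (2^31 - 1)` so stages are
#'   reproducible independently.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            banding = banding_config(),
                            model_outcomes = c("sd", "median", "dp5", "dp95"),
                            stratifiers = character(),
                            sensitivity = NULL,
                            scenarios = NULL,
                            output_dir = tempfile("hazshift-run-"),
                            global_seed = 1L) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(banding, "banding_config"),
            all(model_outcomes %in% MODEL_OUTCOMES))
  if (!is.null(sensitivity)) {
    sensitivity <- match.arg(sensitivity,
                             c("age_lt_24m", "limit_6", "bands_1m", "bands_6m"))
  }
  if (is.null(scenarios)) {
    scenarios <- lapply(c(0.25, 0.5, 0.75, 1), function(p) {
      sim_scenario(p_exposed = p, seed = global_seed)
    })
    names(scenarios) <- sprintf("p%02.0f", 100 * c(0.25, 0.5, 0.75, 1))
  }
  stopifnot(all(vapply(scenarios, inherits, logical(1), "sim_scenario")))
  if (is.null(names(scenarios))) {
    names(scenarios) <- sprintf("scenario%d", seq_along(scenarios))
  }
  structure(list(generator = generator, banding = banding,
                 model_outcomes = model_outcomes, stratifiers = stratifiers,
                 sensitivity = sensitivity, scenarios = scenarios,
                 output_dir = output_dir,
                 global_seed = as.integer(global_seed)),
            class = "pipeline_config")
}

stage_seed <- function(global_seed, stage_index) {
  as.integer((as.numeric(global_seed) * 7 + stage_index * 1000003) %%
               2147483647)
}

## Apply a sensitivity switch to the banding/filtering stage.
apply_sensitivity <- function(banding, sensitivity, generator) {
  age_max <- NULL
  if (is.null(sensitivity)) return(list(banding = banding, age_max = age_max))
  switch(sensitivity,
         age_lt_24m = {
           # 24 months = 8 bands of 91.3 days
           banding <- banding_config(banding$band_width_days, 8L,
                                     banding$plausibility_limit,
                                     banding$min_children_per_unit,
                                     banding$sd_divisor)
           age_max <- 730.4
         },
         limit_6 = {
           banding <- banding_config(banding$band_width_days, banding$n_bands,
                                     6, banding$min_children_per_unit,
                                     banding$sd_divisor)
         },
         bands_1m = {
           banding <- banding_config(365.25 / 12, 36L,
                                     banding$plausibility_limit,
                                     banding$min_children_per_unit,
                                     banding$sd_divisor)
         },
         bands_6m = {
           banding <- banding_config(365.25 / 2, 6L,
                                     banding$plausibility_limit,
                                     banding$min_children_per_unit,
                                     banding$sd_divisor)
         })
  list(banding = banding, age_max = age_max)
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the requested stages in order, writes each stage's output as CSV
#' under `config$output_dir`, and returns a run manifest recording seeds,
#' row counts, exclusion counts and output files. Re-running with the same
#' config and seed reproduces byte-identical CSVs.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of `c("generate", "units", "pool", "fit",
#'   "simulate")` (report is rendered separately via [render_report()]).
#' @return Object of class `run_manifest` (invisibly a list): configuration
#'   hash, per-stage seeds, row counts, exclusion counts, output files and
#'   timestamps.
#' @export
run_pipeline <- function(config,
                         stages = c("generate", "units", "pool", "fit",
                                    "simulate")) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("hazshift")),
                   global_seed = config$global_seed,
                   started = format(Sys.time(), tz = "UTC"),
                   stages = list(), files = character(),
                   counts = list(), exclusions = list())

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  dataset <- NULL
  if ("generate" %in% stages) {
    run_stage("generate", function() {
      gen <- config$generator
      gen$seed <- stage_seed(config$global_seed, 1L)
      dataset <<- generate_multisurvey_dataset(gen)
      manifest$files <<- c(manifest$files,
                           write_stage_csv(dataset$children, config$output_dir,
                                           "children.csv"),
                           write_stage_csv(dataset$surveys, config$output_dir,
                                           "surveys.csv"))
      manifest$stages$generate <<- list(seed = gen$seed)
      manifest$counts$children <<- nrow(dataset$children)
      manifest$counts$surveys <<- nrow(dataset$surveys)
      manifest$counts$countries <<- length(unique(dataset$surveys$country_id))
    })
  } else {
    ch_path <- file.path(config$output_dir, "children.csv")
    sv_path <- file.path(config$output_dir, "surveys.csv")
    if (file.exists(ch_path) && file.exists(sv_path)) {
      dataset <- list(children = utils::read.csv(ch_path, stringsAsFactors = FALSE),
                      surveys = utils::read.csv(sv_path, stringsAsFactors = FALSE))
    }
  }

  units <- NULL
  if ("units" %in% stages) {
    if (is.null(dataset)) stop("units stage requires generated data", call. = FALSE)
    run_stage("units", function() {
      sens <- apply_sensitivity(config$banding, config$sensitivity,
                                config$generator)
      children <- dataset$children
      if (!is.null(sens$age_max)) {
        children <- children[children$age_days < sens$age_max, , drop = FALSE]
      }
      units <<- build_survey_age_units(children, dataset$surveys, sens$banding)
      excl <- attr(units, "exclusions")
      manifest$exclusions <<- as.list(excl)
      manifest$counts$units <<- nrow(units)
      # children in = banded + implausible + out-of-range (+ age restriction)
      banded <- sum(units$n)
      stopifnot(banded + sum(excl) == nrow(children))
      manifest$files <<- c(manifest$files,
                           write_stage_csv(as.data.frame(units),
                                           config$output_dir, "units.csv"))
      manifest$stages$units <<- list(sensitivity = config$sensitivity)
    })
  }

  if ("pool" %in% stages) {
    if (is.null(units)) stop("pool stage requires units", call. = FALSE)
    run_stage("pool", function() {
      pooled <- summarize_all_bands(units)
      manifest$counts$pooled_rows <<- nrow(pooled)
      manifest$files <<- c(manifest$files,
                           write_stage_csv(pooled, config$output_dir,
                                           "band_summaries.csv"))
      manifest$stages$pool <<- list(method = "cluster_robust")
    })
  }

  if ("fit" %in% stages) {
    if (is.null(units)) stop("fit stage requires units", call. = FALSE)
    run_stage("fit", function() {
      coefs <- do.call(rbind, lapply(config$model_outcomes, function(oc) {
        fit <- fit_three_level(units, outcome = oc)
        pred <- predict_at(fit, -2)
        data.frame(outcome = oc,
                   slope = fit$slope,
                   slope_ci_low = fit$slope_ci[1],
                   slope_ci_high = fit$slope_ci[2],
                   intercept = fit$intercept,
                   intercept_ci_low = fit$intercept_ci[1],
                   intercept_ci_high = fit$intercept_ci[2],
                   predicted_at_minus2 = pred[["estimate"]],
                   predicted_ci_low = pred[["ci_low"]],
                   predicted_ci_high = pred[["ci_high"]],
                   icc_country = fit$icc_country,
                   icc_survey_in_country = fit$icc_survey_in_country,
                   converged = fit$converged, stringsAsFactors = FALSE)
      }))
      manifest$files <<- c(manifest$files,
                           write_stage_csv(coefs, config$output_dir,
                                           "model_coefficients.csv"))
      fit_sd <- fit_three_level(units, outcome = config$model_outcomes[1])
      per_survey <- merge(
        survey_fixed_effects_slopes(units, config$model_outcomes[1]),
        blup_survey_slopes(fit_sd), by = "survey_id", all.x = TRUE)
      manifest$files <<- c(manifest$files,
                           write_stage_csv(per_survey, config$output_dir,
                                           "survey_slopes.csv"))
      if (length(config$stratifiers) > 0) {
        strat <- do.call(rbind, lapply(config$stratifiers, function(sf) {
          s <- fit_stratified(units, config$model_outcomes[1], sf)
          cbind(stratifier = sf, s)
        }))
        manifest$files <<- c(manifest$files,
                             write_stage_csv(strat, config$output_dir,
                                             "stratified_slopes.csv"))
      }
      manifest$stages$fit <<- list(outcomes = config$model_outcomes)
    })
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      sims <- lapply(names(config$scenarios), function(nm) {
        sc <- config$scenarios[[nm]]
        tr <- run_scenario(sc)
        cbind(scenario = nm, tr$summary)
      })
      traj <- do.call(rbind, sims)
      manifest$files <<- c(manifest$files,
                           write_stage_csv(traj, config$output_dir,
                                           "sim_trajectories.csv"))
      manifest$stages$simulate <<-
        list(seeds = vapply(config$scenarios, `[[`, integer(1), "seed"))
    })
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  manifest$files <- unique(manifest$files)
  cfg_path <- file.path(config$output_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest[setdiff(names(manifest), "stages")],
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$output_dir <- config$output_dir
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("hazshift run manifest\n")
  cat(sprintf("  output: %s\n  seed: %d; config hash %s\n",
              x$output_dir, x$global_seed, x$config_hash))
  for (nm in names(x$counts)) cat(sprintf("  %s: %s\n", nm, x$counts[[nm]]))
  cat(sprintf("  files: %s\n", paste(basename(x$files), collapse = ", ")))
  invisible(x)
}

#' Serialise / read a pipeline configuration as YAML
#'
#' Curves are serialised by sampling them on a monthly age grid and are read
#' back as piecewise-linear interpolants of those samples.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_pipeline_config` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  gen <- config$generator
  serialize_curve <- function(curve) {
    spec <- attr(curve, "curve_spec")
    if (!is.null(spec)) return(spec)
    # arbitrary function: sample on a monthly grid, read back as piecewise
    grid <- seq(gen$age_range_days[1], gen$age_range_days[2] - 1, by = 30.44)
    list(type = "piecewise", ages = round(grid, 3),
         values = round(curve(grid), 8))
  }
  g <- list(
    n_countries = gen$n_countries, n_surveys = gen$n_surveys,
    surveys_per_country = gen$surveys_per_country,
    children_per_survey = gen$children_per_survey,
    age_range_days = gen$age_range_days,
    mean_haz_curve = serialize_curve(gen$mean_haz_curve),
    sd_curve = serialize_curve(gen$sd_curve),
    measurement_error_curve = serialize_curve(gen$measurement_error_curve),
    covariate_scheme = lapply(gen$covariate_scheme, function(x)
      if (is.list(x)) lapply(x, as.numeric) else x),
    country_intercept_sd = gen$country_intercept_sd,
    survey_intercept_sd = gen$survey_intercept_sd,
    survey_slope_mult_sd = gen$survey_slope_mult_sd,
    weight_scheme = gen$weight_scheme,
    weight_dispersion = gen$weight_dispersion,
    seed = gen$seed)
  scen <- lapply(config$scenarios, function(s) unclass(s))
  yaml::write_yaml(list(generator = g,
                        banding = unclass(config$banding),
                        model_outcomes = config$model_outcomes,
                        stratifiers = config$stratifiers,
                        sensitivity = config$sensitivity,
                        scenarios = scen,
                        global_seed = config$global_seed), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- y$generator
  deserialize_curve <- function(spec) {
    if (identical(spec$type, "constant")) {
      haz_curve_constant(spec$value)
    } else {
      haz_curve_piecewise(unlist(spec$ages), unlist(spec$values))
    }
  }
  scheme <- if (is.null(g$covariate_scheme)) default_covariate_scheme()
  else g$covariate_scheme
  gen <- generator_config(
    n_countries = g$n_countries, n_surveys = g$n_surveys,
    surveys_per_country = g$surveys_per_country,
    children_per_survey = if (is.list(g$children_per_survey))
      g$children_per_survey else unlist(g$children_per_survey),
    age_range_days = unlist(g$age_range_days),
    mean_haz_curve = deserialize_curve(g$mean_haz_curve),
    sd_curve = deserialize_curve(g$sd_curve),
    measurement_error_curve = deserialize_curve(g$measurement_error_curve),
    covariate_scheme = scheme,
    country_intercept_sd = g$country_intercept_sd,
    survey_intercept_sd = g$survey_intercept_sd,
    survey_slope_mult_sd = g$survey_slope_mult_sd,
    weight_scheme = g$weight_scheme,
    weight_dispersion = g$weight_dispersion,
    seed = g$seed)
  b <- y$banding
  band <- banding_config(b$band_width_days, b$n_bands, b$plausibility_limit,
                         b$min_children_per_unit, b$sd_divisor)
  scen <- lapply(y$scenarios, function(s) {
    sim_scenario(n_children = s$n_children, p_exposed = s$p_exposed,
                 n_decrements = s$n_decrements, decrement = s$decrement,
                 noise_fraction = s$noise_fraction,
                 selection_rule = s$selection_rule,
                 floor = s$floor, floor_mode = s$floor_mode,
                 deficit_gradient = s$deficit_gradient,
                 truncate_gain = isTRUE(s$truncate_gain),
                 n_replications = s$n_replications, seed = s$seed)
  })
  pipeline_config(generator = gen, banding = band,
                  model_outcomes = unlist(y$model_outcomes),
                  stratifiers = if (length(y$stratifiers)) unlist(y$stratifiers)
                  else character(),
                  sensitivity = y$sensitivity,
                  scenarios = scen,
                  global_seed = y$global_seed)
}

#' Render a plain-text report from a completed run
#'
#' Summarises the run's stage outputs: pooled band trajectories of the
#' distributional parameters, the model coefficient table (slope, intercept
#' and prediction at mean HAZ -2 per outcome), and the final-step simulated
#' SDs per scenario. Missing stages are noted as gaps rather than errors.
#'
#' @param manifest a `run_manifest` (or the path of a run directory).
#' @return Character vector of report lines (also printed).
#' @export
render_report <- function(manifest) {
  dir <- if (inherits(manifest, "run_manifest")) manifest$output_dir
  else manifest
  if (!dir.exists(dir)) stop("run directory not found: ", dir, call. = FALSE)
  files <- list.files(dir)
  if (length(intersect(files, c("band_summaries.csv", "model_coefficients.csv",
                                "sim_trajectories.csv", "units.csv"))) == 0) {
    stop("no stage outputs found in ", dir, call. = FALSE)
  }
  lines <- c("hazshift run report", strrep("=", 40))
  grab <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }

  units <- grab("units.csv")
  if (!is.null(units)) {
    lines <- c(lines, "",
               sprintf("Survey-age units: %d (surveys %d, bands %d)",
                       nrow(units), length(unique(units$survey_id)),
                       length(unique(units$band_index))))
  }
  pooled <- grab("band_summaries.csv")
  if (!is.null(pooled)) {
    lines <- c(lines, "", "Pooled band means (95% CI) by parameter:")
    for (p in unique(pooled$parameter)) {
      sub <- pooled[pooled$parameter == p, ]
      first <- sub[which.min(sub$band_index), ]
      last <- sub[which.max(sub$band_index), ]
      lines <- c(lines, sprintf(
        "  %-6s band %2d: %6.2f (%.2f, %.2f) -> band %2d: %6.2f (%.2f, %.2f)",
        p, first$band_index, first$pooled_mean, first$ci_low, first$ci_high,
        last$band_index, last$pooled_mean, last$ci_low, last$ci_high))
    }
  } else {
    lines <- c(lines, "", "[pooled band summaries not available]")
  }
  coefs <- grab("model_coefficients.csv")
  if (!is.null(coefs)) {
    lines <- c(lines, "",
               "Three-level models (outcome ~ 1-unit decline in mean HAZ):",
               sprintf("  %-6s slope %6.3f (%.3f, %.3f)  intercept %6.3f  predicted at mean HAZ -2: %6.3f",
                       coefs$outcome, coefs$slope, coefs$slope_ci_low,
                       coefs$slope_ci_high, coefs$intercept,
                       coefs$predicted_at_minus2))
  } else {
    lines <- c(lines, "", "[model coefficients not available]")
  }
  traj <- grab("sim_trajectories.csv")
  if (!is.null(traj)) {
    lines <- c(lines, "", "Faltering simulations (final step):")
    for (nm in unique(traj$scenario)) {
      sub <- traj[traj$scenario == nm, ]
      last <- sub[which.max(sub$step), ]
      lines <- c(lines, sprintf(
        "  %-10s mean %6.2f  sd %5.2f  p5 %6.2f  p95 %6.2f",
        nm, last$mean, last$sd, last$p5, last$p95))
    }
  } else {
    lines <- c(lines, "", "[simulation trajectories not available]")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
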