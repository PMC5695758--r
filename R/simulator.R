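## Faltering simulator -------------------------------------------------------
##
## Monte Carlo model of subgroup versus whole-population growth faltering.
## A population of n children starts at the reference distribution
## (HAZ ~ N(0, 1)). The population mean is lowered in successive decrements
## of 0.1 HAZ by giving a fixed exposed subgroup (fraction p of the
## population) a per-child decline drawn around d = decrement / p, so the
## whole-population mean falls by exactly one decrement per step in
## expectation. Each scenario is replicated and the per-step mean, SD and
## tail percentiles are averaged across replications.

#' Simulation scenario
#'
#' Defaults follow the reference experiment: 10,000 children, 20 decrements
#' of 0.1 HAZ (mean 0 to -2), per-child decline SD equal to a tenth of its
#' mean, and 1000 replications.
#'
#' @param n_children population size.
#' @param p_exposed exposed fraction in (0, 1].
#' @param n_decrements number of decrement steps.
#' @param decrement population mean HAZ drop per step.
#' @param noise_fraction SD of the per-child decline as a fraction of its
#'   mean.
#' @param selection_rule `"random"` (exposure independent of HAZ),
#'   `"low_haz_first"` (the p*n children with lowest baseline HAZ) or
#'   `"high_haz_first"` (highest baseline HAZ).
#' @param floor optional censoring threshold: children whose HAZ falls below
#'   it are treated as died/censored and excluded from later summaries
#'   (`NULL` = no floor; the reference variant uses -6). With
#'   `floor_mode = "clamp"` children are instead held at the floor value.
#' @param deficit_gradient coefficient `gamma` making the per-child mean
#'   decline increase with baseline HAZ:
#'   `d_i = d * (1 + gamma * (haz0_i - mean over exposed))`, centred so the
#'   mean decline over the exposed stays exactly `d` per step (0 = off).
#' @param truncate_gain if `TRUE`, per-child declines are truncated at zero
#'   (no upward moves); off by default.
#' @param n_replications Monte Carlo replications.
#' @param seed integer seed.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_children = 10000L, p_exposed = 1,
                         n_decrements = 20L, decrement = 0.1,
                         noise_fraction = 0.1,
                         selection_rule = c("random", "low_haz_first",
                                            "high_haz_first"),
                         floor = NULL, floor_mode = c("censor", "clamp"),
                         deficit_gradient = 0, truncate_gain = FALSE,
                         n_replications = 1000L, seed = 1L) {
  selection_rule <- match.arg(selection_rule)
  floor_mode <- match.arg(floor_mode)
  stopifnot(n_children >= 1, p_exposed > 0, p_exposed <= 1,
            n_decrements >= 0, decrement > 0, noise_fraction >= 0,
            n_replications >= 1)
  structure(list(n_children = as.integer(n_children), p_exposed = p_exposed,
                 n_decrements = as.integer(n_decrements),
                 decrement = decrement, noise_fraction = noise_fraction,
                 selection_rule = selection_rule, floor = floor,
                 floor_mode = floor_mode, deficit_gradient = deficit_gradient,
                 truncate_gain = truncate_gain,
                 n_replications = as.integer(n_replications),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "Faltering scenario: n=%d, %d x %g decrements, %.0f%% exposed (%s)\n",
    x$n_children, x$n_decrements, x$decrement, 100 * x$p_exposed,
    x$selection_rule))
  cat(sprintf("  decline noise fraction %g; floor %s; deficit gradient %g; %d replications\n",
              x$noise_fraction,
              if (is.null(x$floor)) "none" else
                sprintf("%g (%s)", x$floor, x$floor_mode),
              x$deficit_gradient, x$n_replications))
  invisible(x)
}

#' Draw the initial population
#'
#' @param n population size.
#' @param seed optional integer seed (`NULL` = use current RNG stream).
#' @return `n` independent standard-normal HAZ values (reference
#'   distribution: mean 0, SD 1).
#' @export
initialize_population <- function(n, seed = NULL) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n)
}

#' Assign baseline exposure status
#'
#' Exposure is defined once at baseline and never changes. Preferential
#' selection is deterministic rank-based: the `round(p * n)` lowest (or
#' highest) baseline HAZ values.
#'
#' @param haz0 baseline HAZ values.
#' @param p_exposed exposed fraction in (0, 1].
#' @param selection_rule see [sim_scenario()].
#' @param seed optional integer seed (used by the random rule).
#' @return Logical vector flagging exactly `round(p_exposed * length(haz0))`
#'   children.
#' @export
assign_exposure <- function(haz0, p_exposed,
                            selection_rule = c("random", "low_haz_first",
                                               "high_haz_first"),
                            seed = NULL) {
  selection_rule <- match.arg(selection_rule)
  if (p_exposed <= 0 || p_exposed > 1) {
    stop("p_exposed must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(haz0)
  m <- round(p_exposed * n)
  flags <- logical(n)
  if (m == 0L) return(flags)
  picked <- switch(selection_rule,
                   random = sample.int(n, m),
                   low_haz_first = order(haz0)[seq_len(m)],
                   high_haz_first = order(haz0, decreasing = TRUE)[seq_len(m)])
  flags[picked] <- TRUE
  flags
}

#' Apply one decrement step to a population state
#'
#' Exposed children receive a decline drawn from
#' `Normal(d_i, noise_fraction * d)` with `d = decrement / p_exposed`
#' (adjusted by the deficit gradient if set); unexposed children are
#' unchanged. With a floor, children falling below it are censored (or
#' clamped) according to the scenario.
#'
#' @param state list with `haz` (current values), `haz0` (baseline values),
#'   `exposed` and `alive` logical vectors, as produced by [run_scenario()]'s
#'   internals; a plain numeric `haz` vector plus an `exposed` flag vector is
#'   also accepted.
#' @param exposed logical exposure flags (only when `state` is a numeric
#'   vector).
#' @param scenario a [sim_scenario()].
#' @param seed optional integer seed.
#' @return Updated state list (`haz`, `haz0`, `exposed`, `alive`).
#' @export
apply_decrement <- function(state, exposed = NULL, scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(state)) {
    stopifnot(!is.null(exposed), length(exposed) == length(state))
    state <- list(haz = state, haz0 = state, exposed = exposed,
                  alive = rep(TRUE, length(state)))
  }
  d <- scenario$decrement / scenario$p_exposed
  act <- which(state$exposed & state$alive)
  if (length(act) > 0) {
    mu <- rep(d, length(act))
    if (scenario$deficit_gradient != 0) {
      base <- state$haz0[state$exposed]
      mu <- d * (1 + scenario$deficit_gradient *
                   (state$haz0[act] - mean(base)))
    }
    decline <- stats::rnorm(length(act), mu, scenario$noise_fraction * d)
    if (scenario$truncate_gain) decline <- pmax(decline, 0)
    state$haz[act] <- state$haz[act] - decline
  }
  if (!is.null(scenario$floor)) {
    below <- state$alive & state$haz < scenario$floor
    if (scenario$floor_mode == "censor") {
      state$alive[below] <- FALSE
    } else {
      state$haz[below] <- scenario$floor
    }
  }
  state
}

summarize_alive <- function(haz, alive) {
  v <- haz[alive]
  if (length(v) == 0L) return(c(mean = NA_real_, sd = NA_real_,
                                p5 = NA_real_, p95 = NA_real_))
  q <- stats::quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
  c(mean = mean(v), sd = stats::sd(v), p5 = q[1], p95 = q[2])
}

#' Run one Monte Carlo faltering scenario
#'
#' Runs `n_replications` independent replications of the decrement process
#' and averages the population mean, SD, 5th and 95th percentile at each
#' step. Monte Carlo standard errors (SD across replications / sqrt(R)) are
#' reported for every summary.
#'
#' @param scenario a [sim_scenario()].
#' @return Object of class `sim_trajectory`: element `summary` is a data
#'   frame with one row per step (0 = baseline) holding the averaged
#'   summaries, their MC standard errors and the average number of
#'   uncensored children; element `replications` retains the per-replication
#'   step-by-step values (matrices, steps x replications); `fully_censored`
#'   flags replications whose population died out entirely.
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  K <- scenario$n_decrements
  R <- scenario$n_replications
  stats_names <- c("mean", "sd", "p5", "p95")
  reps <- lapply(stats_names, function(s) matrix(NA_real_, K + 1, R))
  names(reps) <- stats_names
  n_alive <- matrix(NA_real_, K + 1, R)
  for (r in seq_len(R)) {
    haz0 <- initialize_population(scenario$n_children)
    exposed <- assign_exposure(haz0, scenario$p_exposed,
                               scenario$selection_rule)
    state <- list(haz = haz0, haz0 = haz0, exposed = exposed,
                  alive = rep(TRUE, scenario$n_children))
    s0 <- summarize_alive(state$haz, state$alive)
    for (nm in stats_names) reps[[nm]][1, r] <- s0[[nm]]
    n_alive[1, r] <- sum(state$alive)
    for (k in seq_len(K)) {
      state <- apply_decrement(state, scenario = scenario)
      sk <- summarize_alive(state$haz, state$alive)
      for (nm in stats_names) reps[[nm]][k + 1, r] <- sk[[nm]]
      n_alive[k + 1, r] <- sum(state$alive)
    }
  }
  avg <- lapply(reps, rowMeans, na.rm = TRUE)
  mcse <- lapply(reps, function(m) {
    apply(m, 1, stats::sd, na.rm = TRUE) / sqrt(rowSums(!is.na(m)))
  })
  summary <- data.frame(step = 0:K,
                        mean = avg$mean, sd = avg$sd,
                        p5 = avg$p5, p95 = avg$p95,
                        mc_se_mean = mcse$mean, mc_se_sd = mcse$sd,
                        mc_se_p5 = mcse$p5, mc_se_p95 = mcse$p95,
                        n_alive = rowMeans(n_alive))
  structure(list(summary = summary, replications = reps,
                 n_alive = n_alive,
                 fully_censored = any(n_alive == 0, na.rm = TRUE),
                 scenario = scenario),
            class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  s <- x$summary
  K <- nrow(s) - 1L
  cat(sprintf("Faltering trajectory: %d steps x %d replications (%.0f%% exposed, %s)\n",
              K, x$scenario$n_replications, 100 * x$scenario$p_exposed,
              x$scenario$selection_rule))
  cat(sprintf("  step  0: mean %6.3f  sd %5.3f  p5 %6.3f  p95 %6.3f\n",
              s$mean[1], s$sd[1], s$p5[1], s$p95[1]))
  cat(sprintf("  step %2d: mean %6.3f  sd %5.3f  p5 %6.3f  p95 %6.3f\n",
              K, s$mean[K + 1], s$sd[K + 1], s$p5[K + 1], s$p95[K + 1]))
  if (x$fully_censored) cat("  [some replications fully censored]\n")
  invisible(x)
}

#' Closed-form mixture moments of the faltering process
#'
#' For random exposure selection, no floor and no deficit gradient, the
#' population at step k is a two-component Gaussian mixture whose moments
#' are available in closed form: the exposed component has mean `-k d`
#' (`d = decrement / p`) and variance `1 + k (noise_fraction d)^2`; the
#' population mean is `-k * decrement` and the population variance follows
#' from the mixture decomposition
#' `(1-p) * 1 + p * (1 + k (nf d)^2 + (k d)^2) - (k * decrement)^2`.
#'
#' @param scenario a [sim_scenario()]; must use random selection, no floor
#'   and zero deficit gradient, otherwise the closed form is invalid and an
#'   error is raised.
#' @return Data frame with one row per step: `step`, `mean`, `sd`.
#' @export
mixture_moments_oracle <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$selection_rule != "random" || !is.null(scenario$floor) ||
      scenario$deficit_gradient != 0 || scenario$truncate_gain) {
    stop("oracle is only valid for random selection, no floor, no deficit gradient",
         call. = FALSE)
  }
  p <- scenario$p_exposed
  d <- scenario$decrement / p
  k <- 0:scenario$n_decrements
  mu_e <- -k * d
  var_e <- 1 + k * (scenario$noise_fraction * d)^2
  mu <- -k * scenario$decrement
  v <- (1 - p) * 1 + p * (var_e + mu_e^2) - mu^2
  data.frame(step = k, mean = mu, sd = sqrt(v))
}

#' Classify the SD trend of a trajectory
#'
#' @param sd_sequence SD per step.
#' @param tol change treated as noise.
#' @return `"widening"`, `"narrowing"`, `"transient_narrowing"` or `"stable"`.
#' @export
classify_sd_trend <- function(sd_sequence, tol = 0.02) {
  s0 <- sd_sequence[1]
  s_end <- sd_sequence[length(sd_sequence)]
  if (s_end > s0 + tol) return("widening")
  if (min(sd_sequence) < s0 - tol) {
    if (s_end < s0 - tol) "narrowing" else "transient_narrowing"
  } else {
    "stable"
  }
}

#' Run the supplementary simulation variants
#'
#' One trajectory per variant of the subgroup-faltering experiment:
#' preferential selection of low-HAZ children (25% exposed), preferential
#' selection of high-HAZ children (25% exposed), a floor effect censoring
#' children below HAZ -6 (25% exposed, random selection), and a
#' whole-population exposure whose deficit magnitude increases with baseline
#' HAZ.
#'
#' @param seed integer seed (each variant derives its own).
#' @param n_replications Monte Carlo replications per variant.
#' @param n_children population size.
#' @param deficit_gradient gradient coefficient for the baseline-dependent
#'   deficit variant.
#' @return Named list of `sim_trajectory` objects with an extra
#'   `sd_classification` element each.
#' @export
run_variant_suite <- function(seed = 1L, n_replications = 1000L,
                              n_children = 10000L, deficit_gradient = 0.3) {
  variants <- list(
    low_haz_first = sim_scenario(n_children = n_children, p_exposed = 0.25,
                                 selection_rule = "low_haz_first",
                                 n_replications = n_replications,
                                 seed = seed + 1L),
    high_haz_first = sim_scenario(n_children = n_children, p_exposed = 0.25,
                                  selection_rule = "high_haz_first",
                                  n_replications = n_replications,
                                  seed = seed + 2L),
    floor = sim_scenario(n_children = n_children, p_exposed = 0.25,
                         selection_rule = "random", floor = -6,
                         n_replications = n_replications, seed = seed + 3L),
    deficit_gradient = sim_scenario(n_children = n_children, p_exposed = 1,
                                    deficit_gradient = deficit_gradient,
                                    n_replications = n_replications,
                                    seed = seed + 4L)
  )
  lapply(variants, function(sc) {
    tr <- run_scenario(sc)
    tr$sd_classification <- classify_sd_trend(tr$summary$sd)
    tr
  })
}
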