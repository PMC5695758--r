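## Pooled age-band summaries -------------------------------------------------
##
## International summary means of each distributional parameter by age band:
## the unweighted mean over all survey-age units in the band, with a 95% CI
## that accounts for clustering of units by country. Units enter unweighted
## regardless of their child count because the inference is at survey level,
## not child level.

UNIT_PARAMETERS <- c("mean", "median", "sd", "p5", "p95", "dp5", "dp95")

## Cluster-robust (sandwich) SE of a simple mean: intercept-only model with
## CR score sums per cluster and a J/(J-1) small-sample factor. For J balanced
## clusters of identical within-cluster values this reduces to
## sqrt(sum((cluster_mean - mean)^2) * J/(J-1) / J^2).
cluster_robust_mean <- function(values, clusters, conf_level = 0.95) {
  stopifnot(length(values) == length(clusters), length(values) >= 1)
  n <- length(values)
  m <- mean(values)
  sj <- tapply(values - m, clusters, sum)
  J <- length(sj)
  se <- if (J > 1) sqrt(sum(sj^2) * J / (J - 1)) / n else NA_real_
  crit <- if (J >= 30) {
    stats::qnorm(1 - (1 - conf_level) / 2)
  } else if (J > 1) {
    stats::qt(1 - (1 - conf_level) / 2, df = J - 1)
  } else {
    NA_real_
  }
  list(mean = m, se = se, ci_low = m - crit * se, ci_high = m + crit * se,
       n = n, n_clusters = J)
}

## Alternative: country random-intercept model for the pooled mean.
random_intercept_mean <- function(values, clusters, conf_level = 0.95) {
  df <- data.frame(y = values, cl = factor(clusters))
  if (nlevels(df$cl) < 2 || stats::var(values) == 0) {
    return(cluster_robust_mean(values, clusters, conf_level))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | cl), data = df, REML = TRUE)))
  est <- lme4::fixef(fit)[[1]]
  se <- sqrt(as.numeric(stats::vcov(fit)[1, 1]))
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(mean = est, se = se, ci_low = est - crit * se, ci_high = est + crit * se,
       n = length(values), n_clusters = nlevels(df$cl))
}

#' Pool one distributional parameter across survey-age units in a band
#'
#' The pooled estimate is the unweighted mean over all units in the band; its
#' 95% CI accounts for clustering by country, by default via cluster-robust
#' (sandwich) standard errors with a normal critical value when at least 30
#' countries contribute (t with J-1 df otherwise).
#'
#' @param units a `survey_age_units` data frame.
#' @param parameter one of `"mean"`, `"median"`, `"sd"`, `"p5"`, `"p95"`,
#'   `"dp5"`, `"dp95"`.
#' @param band_index band to pool.
#' @param method `"cluster_robust"` (default) or `"random_intercept"`
#'   (country random-intercept model).
#' @return One-row data frame: `band_index`, `parameter`, `pooled_mean`,
#'   `ci_low`, `ci_high`, `n_units`, `n_countries`.
#' @export
pool_age_band <- function(units, parameter, band_index,
                          method = c("cluster_robust", "random_intercept")) {
  method <- match.arg(method)
  if (!parameter %in% UNIT_PARAMETERS) {
    stop("unknown parameter '", parameter, "'; must be one of: ",
         paste(UNIT_PARAMETERS, collapse = ", "), call. = FALSE)
  }
  sel <- units$band_index == band_index
  if (!any(sel)) stop("no units in band ", band_index, call. = FALSE)
  v <- units[[parameter]][sel]
  cl <- units$country_id[sel]
  res <- if (method == "cluster_robust") {
    cluster_robust_mean(v, cl)
  } else {
    random_intercept_mean(v, cl)
  }
  if (res$n_clusters == 1 || !is.finite(res$se)) {
    # single-country band: no between-cluster information, degenerate CI
    res$ci_low <- res$ci_high <- res$mean
    if (stats::var(v) > 0) {
      warning("band ", band_index, ": only one country; CI is degenerate",
              call. = FALSE)
    }
  }
  if (isTRUE(all.equal(stats::var(v), 0))) {
    res$ci_low <- res$ci_high <- res$mean
  }
  data.frame(band_index = band_index, parameter = parameter,
             pooled_mean = res$mean, ci_low = res$ci_low,
             ci_high = res$ci_high, n_units = res$n,
             n_countries = res$n_clusters, stringsAsFactors = FALSE)
}

#' Pooled summaries of every parameter in every populated band
#'
#' @inheritParams pool_age_band
#' @param parameters parameters to summarise (default all seven).
#' @return Tidy data frame, one row per (parameter, band).
#' @export
summarize_all_bands <- function(units, parameters = UNIT_PARAMETERS,
                                method = c("cluster_robust", "random_intercept")) {
  method <- match.arg(method)
  if (nrow(units) == 0L) stop("no survey-age units", call. = FALSE)
  bands <- sort(unique(units$band_index))
  out <- do.call(rbind, lapply(parameters, function(p) {
    do.call(rbind, lapply(bands, function(b) pool_age_band(units, p, b, method)))
  }))
  rownames(out) <- NULL
  out
}
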