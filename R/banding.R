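## Survey-age units ----------------------------------------------------------
##
## The unit of analysis is one survey crossed with one discrete age band.
## Children are grouped into 12 bands of exactly 91.3 days (= 365.25/4) over
## 0-36 months; implausible |HAZ| values beyond a configurable bound are
## excluded; and each unit carries survey-weighted distributional parameters
## of HAZ: mean, median, SD, 5th and 95th percentile, plus the tail distances
## dp5 = mean - p5 and dp95 = p95 - mean.

#' Age-banding and plausibility configuration
#'
#' @param band_width_days width of each age band in days. The default 91.3
#'   (365.25/4) gives 12 three-month bands over 0-36 months. Sensitivity
#'   choices: 30.44 (= 365.25/12, 1-month bands, `n_bands = 36`) and 182.6
#'   (6-month bands, `n_bands = 6`).
#' @param n_bands number of bands; ages at or beyond
#'   `n_bands * band_width_days` are flagged out of range and excluded.
#' @param plausibility_limit absolute HAZ bound beyond which values are
#'   treated as implausible and excluded (default 9; the stricter WHO-style
#'   sensitivity bound is 6).
#' @param min_children_per_unit smallest unit retained (default 1, i.e. no
#'   unit dropped); sparse units destabilise the tail percentiles.
#' @param sd_divisor `"population"` (divisor = total weight; default) or
#'   `"frequency"` (divisor = total weight - 1, a frequency-weight
#'   small-sample correction, negligible at survey sizes).
#' @return An object of class `banding_config`.
#' @export
banding_config <- function(band_width_days = 91.3, n_bands = 12L,
                           plausibility_limit = 9, min_children_per_unit = 1L,
                           sd_divisor = c("population", "frequency")) {
  sd_divisor <- match.arg(sd_divisor)
  stopifnot(band_width_days > 0, n_bands >= 1, plausibility_limit > 0,
            min_children_per_unit >= 1)
  structure(list(band_width_days = band_width_days,
                 n_bands = as.integer(n_bands),
                 plausibility_limit = plausibility_limit,
                 min_children_per_unit = as.integer(min_children_per_unit),
                 sd_divisor = sd_divisor),
            class = "banding_config")
}

#' @export
print.banding_config <- function(x, ...) {
  cat(sprintf("Banding: %d bands of %.4g days; |HAZ| <= %g; min n/unit %d; SD divisor %s\n",
              x$n_bands, x$band_width_days, x$plausibility_limit,
              x$min_children_per_unit, x$sd_divisor))
  invisible(x)
}

#' Assign ages to discrete age bands
#'
#' Bands are half-open intervals `[k*w, (k+1)*w)`; with integer ages and the
#' default non-integer width of 91.3 days no age falls on a boundary. Ages at
#' or beyond the last band are returned as `NA` (out of range).
#'
#' @param age_days integer vector of ages in days.
#' @param config a [banding_config()].
#' @return Integer band indices in `0..n_bands-1`, `NA` for out-of-range ages.
#' @export
assign_age_band <- function(age_days, config = banding_config()) {
  stopifnot(inherits(config, "banding_config"), all(age_days >= 0 | is.na(age_days)))
  band <- as.integer(floor(age_days / config$band_width_days))
  band[band >= config$n_bands] <- NA_integer_
  band
}

#' Exclude implausible HAZ values
#'
#' Keeps records with `-limit <= haz <= limit`; everything outside the bound
#' is treated as biologically implausible (measurement or coding error).
#'
#' @param records data frame with a `haz` column.
#' @param limit positive absolute bound (default 9).
#' @return A list with `records` (kept rows) and `excluded_count`.
#' @export
filter_plausible <- function(records, limit = 9) {
  stopifnot(limit > 0)
  keep <- !is.na(records$haz) & abs(records$haz) <= limit
  list(records = records[keep, , drop = FALSE],
       excluded_count = sum(!keep))
}

#' Weighted quantiles from the weighted empirical CDF
#'
#' Defines `F(x) = sum(w[i] for x[i] <= x) / sum(w)` and returns the inverse
#' of the piecewise-linear curve through the knots `(x_(i), F_i)`: targets at
#' or below `F_1` return the smallest value; otherwise the quantile is
#' linearly interpolated between the adjacent order statistics bracketing the
#' target probability. With equal weights this reduces to the
#' ECDF-interpolation sample quantile (`stats::quantile` type 4).
#'
#' @param x numeric values.
#' @param w positive weights, same length as `x`.
#' @param probs probabilities in \[0, 1\].
#' @return Numeric vector of quantiles, one per probability.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), length(x) >= 1L,
            all(w > 0), all(probs >= 0 & probs <= 1))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    if (p <= cw[1]) return(x[1])
    j <- which(cw >= p - 1e-12)[1]
    if (is.na(j)) return(x[length(x)])
    x[j - 1] + (p - cw[j - 1]) / (cw[j] - cw[j - 1]) * (x[j] - x[j - 1])
  }, numeric(1))
}

#' Survey-weighted distributional parameters of HAZ
#'
#' Computes the weighted mean, median, SD and 5th/95th percentiles of a set
#' of values under probability sampling weights. The SD uses the weighted
#' population form (divisor = total weight) by default; percentiles follow
#' [weighted_quantile()].
#'
#' @param haz numeric values (length >= 1).
#' @param weights positive weights; defaults to equal weights.
#' @param sd_divisor see [banding_config()].
#' @return Named numeric vector `c(mean, median, sd, p5, p95)`.
#' @export
weighted_params <- function(haz, weights = NULL,
                            sd_divisor = c("population", "frequency")) {
  sd_divisor <- match.arg(sd_divisor)
  n <- length(haz)
  if (n == 0L) stop("empty input", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights must match haz in length", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(haz))) stop("haz values must be finite", call. = FALSE)
  W <- sum(weights)
  m <- sum(weights * haz) / W
  s <- if (n > 1L) {
    ss <- sum(weights * (haz - m)^2)
    sqrt(ss / if (sd_divisor == "population") W else (W - 1))
  } else 0
  q <- weighted_quantile(haz, weights, c(0.05, 0.5, 0.95))
  c(mean = m, median = q[2], sd = s, p5 = q[1], p95 = q[3])
}

#' Build survey-age units from child records
#'
#' Applies the plausibility filter and age banding, then computes one row of
#' weighted distributional parameters per populated (survey, band) cell and
#' joins survey-level covariates. Exclusion counts (implausible HAZ and
#' out-of-range ages) are attached as the `"exclusions"` attribute.
#'
#' @param records child-record data frame (see
#'   [generate_multisurvey_dataset()] for the schema).
#' @param meta survey metadata data frame; every `survey_id` in `records`
#'   must be present.
#' @param config a [banding_config()].
#' @return Data frame of class `survey_age_units`, one row per populated
#'   (survey, band) with `n >= min_children_per_unit`: identifiers, covariates,
#'   `band_index`, `n`, `mean`, `median`, `sd`, `p5`, `p95`, `dp5`, `dp95`.
#' @export
build_survey_age_units <- function(records, meta, config = banding_config()) {
  stopifnot(inherits(config, "banding_config"))
  missing_meta <- setdiff(unique(records$survey_id), meta$survey_id)
  if (length(missing_meta) > 0) {
    stop("surveys present in records but absent from meta: ",
         paste(utils::head(missing_meta, 5), collapse = ", "), call. = FALSE)
  }
  fp <- filter_plausible(records, config$plausibility_limit)
  rec <- fp$records
  band <- assign_age_band(rec$age_days, config)
  n_age_excluded <- sum(is.na(band))
  keep <- !is.na(band)
  rec <- rec[keep, , drop = FALSE]
  band <- band[keep]

  unit_cols <- c("band_index", "n", "mean", "median", "sd", "p5", "p95",
                 "dp5", "dp95")
  meta_cols <- intersect(c("survey_id", "country_id", "survey_year", "region",
                           "income_class", "n_children", "baseline_mean_haz"),
                         names(meta))
  if (nrow(rec) == 0L) {
    units <- cbind(meta[0, meta_cols, drop = FALSE],
                   as.data.frame(matrix(numeric(0), 0, length(unit_cols),
                                        dimnames = list(NULL, unit_cols))))
  } else {
    key <- paste(rec$survey_id, band, sep = "\r")
    idx <- split(seq_len(nrow(rec)), key)
    rows <- lapply(idx, function(i) {
      p <- weighted_params(rec$haz[i], rec$weight[i], config$sd_divisor)
      data.frame(survey_id = rec$survey_id[i[1]],
                 band_index = band[i[1]],
                 n = length(i),
                 mean = p[["mean"]], median = p[["median"]], sd = p[["sd"]],
                 p5 = p[["p5"]], p95 = p[["p95"]],
                 dp5 = p[["mean"]] - p[["p5"]],
                 dp95 = p[["p95"]] - p[["mean"]],
                 stringsAsFactors = FALSE)
    })
    units <- do.call(rbind, rows)
    sparse <- units$n < config$min_children_per_unit
    n_sparse_children <- sum(units$n[sparse])
    units <- units[!sparse, , drop = FALSE]
    units <- merge(meta[, meta_cols, drop = FALSE], units, by = "survey_id")
    units <- units[order(units$survey_id, units$band_index), , drop = FALSE]
    rownames(units) <- NULL
  }
  if (!exists("n_sparse_children", inherits = FALSE)) n_sparse_children <- 0L
  attr(units, "exclusions") <- c(implausible_haz = fp$excluded_count,
                                 out_of_age_range = n_age_excluded,
                                 sparse_unit_children = n_sparse_children)
  class(units) <- c("survey_age_units", class(units))
  units
}

#' @export
print.survey_age_units <- function(x, ...) {
  cat(sprintf("Survey-age units: %d units, %d surveys, %d bands\n",
              nrow(x), length(unique(x$survey_id)),
              length(unique(x$band_index))))
  excl <- attr(x, "exclusions")
  if (!is.null(excl)) {
    cat(sprintf("  excluded children: %d implausible HAZ, %d out of age range\n",
                excl[["implausible_haz"]], excl[["out_of_age_range"]]))
  }
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
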