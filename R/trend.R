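# Genetic-trend estimation: OLS and loess regression of breeding values on
# year of origin (or testing, or release), with percent-per-annum
# conversion.

#' Fit a linear genetic trend
#'
#' Ordinary least squares of breeding value on year. The percent-per-annum
#' rate divides the slope by a baseline: the mean of the values (default)
#' or the fitted value at the first year.
#'
#' @param data A data frame with one row per genotype.
#' @param value,year Column names (strings) holding the breeding values
#'   (kg/ha) and the regressor year.
#' @param baseline_rule `"mean_of_values"` or `"fitted_at_first_year"`.
#' @param regressor Label recorded in the result (e.g. `"year_of_origin"`,
#'   `"year_of_testing"`, `"year_of_release"`).
#' @param weights Optional column of regression weights (e.g.
#'   reliabilities); unweighted by default.
#' @return A `trend_fit`: `slope` and `slope_se` (kg/ha/year), `intercept`,
#'   `percent_per_annum`, `baseline`, `n`, `regressor`, and the underlying
#'   `lm` fit.
#' @export
fit_linear_trend <- function(data, value = "breeding_value",
                             year = "year_of_origin",
                             baseline_rule = c("mean_of_values",
                                               "fitted_at_first_year"),
                             regressor = year, weights = NULL) {
  baseline_rule <- match.arg(baseline_rule)
  assert_columns(data, c(value, year, weights), "trend input")
  df <- tibble(value = data[[value]], year = data[[year]])
  if (!is.null(weights)) df$w <- data[[weights]]
  df <- df[complete.cases(df), ]
  if (nrow(df) < 3) {
    abort("need >= 3 genotypes with both a value and a year",
          class = "breedgain_trend_error")
  }
  if (length(unique(df$year)) < 2) {
    abort("all years identical: slope undefined",
          class = "breedgain_trend_error")
  }
  fit <- if (is.null(weights)) {
    lm(value ~ year, data = df)
  } else {
    lm(value ~ year, data = df, weights = df$w)
  }
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits are legal input
  slope <- unname(sm["year", "Estimate"])
  baseline <- switch(baseline_rule,
    mean_of_values = mean(df$value),
    fitted_at_first_year = unname(predict(fit, tibble(year = min(df$year))))
  )
  structure(list(
    slope = slope,
    slope_se = unname(sm["year", "Std. Error"]),
    intercept = unname(sm["(Intercept)", "Estimate"]),
    percent_per_annum = 100 * slope / baseline,
    baseline = baseline, baseline_rule = baseline_rule,
    n = nrow(df), regressor = regressor, model = fit, data = df
  ), class = "trend_fit")
}

#' Fit a loess genetic trend
#'
#' Tricube-weighted local polynomial regression of breeding value on year,
#' evaluated on the grid of distinct observed years (ties in year are
#' allowed; one fitted value per distinct year). Deterministic; uses the
#' direct (non-interpolated) loess surface.
#'
#' @inheritParams fit_linear_trend
#' @param span Smoothing span (proportion of points per local window).
#' @param degree Local polynomial degree, 1 or 2.
#' @return A tibble: `year`, `fitted`.
#' @export
fit_loess_trend <- function(data, value = "breeding_value",
                            year = "year_of_origin",
                            span = 0.75, degree = 2) {
  stopifnot(degree %in% c(1, 2))
  assert_columns(data, c(value, year), "trend input")
  df <- tibble(value = data[[value]], year = data[[year]])
  df <- df[complete.cases(df), ]
  if (nrow(df) < 10) {
    abort("need >= 10 points for a loess trend",
          class = "breedgain_trend_error")
  }
  window <- ceiling(span * nrow(df))
  if (window < degree + 2) {
    abort(sprintf(
      "span %.3f gives local windows of %d point(s) (< degree + 2) near year %s",
      span, window, min(df$year)
    ), class = "breedgain_trend_error")
  }
  fit <- loess(value ~ year, data = df, span = span, degree = degree,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  grid <- sort(unique(df$year))
  tibble(year = grid, fitted = unname(predict(fit, tibble(year = grid))))
}

#' Genetic trend of released varieties
#'
#' Restricts a stage-2 result to released genotypes and regresses their
#' breeding values on the year of release.
#'
#' @param s2 A `stage2_result` (or its `values` tibble).
#' @param releases A data frame with columns `genotype` and
#'   `year_of_release` (rows with a missing release year are ignored).
#' @inheritParams fit_linear_trend
#' @return A `trend_fit` with `regressor = "year_of_release"`.
#' @export
released_variety_trend <- function(s2, releases,
                                   baseline_rule = c("mean_of_values",
                                                     "fitted_at_first_year")) {
  values <- if (inherits(s2, "stage2_result")) s2$values else as_tibble(s2)
  assert_columns(releases, c("genotype", "year_of_release"), "release table")
  rel <- filter(as_tibble(releases), !is.na(.data$year_of_release))
  df <- inner_join(values, rel[, c("genotype", "year_of_release")],
                   by = "genotype")
  if (nrow(df) < 3) {
    abort("insufficient data: need >= 3 released genotypes with breeding values",
          class = "breedgain_trend_error")
  }
  fit_linear_trend(df, value = "breeding_value", year = "year_of_release",
                   baseline_rule = baseline_rule,
                   regressor = "year_of_release")
}
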