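# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @exportS3Method
tidy.trend_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", x$regressor),
         estimate = c(x$intercept, x$slope),
         std.error = c(suppressWarnings(summary(x$model))$coefficients[
                         "(Intercept)", "Std. Error"],
                       x$slope_se))
}

#' @exportS3Method
glance.trend_fit <- function(x, ...) {
  tibble(slope = x$slope, slope_se = x$slope_se,
         percent_per_annum = x$percent_per_annum,
         baseline = x$baseline, baseline_rule = x$baseline_rule,
         n = x$n, regressor = x$regressor,
         r.squared = suppressWarnings(summary(x$model))$r.squared)
}

#' @exportS3Method
tidy.stage2_result <- function(x, ...) x$values

#' @exportS3Method
glance.stage2_result <- function(x, ...) {
  tibble(sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
         n_genotypes = nrow(x$values),
         n_phenotyped = sum(x$values$phenotyped),
         mean_reliability = mean(x$values$reliability[x$values$phenotyped]),
         convergence = x$convergence, n_clamped = x$n_clamped)
}

#' @exportS3Method
tidy.stage1_result <- function(x, ...) x$blues

#' @exportS3Method
glance.stage1_result <- function(x, ...) {
  tibble(n_years = length(unique(x$blues$year)),
         n_blues = nrow(x$blues),
         h2_min = suppressWarnings(min(x$h2$h2)),
         h2_max = suppressWarnings(max(x$h2$h2)),
         n_skipped = nrow(x$skipped))
}

#' @exportS3Method
tidy.gge_result <- function(x, ...) {
  as_tibble(x$genotype_scores, rownames = "genotype") |>
    left_join(x$stability, by = "genotype")
}

#' @exportS3Method
glance.gge_result <- function(x, ...) {
  tibble(pc1_pct = x$pc_variance_pct[1],
         pc2_pct = if (length(x$pc_variance_pct) > 1)
           x$pc_variance_pct[2] else NA_real_,
         n_genotypes = nrow(x$genotype_scores),
         n_environments = nrow(x$environment_scores))
}

#' @exportS3Method
tidy.truth_set <- function(x, ...) {
  tibble(genotype = names(x$true_bv), true_bv = unname(x$true_bv))
}

#' @exportS3Method
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Genetic trend on %s: %.2f kg/ha/year (SE %.2f), %.3f%% per annum (baseline %.1f, n = %d)\n",
    x$regressor, x$slope, x$slope_se, x$percent_per_annum, x$baseline, x$n))
  invisible(x)
}

#' @exportS3Method
print.stage2_result <- function(x, ...) {
  cat(sprintf(
    "Stage-2 fit: %d genotypes (%d phenotyped), sigma2_g = %.0f, sigma2_e = %.2f\n",
    nrow(x$values), sum(x$values$phenotyped), x$sigma2_g, x$sigma2_e))
  print(head(x$values))
  invisible(x)
}
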