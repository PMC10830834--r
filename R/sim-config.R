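#' Configuration for the synthetic breeding-program generator
#'
#' Bundles and validates every knob of the simulator: crossing-program shape,
#' genetic and environmental variances, trial layout, and contamination
#' rates. Defaults describe a mid-sized stress-breeding program: a founder
#' set crossed over a decade with single, double, three-way, complex and
#' backcrosses, truncation selection of parents (which is what induces an
#' upward genetic trend), and yearly two-season trials under rotating
#' experimental designs with heterogeneous error variances.
#'
#' @param n_founders Number of founder genotypes.
#' @param n_years_crossing Number of crossing years after the founder year.
#' @param crosses_per_year Number of new primary entries per crossing year
#'   (each multi-stage cross still yields exactly one primary entry; its
#'   intermediate single crosses are extra pedigree rows).
#' @param cross_type_mix Named proportions over
#'   `c("single","double","three_way","complex","backcross")`; must sum to 1.
#'   Multi-stage types only become available once enough crossing history
#'   exists (their intermediates are back-dated to earlier years so parents
#'   always strictly precede offspring in year of origin).
#' @param selection_fraction Fraction of candidates used as parents each
#'   year (truncation selection on true genetic value; 1 = random mating).
#'   The default emulates a long-cycle stress-breeding program whose
#'   realized gain is a few tenths of a percent per annum.
#' @param sigma2_g Additive genetic variance, (kg/ha)^2.
#' @param sigma2_e_range Per-trial residual variance interval, (kg/ha)^2;
#'   trial variances are drawn log-uniformly over it (uniformly if the lower
#'   end is 0), creating the heterogeneity the stage-2 weights must absorb.
#' @param mu_yield Baseline mean yield, kg/ha.
#' @param dtf_mean,dtf_sd Days-to-flowering mean and genotype SD (days).
#' @param beta_dtf Yield change per day of flowering, kg/ha/day.
#' @param n_trial_years Number of trial years (2 seasons each).
#' @param designs Experimental designs cycled across trials; subset of
#'   `c("rcbd","augmented_rcbd","alpha_lattice","row_column")`.
#' @param n_checks Number of check genotypes present in every trial
#'   (connectivity across years); at least 2.
#' @param entries_per_trial Total entries per trial including checks.
#' @param sigma2_env Variance of the year-season environment effect.
#' @param sigma2_rep,sigma2_block,sigma2_row,sigma2_col Variances of the
#'   design-factor effects, (kg/ha)^2.
#' @param missing_rate Proportion of plots with missing yield.
#' @param outlier_rate Proportion of plots receiving an additive outlier
#'   shift.
#' @param outlier_shift_sd Outlier shift magnitude in multiples of the
#'   trial error SD (sign random).
#' @param first_year Calendar year of the founder set.
#' @param seed Integer seed; identical configs give byte-identical tables.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_founders = 40,
                       n_years_crossing = 10,
                       crosses_per_year = 50,
                       cross_type_mix = c(single = 0.50, double = 0.15,
                                          three_way = 0.15, complex = 0.10,
                                          backcross = 0.10),
                       selection_fraction = 0.85,
                       sigma2_g = 40000,
                       sigma2_e_range = c(60000, 250000),
                       mu_yield = 2500,
                       dtf_mean = 90,
                       dtf_sd = 10,
                       beta_dtf = -15,
                       n_trial_years = 10,
                       designs = c("rcbd", "augmented_rcbd",
                                   "alpha_lattice", "row_column"),
                       n_checks = 4,
                       entries_per_trial = 200,
                       sigma2_env = 90000,
                       sigma2_rep = 10000,
                       sigma2_block = 15000,
                       sigma2_row = 8000,
                       sigma2_col = 8000,
                       missing_rate = 0.03,
                       outlier_rate = 0.005,
                       outlier_shift_sd = 8,
                       first_year = 2000,
                       seed = 42) {
  cfg <- list(
    n_founders = n_founders, n_years_crossing = n_years_crossing,
    crosses_per_year = crosses_per_year, cross_type_mix = cross_type_mix,
    selection_fraction = selection_fraction, sigma2_g = sigma2_g,
    sigma2_e_range = sigma2_e_range, mu_yield = mu_yield,
    dtf_mean = dtf_mean, dtf_sd = dtf_sd, beta_dtf = beta_dtf,
    n_trial_years = n_trial_years, designs = designs, n_checks = n_checks,
    entries_per_trial = entries_per_trial, sigma2_env = sigma2_env,
    sigma2_rep = sigma2_rep, sigma2_block = sigma2_block,
    sigma2_row = sigma2_row, sigma2_col = sigma2_col,
    missing_rate = missing_rate, outlier_rate = outlier_rate,
    outlier_shift_sd = outlier_shift_sd, first_year = first_year,
    seed = seed
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) abort(msg, class = "breedgain_config_error")
  types <- c("single", "double", "three_way", "complex", "backcross")
  vars <- c("sigma2_g", "sigma2_env", "sigma2_rep", "sigma2_block",
            "sigma2_row", "sigma2_col")
  for (v in vars) if (cfg[[v]] < 0) bad(sprintf("%s must be >= 0", v))
  if (length(cfg$sigma2_e_range) != 2 || any(cfg$sigma2_e_range < 0) ||
      cfg$sigma2_e_range[1] > cfg$sigma2_e_range[2]) {
    bad("sigma2_e_range must be a non-negative, non-decreasing interval")
  }
  mix <- cfg$cross_type_mix
  if (!setequal(names(mix), types) || any(mix < 0) ||
      abs(sum(mix) - 1) > 1e-8) {
    bad("cross_type_mix must be proportions over the five cross types summing to 1")
  }
  for (p in c("selection_fraction", "missing_rate", "outlier_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) bad(sprintf("%s must be in [0, 1]", p))
  }
  if (cfg$selection_fraction == 0) bad("selection_fraction must be > 0")
  if (cfg$n_checks < 2) bad("n_checks must be >= 2 (connectivity requires repeated checks)")
  if (cfg$n_checks > cfg$n_founders) bad("n_checks cannot exceed n_founders")
  if (cfg$n_years_crossing > 0 && cfg$crosses_per_year == 0) {
    bad("crosses_per_year = 0 with n_years_crossing > 0 is an invalid configuration")
  }
  if (!all(cfg$designs %in% c("rcbd", "augmented_rcbd", "alpha_lattice",
                              "row_column"))) {
    bad("unknown design in `designs`")
  }
  if (cfg$entries_per_trial <= cfg$n_checks) {
    bad("entries_per_trial must exceed n_checks")
  }
  structure(cfg, class = "sim_config")
}
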