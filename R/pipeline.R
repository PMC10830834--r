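# End-to-end orchestration: QC -> A-matrix -> stage 1 -> stage 2 -> trend
# -> panel, with every intermediate artifact and a run manifest on disk.

default_run_config <- function() {
  list(
    paths = list(pheno = NULL, pedigree = NULL, out = "breedgain_out"),
    qc = list(alpha = 0.05, max_missing = 0.20, aberrant_max = 20000),
    model = list(season_role = "random", use_dtf = TRUE, use_pedigree = TRUE),
    trend = list(regressor = "year_of_origin",
                 baseline_rule = "mean_of_values",
                 loess_span = 0.75, loess_degree = 2),
    panel = list(bv_threshold = NULL, rel_threshold = 0.4, top_n = NULL),
    seed = 1
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full genetic-gain pipeline
#'
#' Executes quality control, optional A-matrix construction, the two-stage
#' analysis, trend regression and panel selection, writing each artifact
#' (`stage1.csv`, `h2.csv`, `stage2.csv`, `trend.json`,
#' `trend_points.csv`, `panel.csv`, `qc_report.json`, `manifest.json`) to
#' the configured output directory. The run is deterministic: identical
#' inputs and configuration give identical artifacts. When
#' `model$use_pedigree` is `FALSE` the pipeline runs in no-pedigree mode
#' (genotype covariance = identity, plain BLUPs) and the trend regressor
#' defaults to the year of first testing.
#'
#' @param config A configuration list (see `default_run_config` in the
#'   sources for the shape) or a path to a YAML file holding one. Paths may
#'   be omitted by supplying `pheno` / `pedigree` tables directly.
#' @param pheno,pedigree Optional in-memory tables overriding the
#'   configured paths.
#' @return A list of all stage results plus the manifest, invisibly
#'   written to disk.
#' @export
run_pipeline <- function(config = list(), pheno = NULL, pedigree = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config)
  out_dir <- cfg$paths$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  stage <- "ingest"
  result <- tryCatch({
    if (is.null(pheno)) pheno <- read_phenotypes(cfg$paths$pheno)
    use_ped <- isTRUE(cfg$model$use_pedigree)
    if (is.null(pedigree) && use_ped && !is.null(cfg$paths$pedigree)) {
      pedigree <- read_pedigree(cfg$paths$pedigree)
    }

    stage <- "qc"
    qc <- run_qc(pheno, max_missing = cfg$qc$max_missing,
                 aberrant_max = cfg$qc$aberrant_max, alpha = cfg$qc$alpha)
    jsonlite::write_json(
      list(trials_in = qc$filter_report$trials_in,
           trials_dropped = qc$filter_report$trials_dropped,
           drop_reasons = qc$filter_report$drop_reasons,
           outliers_flagged = qc$outlier_report$outliers_flagged,
           records_retained = qc$outlier_report$records_retained),
      file.path(out_dir, "qc_report.json"), auto_unbox = TRUE, digits = NA
    )

    stage <- "amatrix"
    a <- NULL
    if (use_ped) {
      if (is.null(pedigree)) abort("pedigree required when use_pedigree = TRUE")
      a <- build_a_matrix(pedigree)
    }

    stage <- "stage1"
    s1 <- stage1_by_year(qc$data,
                         use_dtf_covariate = isTRUE(cfg$model$use_dtf),
                         season_role = cfg$model$season_role)
    readr::write_csv(s1$blues, file.path(out_dir, "stage1.csv"))
    readr::write_csv(s1$h2, file.path(out_dir, "h2.csv"))
    if (nrow(s1$skipped) > 0) {
      note("stage 1 skipped %d year(s)", nrow(s1$skipped))
    }

    stage <- "stage2"
    s2 <- stage2_blup(s1, a = a)
    readr::write_csv(s2$values, file.path(out_dir, "stage2.csv"))
    if (s2$n_clamped > 0) note("%d reliability clamp(s)", s2$n_clamped)
    if (!s2$convergence) note("stage-2 REML did not converge")

    stage <- "trend"
    regressor <- cfg$trend$regressor
    if (!use_ped && identical(regressor, "year_of_origin")) {
      regressor <- "year_of_testing"
    }
    tr_data <- trend_input(s2, pedigree, qc$data, regressor)
    trend <- fit_linear_trend(tr_data, value = "breeding_value",
                              year = "reg_year",
                              baseline_rule = cfg$trend$baseline_rule,
                              regressor = regressor)
    lo <- withCallingHandlers(
      tryCatch(
        fit_loess_trend(tr_data, value = "breeding_value", year = "reg_year",
                        span = cfg$trend$loess_span,
                        degree = cfg$trend$loess_degree),
        error = function(e) {
          note("loess trend: %s", conditionMessage(e))
          NULL
        }
      ),
      warning = function(w) {
        note("loess trend warning: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    jsonlite::write_json(
      list(slope = trend$slope, slope_se = trend$slope_se,
           intercept = trend$intercept,
           percent_per_annum = trend$percent_per_annum,
           baseline = trend$baseline, baseline_rule = trend$baseline_rule,
           n = trend$n, regressor = trend$regressor),
      file.path(out_dir, "trend.json"), auto_unbox = TRUE, digits = NA
    )
    readr::write_csv(trend$data, file.path(out_dir, "trend_points.csv"))
    if (!is.null(lo)) readr::write_csv(lo, file.path(out_dir, "trend_loess.csv"))

    stage <- "panel"
    panel <- NULL
    if (!is.null(cfg$panel$bv_threshold)) {
      panel <- select_elite(s2, bv_threshold = cfg$panel$bv_threshold,
                            rel_threshold = cfg$panel$rel_threshold,
                            top_n = cfg$panel$top_n)
      readr::write_csv(as_tibble(panel), file.path(out_dir, "panel.csv"))
    }

    list(qc = qc, a = a, stage1 = s1, stage2 = s2, trend = trend,
         loess = lo, panel = panel)
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)),
          class = "breedgain_pipeline_error", parent = e)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("breedgain")),
    config = cfg, warnings = warnings_log,
    n_records_in = nrow(pheno),
    n_records_retained = result$qc$outlier_report$records_retained,
    n_outliers_flagged = nrow(result$qc$outlier_report$outliers_flagged),
    reliability_clamps = result$stage2$n_clamped
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  result$manifest <- manifest
  invisible(result)
}

# attach the trend regressor year to phenotyped genotypes: year of origin
# from the pedigree, year of first testing from the phenotypes, or year of
# release from the pedigree metadata
trend_input <- function(s2, pedigree, pheno, regressor) {
  vals <- filter(s2$values, .data$phenotyped)
  if (regressor == "year_of_origin") {
    if (is.null(pedigree)) abort("year_of_origin regressor needs a pedigree")
    left_join(vals,
              tibble(genotype = as.character(pedigree$genotype),
                     reg_year = pedigree$year_of_origin),
              by = "genotype")
  } else if (regressor == "year_of_testing") {
    first_test <- pheno |>
      group_by(.data$genotype) |>
      summarise(reg_year = min(.data$year), .groups = "drop")
    left_join(vals, first_test, by = "genotype")
  } else if (regressor == "year_of_release") {
    if (is.null(pedigree)) abort("year_of_release regressor needs a pedigree")
    left_join(vals,
              tibble(genotype = as.character(pedigree$genotype),
                     reg_year = pedigree$year_of_release),
              by = "genotype")
  } else {
    abort(sprintf("unknown regressor '%s'", regressor))
  }
}
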