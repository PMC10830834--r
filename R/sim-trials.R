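# Synthetic multi-environment trials over a simulated pedigree.

draw_trial_sigma2 <- function(stream, range) {
  if (range[2] == 0) return(0)
  if (range[1] == 0) {
    stream_draw(stream, function() runif(1, range[1], range[2]))
  } else {
    # log-uniform: heterogeneous error variances across trials
    stream_draw(stream, function() exp(runif(1, log(range[1]), log(range[2]))))
  }
}

# Field layout per design: returns tibble(genotype, rep, block, row, col),
# one row per plot. `entries` is the genotype id vector for the trial.
layout_trial <- function(design, entries, checks, stream) {
  n <- length(entries)
  if (n < 2) {
    abort("design requires more plots than genotypes supplied",
          class = "breedgain_layout_error")
  }
  shuffle <- function(x) stream_draw(stream, function() sample(x))
  switch(design,
    rcbd = {
      reps <- lapply(1:2, function(r) {
        tibble(genotype = shuffle(entries), rep = as.character(r),
               block = as.character(r), row = NA_character_,
               col = NA_character_)
      })
      bind_rows(reps)
    },
    augmented_rcbd = {
      tests <- setdiff(entries, checks)
      nb <- max(2L, ceiling(length(tests) / 20))
      blk <- rep(seq_len(nb), length.out = length(tests))
      tests <- shuffle(tests)
      bind_rows(
        tibble(genotype = tests, rep = "1", block = as.character(blk),
               row = NA_character_, col = NA_character_),
        tidyr::expand_grid(block = as.character(seq_len(nb)),
                           genotype = checks) |>
          mutate(rep = "1", row = NA_character_, col = NA_character_) |>
          select("genotype", "rep", "block", "row", "col")
      )
    },
    alpha_lattice = {
      k <- 10L
      reps <- lapply(1:2, function(r) {
        g <- shuffle(entries)
        tibble(genotype = g, rep = as.character(r),
               block = as.character(ceiling(seq_along(g) / k)),
               row = NA_character_, col = NA_character_)
      })
      bind_rows(reps)
    },
    row_column = {
      nc <- ceiling(sqrt(n))
      reps <- lapply(1:2, function(r) {
        g <- shuffle(entries)
        i <- seq_along(g)
        tibble(genotype = g, rep = as.character(r),
               block = NA_character_,
               row = as.character(ceiling(i / nc)),
               col = as.character((i - 1L) %% nc + 1L))
      })
      bind_rows(reps)
    },
    abort(sprintf("unknown design '%s'", design))
  )
}

#' Simulate multi-year trial phenotypes
#'
#' Lays out one trial per year-by-season combination over the configured
#' designs (cycled), testing a moving window of recent cohorts plus the
#' check genotypes in every trial (the checks are what connect trials across
#' years). Each observation is the genotype's true value plus a year-season
#' environment effect, design-factor effects (replicate/block/row/column,
#' drawn from the configured normal distributions and recorded in the trial
#' log), a linear days-to-flowering contribution
#' `beta_dtf * (dtf - dtf_mean)`, and a residual with a trial-specific
#' variance drawn from `sigma2_e_range`. Missingness and additive outlier
#' shifts (recorded by plot id) are applied last.
#'
#' @param pedigree Pedigree tibble from [simulate_pedigree()].
#' @param truth A `truth_set` from [simulate_true_values()].
#' @param config The same [sim_config()].
#' @return A tibble with one row per plot: `plot_id`, `genotype`, `year`,
#'   `season`, `location`, `design`, `rep`, `block`, `row`, `col`,
#'   `yield_kg_ha`, `dtf`. Attributes: `outlier_ids` (plot ids of injected
#'   outliers), `trial_log` (per-trial design, error variance, environment
#'   effect and factor-effect SDs).
#' @export
simulate_trials <- function(pedigree, truth, config) {
  config <- validate_sim_config(config)
  ss <- rng_stream(seed_offset(config$seed, 3))
  bv <- truth$true_bv

  primary <- pedigree[!pedigree$is_intermediate, ]
  if (!all(primary$genotype %in% names(bv))) {
    abort("every tested genotype needs a true value",
          class = "breedgain_sim_error")
  }
  checks <- head(primary$genotype[primary$cross_type == "founder"],
                 config$n_checks)
  if (length(checks) < config$n_checks) {
    abort("not enough founders to serve as checks",
          class = "breedgain_sim_error")
  }

  # genotype-constant days to flowering, one draw per pedigree row
  dtf_g <- setNames(
    stream_draw(ss, function() {
      rnorm(nrow(pedigree), config$dtf_mean, config$dtf_sd)
    }),
    pedigree$genotype
  )

  trial_years <- config$first_year + 1L + seq_len(config$n_trial_years) - 1L
  seasons <- c("DS", "WS")
  out <- list()
  log <- list()
  outlier_ids <- character()
  trial_idx <- 0L
  plot_seq <- 0L

  for (year in trial_years) {
    for (season in seasons) {
      trial_idx <- trial_idx + 1L
      design <- config$designs[(trial_idx - 1L) %% length(config$designs) + 1L]
      window <- primary$genotype[primary$year_of_origin >= year - 2L &
                                 primary$year_of_origin <= year]
      window <- setdiff(window, checks)
      n_test <- config$entries_per_trial - length(checks)
      tests <- if (length(window) > n_test) {
        stream_draw(ss, function() sample(window, n_test))
      } else {
        window
      }
      entries <- c(checks, tests)

      plots <- layout_trial(design, entries, checks, ss)
      n <- nrow(plots)

      s2e <- draw_trial_sigma2(ss, config$sigma2_e_range)
      sde <- sqrt(s2e)
      env <- stream_draw(ss, function() rnorm(1, 0, sqrt(config$sigma2_env)))

      eff <- function(labels, s2) {
        lev <- unique(labels[!is.na(labels)])
        if (length(lev) == 0 || s2 == 0) return(numeric(n))
        e <- setNames(stream_draw(ss, function() {
          rnorm(length(lev), 0, sqrt(s2))
        }), lev)
        ifelse(is.na(labels), 0, e[labels])
      }
      rep_e <- eff(plots$rep, config$sigma2_rep)
      blk_e <- eff(paste(plots$rep, plots$block),
                   config$sigma2_block) * !is.na(plots$block)
      row_e <- eff(paste(plots$rep, plots$row),
                   config$sigma2_row) * !is.na(plots$row)
      col_e <- eff(paste(plots$rep, plots$col),
                   config$sigma2_col) * !is.na(plots$col)

      jit <- setNames(stream_draw(ss, function() {
        rnorm(length(entries), 0, 1.5)
      }), entries)
      dtf_obs <- pmax(50, round(dtf_g[plots$genotype] + jit[plots$genotype]))

      err <- stream_draw(ss, function() rnorm(n, 0, sde))
      yield <- bv[plots$genotype] + env + rep_e + blk_e + row_e + col_e +
        config$beta_dtf * (dtf_obs - config$dtf_mean) + err

      ids <- sprintf("P%07d", plot_seq + seq_len(n))
      plot_seq <- plot_seq + n

      miss <- stream_draw(ss, function() {
        runif(n) < config$missing_rate
      })
      shift <- stream_draw(ss, function() {
        (runif(n) < config$outlier_rate) *
          sign(runif(n) - 0.5) * config$outlier_shift_sd * sde
      })
      shift[miss] <- 0
      yield[miss] <- NA_real_
      yield <- yield + shift
      # contaminated plots stay physically valid: a negative-direction
      # shift that would drive yield below zero is applied upward instead
      neg <- !is.na(yield) & yield < 0 & shift != 0
      yield[neg] <- yield[neg] - 2 * shift[neg]
      outlier_ids <- c(outlier_ids, ids[shift != 0])

      out[[trial_idx]] <- tibble(
        plot_id = ids, genotype = plots$genotype, year = year,
        season = season, location = "ST1", design = design,
        rep = plots$rep, block = plots$block, row = plots$row,
        col = plots$col,
        yield_kg_ha = unname(yield), dtf = as.integer(unname(dtf_obs))
      )
      log[[trial_idx]] <- tibble(
        year = year, season = season, design = design, n_plots = n,
        sigma2_e = s2e, env_effect = env
      )
    }
  }
  pheno <- bind_rows(out)
  attr(pheno, "outlier_ids") <- outlier_ids
  attr(pheno, "trial_log") <- bind_rows(log)
  pheno
}

#' Simulate a complete breeding program
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_true_values()] and [simulate_trials()].
#'
#' @param config A [sim_config()].
#' @return A list with `pedigree`, `truth`, `phenotypes`, `config`.
#' @export
simulate_program <- function(config) {
  config <- validate_sim_config(config)
  ped <- simulate_pedigree(config)
  truth <- simulate_true_values(ped, config)
  pheno <- simulate_trials(ped, truth, config)
  structure(list(pedigree = ped, truth = truth, phenotypes = pheno,
                 config = config),
            class = "sim_program")
}

#' Write simulated data to disk
#'
#' Writes `phenotypes.csv`, `pedigree.csv` and `truth.json` (true values,
#' realized trend, injected outlier plot ids) in the formats read back by
#' [read_phenotypes()] and [read_pedigree()].
#'
#' @param sim A `sim_program` from [simulate_program()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_simdata <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    phenotypes = file.path(dir, "phenotypes.csv"),
    pedigree = file.path(dir, "pedigree.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(sim$phenotypes, paths[["phenotypes"]], na = "NA")
  readr::write_csv(sim$pedigree, paths[["pedigree"]], na = "")
  jsonlite::write_json(
    list(true_bv = as.list(sim$truth$true_bv),
         realized_trend_slope = sim$truth$realized_trend_slope,
         realized_trend_percent = sim$truth$realized_trend_percent,
         outlier_ids = attr(sim$phenotypes, "outlier_ids")),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
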