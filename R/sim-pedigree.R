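# Synthetic crossing program: pedigree structure and true genetic values.
#
# Truncation selection of parents requires true values while the pedigree is
# being built, so construction uses two independent RNG substreams derived
# from the config seed: a *structure* stream (cross types, parent draws,
# trial layouts elsewhere) and a *value* stream that is consumed exactly
# once per pedigree row, in row order. simulate_true_values() replays only
# the value stream over the emitted rows, so pedigree and truth are
# mutually consistent yet independently reproducible.

seed_offset <- function(seed, k) {
  as.integer((as.numeric(seed) + k) %% 2147483647)
}

cross_depth <- c(single = 0L, double = 1L, three_way = 1L,
                 backcross = 1L, complex = 2L)
cross_nparents <- c(single = 2L, double = 4L, three_way = 3L,
                    backcross = 2L, complex = 4L)

# Internal joint generator; returns pedigree rows plus genetic values
# (on the yield scale, mu_yield + additive value).
sim_program_core <- function(cfg) {
  vs <- rng_stream(seed_offset(cfg$seed, 1))
  ss <- rng_stream(seed_offset(cfg$seed, 2))
  sdg <- sqrt(cfg$sigma2_g)

  cap <- cfg$n_founders + cfg$n_years_crossing * cfg$crosses_per_year * 4 + 8
  id <- pf <- pm <- ct <- character(cap)
  yoo <- integer(cap)
  interm <- logical(cap)
  gval <- numeric(cap)
  A <- matrix(0, cap, cap)
  n <- 0L
  pos <- new.env(parent = emptyenv())

  add_entry <- function(gid, s, d, year, type, intermediate) {
    i <- n + 1L
    id[i] <<- gid; pf[i] <<- s; pm[i] <<- d
    yoo[i] <<- year; ct[i] <<- type; interm[i] <<- intermediate
    si <- if (is_unknown_parent(s)) NA_integer_ else get(s, envir = pos)
    di <- if (is_unknown_parent(d)) NA_integer_ else get(d, envir = pos)
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      row_s <- if (is.na(si)) numeric(i - 1L) else A[prev, si]
      row_d <- if (is.na(di)) numeric(i - 1L) else A[prev, di]
      aij <- 0.5 * (row_s + row_d)
      A[prev, i] <<- aij
      A[i, prev] <<- aij
    }
    asd <- if (is.na(si) || is.na(di)) 0 else A[si, di]
    A[i, i] <<- 1 + 0.5 * asd
    if (is.na(si) && is.na(di)) {
      gval[i] <<- cfg$mu_yield + stream_draw(vs, function() rnorm(1, 0, sdg))
    } else {
      fbar <- mean(c(if (is.na(si)) 0 else A[si, si] - 1,
                     if (is.na(di)) 0 else A[di, di] - 1))
      ms_sd <- sqrt(max(0.5 * cfg$sigma2_g * (1 - fbar), 0))
      mid <- mean(c(if (is.na(si)) cfg$mu_yield else gval[si],
                    if (is.na(di)) cfg$mu_yield else gval[di]))
      gval[i] <<- mid + stream_draw(vs, function() rnorm(1, 0, ms_sd))
    }
    assign(gid, i, envir = pos)
    n <<- i
    gid
  }

  for (i in seq_len(cfg$n_founders)) {
    add_entry(sprintf("F%03d", i), "0", "0", cfg$first_year, "founder", FALSE)
  }

  for (t in seq_len(cfg$n_years_crossing)) {
    year <- cfg$first_year + t
    cand <- which(!interm[seq_len(n)] & yoo[seq_len(n)] < year)
    sel_n <- max(2L, ceiling(cfg$selection_fraction * length(cand)))
    sel <- cand[order(gval[cand], decreasing = TRUE)][seq_len(min(sel_n, length(cand)))]
    for (k in seq_len(cfg$crosses_per_year)) {
      avail <- names(cfg$cross_type_mix)[vapply(names(cfg$cross_type_mix), function(ty) {
        cross_type_feasible(ty, sel, yoo, year)
      }, logical(1))]
      mix <- cfg$cross_type_mix[avail]
      if (length(avail) == 0 || sum(mix) <= 0) {
        avail <- "single"; mix <- c(single = 1)
      }
      type <- stream_draw(ss, function() {
        sample(avail, 1, prob = mix / sum(mix))
      })
      d <- cross_depth[[type]]
      elig <- sel[yoo[sel] <= year - 1L - d]
      par <- stream_draw(ss, function() {
        sample(elig, cross_nparents[[type]])
      })
      gid <- sprintf("C%d-%03d", year, k)
      pid <- id[par]
      switch(type,
        single = add_entry(gid, pid[1], pid[2], year, "single", FALSE),
        double = {
          i1 <- add_entry(paste0("X", year, "-", k, "a"), pid[1], pid[2],
                          year - 1L, "intermediate", TRUE)
          i2 <- add_entry(paste0("X", year, "-", k, "b"), pid[3], pid[4],
                          year - 1L, "intermediate", TRUE)
          add_entry(gid, i1, i2, year, "double", FALSE)
        },
        three_way = {
          i1 <- add_entry(paste0("X", year, "-", k, "a"), pid[1], pid[2],
                          year - 1L, "intermediate", TRUE)
          add_entry(gid, i1, pid[3], year, "three_way", FALSE)
        },
        backcross = {
          i1 <- add_entry(paste0("X", year, "-", k, "a"), pid[1], pid[2],
                          year - 1L, "intermediate", TRUE)
          add_entry(gid, i1, pid[1], year, "backcross", FALSE)
        },
        complex = {
          i1 <- add_entry(paste0("X", year, "-", k, "a"), pid[1], pid[2],
                          year - 2L, "intermediate", TRUE)
          i2 <- add_entry(paste0("X", year, "-", k, "b"), i1, pid[3],
                          year - 1L, "intermediate", TRUE)
          add_entry(gid, i2, pid[4], year, "complex", FALSE)
        }
      )
    }
  }

  take <- seq_len(n)
  ped <- tibble(
    genotype = id[take], parent_f = pf[take], parent_m = pm[take],
    year_of_origin = yoo[take], cross_type = ct[take],
    is_intermediate = interm[take],
    year_of_release = NA_integer_
  )
  # one release per crossing-year cohort: its top genotype by true value,
  # released four years after the cross (deterministic given values)
  for (yr in unique(ped$year_of_origin[!ped$is_intermediate &
                                       ped$cross_type != "founder"])) {
    cohort <- which(!interm[take] & yoo[take] == yr & ct[take] != "founder")
    if (length(cohort) > 0) {
      best <- cohort[which.max(gval[cohort])]
      ped$year_of_release[best] <- yr + 4L
    }
  }
  list(pedigree = ped, gval = setNames(gval[take], id[take]))
}

cross_type_feasible <- function(type, sel, yoo, year) {
  d <- cross_depth[[type]]
  sum(yoo[sel] <= year - 1L - d) >= cross_nparents[[type]]
}

#' Simulate a breeding-program pedigree
#'
#' Builds a multi-year crossing program: a founder set, then yearly cohorts
#' of crosses whose parents are chosen by truncation selection on true
#' genetic value (top `selection_fraction` of earlier genotypes). Double,
#' three-way, complex and backcrosses are realized as chains of intermediate
#' single crosses (extra pedigree rows flagged `is_intermediate`), so every
#' entry has exactly two parent slots; intermediates are back-dated so every
#' parent has a strictly earlier year of origin than its offspring, which
#' makes the pedigree acyclic by construction. One genotype per cohort (its
#' best by true value) receives a `year_of_release` four years after the
#' cross.
#'
#' @param config A [sim_config()].
#' @return A tibble: `genotype`, `parent_f`, `parent_m` (`"0"` = unknown),
#'   `year_of_origin`, `cross_type`, `is_intermediate`, `year_of_release`,
#'   in creation (topological) order.
#' @export
simulate_pedigree <- function(config) {
  config <- validate_sim_config(config)
  sim_program_core(config)$pedigree
}

#' Simulate true genetic values over a pedigree
#'
#' Walks the pedigree in row order drawing one value per entry: founders
#' (unknown parents) from `N(mu_yield, sigma2_g)`, non-founders as the
#' parent average plus a Mendelian-sampling deviate
#' `N(0, 0.5 sigma2_g (1 - Fbar))`, with parental inbreeding `Fbar` from
#' the A-matrix diagonal. Values are on the yield scale (baseline mean plus
#' additive merit). The same config seed used by [simulate_pedigree()]
#' reproduces exactly the values under which parents were selected.
#'
#' @param pedigree A pedigree tibble in the row order emitted by
#'   [simulate_pedigree()] (topological order is required).
#' @param config The same [sim_config()].
#' @return A `truth_set` list: `true_bv` (named vector, kg/ha),
#'   `realized_trend_slope` (kg/ha per year of origin, OLS over primary
#'   entries), `realized_trend_percent` (percent of the mean true value).
#' @export
simulate_true_values <- function(pedigree, config) {
  config <- validate_sim_config(config)
  vs <- rng_stream(seed_offset(config$seed, 1))
  sdg <- sqrt(config$sigma2_g)
  A <- build_a_matrix(pedigree)
  # build_a_matrix re-sorts; map F back to input order
  Fcoef <- setNames(diag(A) - 1, rownames(A))

  ids <- as.character(pedigree$genotype)
  pf <- as.character(pedigree$parent_f)
  pm <- as.character(pedigree$parent_m)
  val <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    s_unk <- is_unknown_parent(pf[i]); d_unk <- is_unknown_parent(pm[i])
    if (s_unk && d_unk) {
      val[i] <- config$mu_yield + stream_draw(vs, function() rnorm(1, 0, sdg))
    } else {
      if ((!s_unk && !pf[i] %in% ids[seq_len(i - 1)]) ||
          (!d_unk && !pm[i] %in% ids[seq_len(i - 1)])) {
        abort("pedigree rows must be in topological (parent-first) order",
              class = "breedgain_pedigree_error")
      }
      fbar <- mean(c(if (s_unk) 0 else Fcoef[[pf[i]]],
                     if (d_unk) 0 else Fcoef[[pm[i]]]))
      ms_sd <- sqrt(max(0.5 * config$sigma2_g * (1 - fbar), 0))
      mid <- mean(c(if (s_unk) config$mu_yield else val[[pf[i]]],
                    if (d_unk) config$mu_yield else val[[pm[i]]]))
      val[i] <- mid + stream_draw(vs, function() rnorm(1, 0, ms_sd))
    }
  }

  primary <- if ("is_intermediate" %in% names(pedigree)) {
    !pedigree$is_intermediate
  } else {
    rep(TRUE, nrow(pedigree))
  }
  yrs <- pedigree$year_of_origin[primary]
  v <- val[primary]
  slope <- if (length(unique(yrs)) < 2) 0 else unname(coef(lm(v ~ yrs))[2])
  structure(list(
    true_bv = val,
    realized_trend_slope = slope,
    realized_trend_percent = 100 * slope / mean(v)
  ), class = "truth_set")
}
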