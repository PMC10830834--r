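# Two-stage weighted mixed-model analysis: per-year genotype BLUEs with a
# days-to-flowering covariate (stage 1), per-season Cullis heritability, and
# breeding values with reliability from a weighted pedigree-BLUP (stage 2).

# composite design-factor columns, unique across trials so IID blocking
# effects from different trials never share a level
add_blocking_columns <- function(df) {
  tr <- trial_id(df)
  mk <- function(...) {
    parts <- list(...)
    isna <- Reduce(`|`, lapply(parts, is.na))
    out <- do.call(paste, c(parts, sep = ":"))
    out[isna] <- NA_character_
    out
  }
  df$.rep <- mk(tr, df$rep)
  df$.block <- mk(tr, df$rep, df$block)
  df$.row <- mk(tr, df$rep, df$row)
  df$.col <- mk(tr, df$rep, df$col)
  df
}

stage1_random_terms <- function(df, include_season = TRUE) {
  terms <- list()
  groupings <- list()
  if (include_season && length(unique(df$season)) > 1) {
    terms$season <- "iid"
    groupings$season <- as.integer(factor(df$season))
  }
  for (f in c(".rep", ".block", ".row", ".col")) {
    x <- df[[f]]
    if (sum(!is.na(x)) == 0 || length(unique(x[!is.na(x)])) < 2) next
    codes <- as.integer(factor(x))
    # skip factors whose grouping duplicates an already-included term
    # (e.g. one block per replicate): the variance split is unidentifiable
    dup <- any(vapply(groupings, function(g) identical(g, codes), logical(1)))
    if (dup) next
    terms[[f]] <- "iid"
    groupings[[f]] <- codes
  }
  terms
}

#' Stage 1: per-year genotype BLUEs, standard errors and weights
#'
#' For each year, fits a mixed model with genotype as fixed, season as
#' random (or fixed, see `season_role`), the design-specific blocking
#' factors (replicate, block nested in replicate, row, column — labelled
#' per trial) as IID random effects, and days to flowering as a fixed
#' covariate. Genotype BLUEs are adjusted means evaluated at the mean DTF.
#' The reported standard error is that of the genotype's deviation contrast
#' (its adjusted mean relative to the mean of all genotype adjusted means),
#' computed from the full fixed-effect covariance; this removes the
#' year-common intercept/season uncertainty, which carries no information
#' about genotype comparisons but would distort the stage-2 weights. The
#' stage-2 weight is `1 / se^2`. Cullis heritability is computed per
#' year-by-season slice with [cullis_h2()].
#'
#' @param table A QC'd phenotype tibble.
#' @param use_dtf_covariate Include the DTF covariate?
#' @param season_role `"random"` (default) or `"fixed"`.
#' @param compute_h2 Also fit the per-season heritability models? Skipping
#'   them roughly halves the cost when only BLUEs are needed.
#' @return A `stage1_result`: `blues` tibble (`year`, `genotype`, `blue`,
#'   `se`, `weight`), `h2` tibble (`year`, `season`, `h2`, `sigma2_g`,
#'   `sigma2_e`), `skipped` (years that could not be fit, with reasons).
#' @export
stage1_by_year <- function(table, use_dtf_covariate = TRUE,
                           season_role = c("random", "fixed"),
                           compute_h2 = TRUE) {
  season_role <- match.arg(season_role)
  assert_columns(table, c("genotype", "year", "season", "location",
                          "yield_kg_ha"), "phenotype table")
  df <- add_blocking_columns(as_tibble(table))
  blues <- list()
  h2s <- list()
  skipped <- tibble(year = integer(), reason = character())

  for (yr in sort(unique(df$year))) {
    dy <- df[df$year == yr & !is.na(df$yield_kg_ha), ]
    if (nrow(dy) == 0) next
    fixed <- "genotype"
    if (use_dtf_covariate) fixed <- c(fixed, "dtf")
    random <- stage1_random_terms(dy, include_season = season_role == "random")
    if (season_role == "fixed" && length(unique(dy$season)) > 1) {
      fixed <- c(fixed, "season")
    }
    spec <- model_spec("yield_kg_ha", fixed = fixed, random = random)
    res <- tryCatch({
      dm <- build_design(dy, spec)
      vc <- reml_fit(dm)
      fit <- solve_mme(dm, vc)
      extract_blues(dm, fit, use_dtf = use_dtf_covariate &&
                      "dtf" %in% colnames_of_fixed(dm))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- bind_rows(skipped, tibble(year = yr,
                                           reason = conditionMessage(res)))
      next
    }
    blues[[as.character(yr)]] <- mutate(res, year = yr, .before = 1)

    if (!compute_h2) next
    for (sn in unique(dy$season)) {
      slice <- dy[dy$season == sn, ]
      ch <- tryCatch(cullis_h2(slice, use_dtf_covariate = use_dtf_covariate),
                     error = function(e) NULL)
      if (!is.null(ch)) {
        h2s[[paste(yr, sn)]] <- tibble(year = yr, season = sn,
                                       h2 = ch$h2, sigma2_g = ch$sigma2_g,
                                       sigma2_e = ch$sigma2_e,
                                       boundary = ch$boundary)
      }
    }
  }
  structure(list(blues = bind_rows(blues), h2 = bind_rows(h2s),
                 skipped = skipped),
            class = "stage1_result")
}

colnames_of_fixed <- function(dm) colnames(dm$X)

# Adjusted genotype means at mean DTF from a stage-1 fit: L b with L the
# intercept + genotype dummy (+ mean-DTF covariate) rows. The SE is the
# standard error of the genotype's *deviation contrast* (its adjusted mean
# relative to the mean of all genotype adjusted means), from the full
# fixed-effect covariance: the common intercept/season uncertainty is
# irrelevant to genotype comparisons and, being re-estimated per year from
# few season levels, would otherwise distort the stage-2 weights across
# years.
extract_blues <- function(dm, fit, use_dtf) {
  X <- dm$X
  genos <- unique(as.character(dm$data$genotype))
  cols <- colnames(X)
  L <- matrix(0, length(genos), length(cols),
              dimnames = list(genos, cols))
  L[, "(Intercept)"] <- 1
  for (g in genos) {
    nm <- paste0("genotype", g)
    if (nm %in% cols) L[g, nm] <- 1
  }
  if (use_dtf && "dtf" %in% cols) L[, "dtf"] <- mean(dm$data$dtf)
  # fixed season: average over season levels
  sea <- grep("^season", cols, value = TRUE)
  if (length(sea) > 0) {
    n_lev <- length(sea) + 1
    L[, sea] <- 1 / n_lev
  }
  b <- fit$fixed$estimate
  est <- drop(L %*% b)
  Ld <- sweep(L, 2, colMeans(L))
  se <- sqrt(pmax(diag(Ld %*% fit$fixed_cov %*% t(Ld)), 0))
  tibble(genotype = genos, blue = unname(est), se = unname(se),
         weight = 1 / unname(se)^2)
}

#' Cullis heritability for one year-by-season slice
#'
#' Fits the stage-1 model modified as the generalized-heritability method
#' requires: genotype random (IID), design blocking factors random, DTF
#' covariate fixed, no season term (the slice is a single season). Returns
#' `H^2 = 1 - Vbar_BLUP / (2 sigma2_g)` where `Vbar_BLUP` is the mean
#' variance of a difference between two genotype BLUPs, computed from the
#' full PEV block of the genotype term. The estimate is clamped to [0, 1];
#' if the genetic variance is at its boundary floor the heritability is 0
#' and flagged.
#'
#' @param table_one_slice Phenotype records of one year-by-season trial set.
#' @param use_dtf_covariate Include the DTF covariate?
#' @param vc Optional fixed variance components (named vector with entries
#'   `genotype` and `residual`, plus any blocking terms) to use instead of
#'   REML estimates — useful for validating the PEV algebra at known
#'   components.
#' @return A list: `h2`, `sigma2_g`, `sigma2_e`, `vbar_blup`, `boundary`.
#' @export
cullis_h2 <- function(table_one_slice, use_dtf_covariate = TRUE, vc = NULL) {
  df <- as_tibble(table_one_slice)
  if (length(unique(paste(df$year, df$season))) > 1) {
    abort("cullis_h2 expects a single year-by-season slice")
  }
  if (length(unique(df$genotype[!is.na(df$yield_kg_ha)])) < 2) {
    abort("need >= 2 genotypes with records", class = "breedgain_model_error")
  }
  if (!".rep" %in% names(df)) df <- add_blocking_columns(df)
  random <- c(list(genotype = "iid"),
              stage1_random_terms(df, include_season = FALSE))
  fixed <- character()
  if (use_dtf_covariate && "dtf" %in% names(df)) fixed <- "dtf"
  spec <- model_spec("yield_kg_ha", fixed = fixed, random = random)
  dm <- build_design(df, spec)
  if (is.null(vc)) {
    vc <- reml_fit(dm)
    sigma2 <- vc$sigma2
  } else {
    sigma2 <- if (inherits(vc, "variance_components")) vc$sigma2 else vc
    missing <- setdiff(names(dm$Z), names(sigma2))
    if (length(missing) > 0) {
      sigma2[missing] <- sigma2[["residual"]]
    }
  }
  fit <- solve_mme(dm, sigma2)
  s2g <- sigma2[["genotype"]]
  s2e <- sigma2[["residual"]]
  floor_v <- 1e-8 * max(var(dm$y), .Machine$double.eps)
  boundary <- s2g <= floor_v * (1 + 1e-6)
  if (boundary) {
    return(list(h2 = 0, sigma2_g = s2g, sigma2_e = s2e,
                vbar_blup = NA_real_, boundary = TRUE))
  }
  vbar <- vbar_blup(fit, "genotype")
  list(h2 = clamp01(1 - vbar / (2 * s2g)), sigma2_g = unname(s2g),
       sigma2_e = unname(s2e), vbar_blup = vbar, boundary = FALSE)
}

#' Stage 2: breeding values from weighted BLUEs
#'
#' Combines the stage-1 BLUEs in a weighted mixed model: response = BLUE,
#' observation weights = `1/se^2` entering the residual precision, year as
#' fixed, genotype random with covariance `sigma2_g A` (pedigree mode) or
#' `sigma2_g I` (`a = NULL`, the no-pedigree mode in which the predictions
#' are plain BLUPs). Variance components are estimated by REML. The
#' reported breeding value is the mean fitted year level plus the genotype
#' prediction, so it is on the yield scale; reliability is
#' `1 - PEV / sigma2_g`, clamped to [0, 1] with clamp events counted.
#'
#' @param s1 A `stage1_result` (or its `blues` tibble).
#' @param a Optional A-matrix from [build_a_matrix()]. Every phenotyped
#'   genotype must appear in it; genotypes present in `a` but never
#'   phenotyped also receive predictions through the pedigree (flagged
#'   `phenotyped = FALSE`).
#' @return A `stage2_result`: `values` tibble (`genotype`,
#'   `breeding_value`, `pev`, `reliability`, `n_years`, `phenotyped`),
#'   `sigma2_g`, `sigma2_e`, `year_effects`, `convergence`, `n_clamped`.
#' @export
stage2_blup <- function(s1, a = NULL) {
  blues <- if (inherits(s1, "stage1_result")) s1$blues else as_tibble(s1)
  if (nrow(blues) == 0) abort("stage-1 result is empty",
                              class = "breedgain_model_error")
  assert_columns(blues, c("year", "genotype", "blue", "se", "weight"),
                 "stage-1 BLUEs")
  blues <- mutate(blues, year = factor(as.character(.data$year)))
  random <- if (is.null(a)) {
    list(genotype = "iid")
  } else {
    missing <- setdiff(unique(blues$genotype), rownames(a))
    if (length(missing) > 0) {
      abort(sprintf("A-matrix is missing phenotyped genotype(s): %s",
                    paste(head(missing, 10), collapse = ", ")),
            class = "breedgain_model_error")
    }
    list(genotype = unclass(a))
  }
  spec <- model_spec("blue", fixed = "year", random = random,
                     weights = "weight")
  dm <- build_design(blues, spec)
  vc <- reml_fit(dm)
  fit <- solve_mme(dm, vc)
  s2g <- vc$sigma2[["genotype"]]
  s2e <- vc$sigma2[["residual"]]

  # mean fitted year level (equal weight per observed year)
  yrs <- levels(blues$year)
  cols <- colnames(dm$X)
  Ly <- matrix(0, length(yrs), length(cols), dimnames = list(yrs, cols))
  Ly[, "(Intercept)"] <- 1
  for (yr in yrs) {
    nm <- paste0("year", yr)
    if (nm %in% cols) Ly[yr, nm] <- 1
  }
  year_effects <- tibble(year = yrs,
                         mean_yield = drop(Ly %*% fit$fixed$estimate))
  base <- mean(year_effects$mean_yield)

  g <- fit$random$genotype
  reliab_raw <- 1 - g$pev / s2g
  n_clamped <- sum(reliab_raw < 0 | reliab_raw > 1)
  nrec <- count(blues, .data$genotype, name = "n_years")
  values <- g |>
    rename(genotype = "level") |>
    mutate(breeding_value = base + .data$blup,
           reliability = clamp01(reliab_raw)) |>
    left_join(nrec, by = "genotype") |>
    mutate(n_years = if_else(is.na(.data$n_years), 0L, .data$n_years),
           phenotyped = .data$n_years > 0L) |>
    select("genotype", "breeding_value", "pev", "reliability",
           "n_years", "phenotyped")
  structure(list(values = values, sigma2_g = unname(s2g),
                 sigma2_e = unname(s2e), year_effects = year_effects,
                 base = base,
                 convergence = vc$convergence, n_clamped = n_clamped),
            class = "stage2_result")
}
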