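# Phenotype ingestion and quality control: trial-level filters and the
# Holm-adjusted studentized-residual outlier screen.

pheno_cols <- c("genotype", "year", "season", "location", "design",
                "rep", "block", "row", "col", "yield_kg_ha", "dtf")

# which factor columns each design must provide (entirely absent ones mean
# a missing replication / design error at the trial level)
design_factors <- list(
  rcbd = c("rep", "block"),
  augmented_rcbd = c("rep", "block"),
  alpha_lattice = c("rep", "block"),
  row_column = c("row", "col")
)

#' Read a phenotype table
#'
#' Reads a long-format plot table (one row per plot) with the columns
#' written by [write_simdata()]. Unparseable yield cells become missing
#' values rather than errors; the parse log is attached as an attribute.
#'
#' @param path Path to a CSV file.
#' @return A typed tibble of phenotype records; attribute `parse_log`.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  assert_columns(df, setdiff(pheno_cols, c("rep", "block", "row", "col")),
                 "phenotype table")
  log <- character()
  for (col in setdiff(c("plot_id", pheno_cols), names(df))) {
    df[[col]] <- NA_character_
  }
  num <- suppressWarnings(as.numeric(df$yield_kg_ha))
  bad <- !is.na(df$yield_kg_ha) & df$yield_kg_ha != "NA" & is.na(num)
  if (any(bad)) {
    log <- c(log, sprintf("%d unparseable yield cell(s) set to missing", sum(bad)))
  }
  df$yield_kg_ha <- num
  df$year <- suppressWarnings(as.integer(df$year))
  df$dtf <- suppressWarnings(as.integer(df$dtf))
  out <- as_tibble(df[, c("plot_id", pheno_cols)])
  if (all(is.na(out$plot_id))) out$plot_id <- sprintf("P%07d", seq_len(nrow(out)))
  attr(out, "parse_log") <- log
  out
}

#' Filter trials by quality rules
#'
#' A trial is one year-by-season-by-location combination. Trials are dropped
#' when (i) the proportion of missing yields strictly exceeds `max_missing`,
#' (ii) a factor column mandated by the trial's design is entirely absent
#' (missing replication / design error), or (iii) any yield falls outside
#' the plausibility interval `[0, aberrant_max]`.
#'
#' @param table A phenotype tibble.
#' @param max_missing Maximum tolerated missing-yield proportion (strict
#'   inequality; exactly `max_missing` is retained).
#' @param aberrant_max Upper plausibility bound for yield, kg/ha.
#' @return A list: `data` (retained records) and `report` (a `qc_report`
#'   with per-trial reasons and counts).
#' @export
filter_trials <- function(table, max_missing = 0.20, aberrant_max = 20000) {
  assert_columns(table, c("year", "season", "location", "design",
                          "yield_kg_ha"), "phenotype table")
  table <- as_tibble(table)
  tid <- trial_id(table)
  trials <- unique(tid)
  reasons <- tibble(trial = character(), reason = character())
  keep_trial <- setNames(rep(TRUE, length(trials)), trials)
  for (tr in trials) {
    rows <- table[tid == tr, ]
    reason <- NULL
    prop_missing <- mean(is.na(rows$yield_kg_ha))
    fac <- design_factors[[rows$design[1]]]
    if (!is.null(fac) && any(vapply(fac, function(f) {
      !f %in% names(rows) || all(is.na(rows[[f]]))
    }, logical(1)))) {
      reason <- c(reason, "missing_replication")
    }
    if (is.null(design_factors[[rows$design[1]]])) {
      reason <- c(reason, "design_error")
    }
    if (prop_missing > max_missing) reason <- c(reason, "excess_missing")
    yy <- rows$yield_kg_ha[!is.na(rows$yield_kg_ha)]
    if (any(yy < 0 | yy > aberrant_max)) reason <- c(reason, "aberrant_values")
    if (!is.null(reason)) {
      keep_trial[tr] <- FALSE
      reasons <- bind_rows(reasons, tibble(trial = tr, reason = reason))
    }
  }
  kept <- table[keep_trial[tid], ]
  report <- structure(list(
    trials_in = length(trials),
    trials_dropped = sum(!keep_trial),
    drop_reasons = reasons,
    outliers_flagged = tibble(plot_id = character(), trial = character(),
                              studentized_residual = numeric(),
                              p_adjusted = numeric()),
    records_retained = nrow(kept)
  ), class = "qc_report")
  list(data = kept, report = report)
}

#' Flag outliers by the Holm-adjusted studentized-residual test
#'
#' Per trial, fits a mixed working model — genotype and the design's
#' available factor columns as IID random effects, following the
#' phenotypic-screening practice for series of breeding trials (a
#' fixed-genotype model would give unreplicated entries, the bulk of an
#' augmented design, zero residuals and make their contamination
#' undetectable). Conditional residuals are studentized with their exact
#' model variance `diag(R - M C^-1 M')`, converted to externally
#' studentized (deletion-style) statistics. Screening has two phases:
#' candidate outliers are found iteratively with robustly rescaled
#' residuals (gross outliers inflate the residual variance and would
#' otherwise mask milder ones), then every candidate is confirmed as an
#' exact deletion residual against a refit on the clean records, with
#' Holm's step-down procedure at family-wise level `alpha` over the full
#' trial. Flagged yields are set to missing (rows are kept, preserving
#' the design structure). Trials too small to screen are skipped with a
#' warning.
#'
#' @param table A phenotype tibble (typically after [filter_trials()]).
#' @param alpha Family-wise error level per trial.
#' @return A list: `data` (yields of flagged records set to `NA`) and
#'   `report` (a `qc_report` listing flags with residuals and adjusted
#'   p-values).
#' @export
detect_outliers_bh <- function(table, alpha = 0.05) {
  assert_columns(table, c("plot_id", "genotype", "year", "season", "location",
                          "yield_kg_ha"), "phenotype table")
  table <- as_tibble(table)
  tid <- trial_id(table)
  flags <- list()
  skipped <- character()
  for (tr in unique(tid)) {
    rows <- table[tid == tr & !is.na(table$yield_kg_ha), ]
    if (nrow(rows) < 5) next
    res <- tryCatch(screen_trial(rows, alpha), error = function(e) NULL)
    if (is.null(res)) {
      skipped <- c(skipped, tr)
      next
    }
    if (nrow(res) > 0) {
      res$trial <- tr
      flags[[tr]] <- res
    }
  }
  if (length(skipped) > 0) {
    warn(sprintf("trial(s) with no residual degrees of freedom skipped: %s",
                 paste(skipped, collapse = ", ")))
  }
  flagged <- bind_rows(flags)
  if (nrow(flagged) > 0) {
    table$yield_kg_ha[table$plot_id %in% flagged$plot_id] <- NA_real_
  }
  report <- structure(list(
    trials_in = length(unique(tid)),
    trials_dropped = 0L,
    drop_reasons = tibble(trial = character(), reason = character()),
    outliers_flagged = flagged,
    records_retained = sum(!is.na(table$yield_kg_ha))
  ), class = "qc_report")
  list(data = table, report = report)
}

# Mixed-model outlier screen for one trial's non-missing records: genotype
# and blocking factors random, intercept fixed. Phase 1 finds candidate
# outliers iteratively with MAD-inflated studentized residuals (robust to
# the variance inflation gross outliers cause); phase 2 confirms each
# candidate as an exact deletion residual against a clean refit, with
# Holm at the full trial family size. Returns the confirmed rows.
screen_trial <- function(rows, alpha, max_pass = 4) {
  random <- list(genotype = "iid")
  for (f in c("rep", "block", "row", "col")) {
    if (f %in% names(rows) && sum(!is.na(rows[[f]])) > 0 &&
        length(unique(rows[[f]][!is.na(rows[[f]])])) > 1) {
      random[[f]] <- "iid"
    }
  }
  spec <- model_spec("yield_kg_ha", random = random)
  n_all <- nrow(rows)

  fit_screen <- function(active) {
    dm <- build_design(active, spec)
    # coarse components suffice for screening
    vc <- reml_fit(dm, max_iter = 25, tol = 1e-5, optim_maxit = 40,
                   factr = 1e9)
    gs <- prep_gstruct(dm)
    eng <- mme_engine(dm, gs, vc$sigma2, want_inverse = TRUE)
    M <- do.call(cbind, c(list(dm$X), unname(dm$Z)))
    list(dm = dm, vc = vc, eng = eng, M = M,
         resid = dm$y - drop(M %*% eng$sol))
  }

  # phase 1: iterative candidate detection with robust rescaling
  candidates <- character()
  active <- rows
  for (pass in seq_len(max_pass)) {
    if (nrow(active) < 5) break
    f <- fit_screen(active)
    s2e <- f$vc$sigma2[["residual"]]
    v_e <- pmax(s2e - rowSums((f$M %*% f$eng$Cinv) * f$M), s2e * 1e-8)
    r <- f$resid / sqrt(v_e)
    # inflate only: gross outliers deflate the studentized scale and
    # would mask milder ones
    r <- r / min(1, 1.4826 * median(abs(r)))
    nu <- length(f$dm$y) - ncol(f$dm$X)
    if (nu < 3) abort("no residual degrees of freedom")
    r2 <- pmin(r^2, nu - 1e-8)
    t_ext <- r * sqrt((nu - 1) / (nu - r2))
    padj <- p.adjust(2 * pt(-abs(t_ext), df = nu - 1), method = "holm")
    hit <- padj < alpha
    if (!any(hit)) break
    candidates <- c(candidates, f$dm$data$plot_id[hit])
    active <- active[!active$plot_id %in% candidates, ]
  }
  if (length(candidates) == 0) {
    return(tibble(plot_id = character(), studentized_residual = numeric(),
                  p_adjusted = numeric()))
  }

  # phase 2: exact deletion test of each candidate against the clean fit
  clean <- rows[!rows$plot_id %in% candidates, ]
  if (nrow(clean) < 5) abort("too few clean records to confirm candidates")
  f <- fit_screen(clean)
  s2e <- f$vc$sigma2[["residual"]]
  nu <- length(f$dm$y) - ncol(f$dm$X)
  if (nu < 3) abort("no residual degrees of freedom")
  cand_rows <- rows[match(candidates, rows$plot_id), ]
  cols_all <- c(colnames(f$dm$X),
                unlist(lapply(f$dm$Z, colnames), use.names = FALSE))
  tstat <- vapply(seq_len(nrow(cand_rows)), function(i) {
    cr <- cand_rows[i, ]
    m <- numeric(length(cols_all))
    names(m) <- NULL
    pos <- 1L
    m[1] <- 1  # intercept
    extra_var <- 0
    off <- ncol(f$dm$X)
    for (term in names(f$dm$Z)) {
      lev <- as.character(cr[[term]])
      levs <- colnames(f$dm$Z[[term]])
      j <- match(lev, levs)
      if (!is.na(lev) && !is.na(j)) {
        m[off + j] <- 1
      } else if (!is.na(lev)) {
        # level held out entirely: its effect is predicted as 0 with the
        # full prior variance
        extra_var <- extra_var + f$vc$sigma2[[term]]
      }
      off <- off + length(levs)
    }
    pred <- sum(m * f$eng$sol)
    pev <- drop(t(m) %*% f$eng$Cinv %*% m)
    (cr$yield_kg_ha - pred) / sqrt(s2e + pev + extra_var)
  }, numeric(1))
  # Holm at the full family size of the trial
  p_raw <- 2 * pt(-abs(tstat), df = nu)
  p_adj <- pmin(1, p_raw * (n_all - rank(p_raw) + 1))
  p_adj <- cummax(p_adj[order(p_raw)])[order(order(p_raw))]
  hit <- p_adj < alpha
  tibble(plot_id = candidates[hit],
         studentized_residual = unname(tstat[hit]),
         p_adjusted = unname(p_adj[hit]))
}

#' Run the full quality-control stage
#'
#' [filter_trials()] followed by [detect_outliers_bh()].
#'
#' @inheritParams filter_trials
#' @inheritParams detect_outliers_bh
#' @return A list: `data`, `filter_report`, `outlier_report`.
#' @export
run_qc <- function(table, max_missing = 0.20, aberrant_max = 20000,
                   alpha = 0.05) {
  f <- filter_trials(table, max_missing = max_missing,
                     aberrant_max = aberrant_max)
  o <- detect_outliers_bh(f$data, alpha = alpha)
  list(data = o$data, filter_report = f$report, outlier_report = o$report)
}
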