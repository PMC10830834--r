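# Elite-panel selection and GGE stability ranking.

#' Select the elite breeding panel
#'
#' Keeps genotypes with breeding value strictly above `bv_threshold` and
#' reliability strictly above `rel_threshold`, sorted by descending
#' breeding value, optionally truncated to the top `top_n` (boundary ties
#' broken by higher reliability, then genotype id, so the selection is
#' deterministic and invariant to input row order).
#'
#' @param s2 A `stage2_result` (or a data frame with `genotype`,
#'   `breeding_value`, `reliability`).
#' @param bv_threshold Breeding-value threshold, kg/ha. No default:
#'   programs differ, and the threshold is a deliberate choice.
#' @param rel_threshold Reliability threshold.
#' @param top_n Optional cap on panel size.
#' @return An `elite_panel`: the selected rows plus a `criteria` attribute.
#' @export
select_elite <- function(s2, bv_threshold, rel_threshold = 0.4,
                         top_n = NULL) {
  values <- if (inherits(s2, "stage2_result")) s2$values else as_tibble(s2)
  assert_columns(values, c("genotype", "breeding_value", "reliability"),
                 "stage-2 values")
  sel <- values |>
    filter(.data$breeding_value > bv_threshold,
           .data$reliability > rel_threshold) |>
    arrange(dplyr::desc(.data$breeding_value),
            dplyr::desc(.data$reliability), .data$genotype)
  if (!is.null(top_n)) sel <- head(sel, top_n)
  if (nrow(sel) == 0) warn("elite panel is empty under these thresholds")
  structure(sel,
            criteria = list(bv_threshold = bv_threshold,
                            rel_threshold = rel_threshold,
                            top_n = top_n),
            class = c("elite_panel", class(sel)))
}

#' GGE analysis of a genotype-by-environment mean table
#'
#' Centers each environment column by its mean (tester-centered G + GE, no
#' scaling) and decomposes the centered table by SVD with row metric
#' preserved: genotype scores `U S`, environment scores `V`. The
#' average-environment axis is the direction of the mean environment score;
#' the ideal point lies on that axis at the largest genotype projection;
#' genotypes are ranked by ascending distance of their PC1-PC2 scores from
#' the ideal point.
#'
#' @param ge_means A complete genotype-by-environment table: either a
#'   numeric matrix with genotype rownames, or a data frame with a
#'   `genotype` column and one numeric column per environment. Missing
#'   cells are rejected.
#' @return A `gge_result`: `genotype_scores`, `environment_scores`,
#'   `pc_variance_pct`, `mean_env_axis`, `ideal_point`, `stability`
#'   (tibble with `genotype`, `distance`, `stability_rank`), `centered`.
#' @export
gge_analysis <- function(ge_means) {
  if (is.data.frame(ge_means)) {
    assert_columns(ge_means, "genotype", "GE table")
    m <- as.matrix(ge_means[, setdiff(names(ge_means), "genotype")])
    rownames(m) <- ge_means$genotype
  } else {
    m <- as.matrix(ge_means)
  }
  if (nrow(m) < 3 || ncol(m) < 2) {
    abort("need >= 3 genotypes and >= 2 environments",
          class = "breedgain_gge_error")
  }
  if (any(is.na(m))) {
    abort("GE table has missing cells; complete tables are required",
          class = "breedgain_gge_error")
  }
  centered <- sweep(m, 2, colMeans(m))
  if (max(abs(centered)) < 1e-10) {
    abort("degenerate table: no genotype or interaction signal after centering",
          class = "breedgain_gge_error")
  }
  sv <- svd(centered)
  k <- length(sv$d)
  # deterministic sign: orient each axis so the mean environment loading
  # is non-negative (falling back to the largest-magnitude loading)
  for (j in seq_len(k)) {
    s <- sum(sv$v[, j])
    if (s == 0) s <- sv$v[which.max(abs(sv$v[, j])), j]
    if (s < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  gscore <- sv$u %*% diag(sv$d, k)
  escore <- sv$v
  dimnames(gscore) <- list(rownames(m), paste0("PC", seq_len(k)))
  dimnames(escore) <- list(colnames(m), paste0("PC", seq_len(k)))
  pc_var <- 100 * sv$d^2 / sum(sv$d^2)

  axis <- colMeans(escore[, 1:2, drop = FALSE])
  axis_unit <- axis / sqrt(sum(axis^2))
  proj <- drop(gscore[, 1:2, drop = FALSE] %*% axis_unit)
  ideal <- axis_unit * max(proj)
  d2 <- sqrt(rowSums(sweep(gscore[, 1:2, drop = FALSE], 2, ideal)^2))
  stability <- tibble(genotype = rownames(m), distance = unname(d2)) |>
    arrange(.data$distance) |>
    mutate(stability_rank = row_number())

  structure(list(
    genotype_scores = gscore, environment_scores = escore,
    pc_variance_pct = pc_var, mean_env_axis = axis_unit,
    ideal_point = ideal, stability = stability, centered = centered,
    d = sv$d
  ), class = "gge_result")
}

#' Merged panel / stability report
#'
#' Joins elite-panel membership, breeding values, reliabilities and GGE
#' stability ranks into one table; genotypes present in the GGE table but
#' absent from the stage-2 values are listed, not errors.
#'
#' @param gge A `gge_result`.
#' @param panel An `elite_panel`.
#' @return A tibble: `genotype`, `breeding_value`, `reliability`,
#'   `distance`, `stability_rank`, `in_panel`.
#' @export
rank_report <- function(gge, panel) {
  stopifnot(inherits(gge, "gge_result"))
  pan <- as_tibble(panel)
  out <- gge$stability |>
    left_join(pan[, intersect(c("genotype", "breeding_value", "reliability"),
                              names(pan))],
              by = "genotype") |>
    mutate(in_panel = .data$genotype %in% pan$genotype) |>
    select(dplyr::any_of(c("genotype", "breeding_value", "reliability",
                           "distance", "stability_rank", "in_panel")))
  out
}
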