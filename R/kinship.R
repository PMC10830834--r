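#' Read a pedigree table
#'
#' Reads a pedigree CSV with columns `genotype`, `parent_f`, `parent_m` and
#' optional metadata columns (`year_of_origin`, `cross_type`,
#' `year_of_release`). Unknown parents may be coded `"0"`, an empty string or
#' `NA`. The result is topologically sorted so every parent precedes its
#' offspring, which is the order required by [build_a_matrix()].
#'
#' @param path Path to a CSV file.
#' @return A tibble of pedigree entries in topological order.
#' @export
read_pedigree <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  assert_columns(df, c("genotype", "parent_f", "parent_m"), "pedigree")
  for (col in intersect(c("year_of_origin", "year_of_release"), names(df))) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  sort_pedigree(as_tibble(df))
}

#' Topologically sort a pedigree
#'
#' Orders entries parent-first (Kahn's algorithm) and validates that no
#' genotype is its own ancestor and no genotype id is duplicated.
#'
#' @param pedigree A data frame with `genotype`, `parent_f`, `parent_m`.
#' @return The same rows, reordered so parents precede offspring.
#' @export
sort_pedigree <- function(pedigree) {
  assert_columns(pedigree, c("genotype", "parent_f", "parent_m"), "pedigree")
  ids <- as.character(pedigree$genotype)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate genotype id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "breedgain_pedigree_error")
  }
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  pf <- as.character(pedigree$parent_f)
  pm <- as.character(pedigree$parent_m)
  parent_idx <- function(p) {
    out <- rep(NA_integer_, n)
    known <- !is_unknown_parent(p)
    out[known] <- idx[p[known]]
    out
  }
  fi <- parent_idx(pf)
  mi <- parent_idx(pm)

  # Kahn: repeatedly emit entries whose (in-table) parents are already emitted.
  indeg <- (!is.na(fi)) + (!is.na(mi))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fi[i], mi[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0)
  order <- integer(0)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    member <- ids[setdiff(seq_len(n), order)[1]]
    abort(sprintf("pedigree contains a cycle involving genotype '%s'", member),
          class = "breedgain_pedigree_error")
  }
  as_tibble(pedigree[order, , drop = FALSE])
}

# Extend an additive relationship matrix by new pedigree rows (tabular
# method). `a` is the matrix for the first nrow(a) sorted entries; `pedigree`
# holds all entries in topological order. Returns the enlarged matrix.
extend_a_matrix <- function(a, pedigree) {
  ids <- as.character(pedigree$genotype)
  n <- length(ids)
  n0 <- nrow(a)
  if (n0 == n) return(a)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n0 > 0) out[seq_len(n0), seq_len(n0)] <- a
  idx <- setNames(seq_len(n), ids)
  pf <- as.character(pedigree$parent_f)
  pm <- as.character(pedigree$parent_m)
  for (i in seq.int(n0 + 1L, n)) {
    s <- if (is_unknown_parent(pf[i])) NA_integer_ else idx[[pf[i]]]
    d <- if (is_unknown_parent(pm[i])) NA_integer_ else idx[[pm[i]]]
    if ((!is.na(s) && s >= i) || (!is.na(d) && d >= i)) {
      abort("pedigree is not topologically sorted; call sort_pedigree() first",
            class = "breedgain_pedigree_error")
    }
    prev <- seq_len(i - 1L)
    row_s <- if (is.na(s)) numeric(i - 1L) else out[prev, s]
    row_d <- if (is.na(d)) numeric(i - 1L) else out[prev, d]
    if (i > 1L) {
      aij <- 0.5 * (row_s + row_d)
      out[prev, i] <- aij
      out[i, prev] <- aij
    }
    asd <- if (is.na(s) || is.na(d)) 0 else out[s, d]
    out[i, i] <- 1 + 0.5 * asd
  }
  out
}

#' Build the additive relationship matrix (tabular method)
#'
#' Computes the numerator relationship matrix A from a pedigree by the
#' recursive tabular method: for individual i with parents s and d,
#' `a_ii = 1 + a_sd / 2` and `a_ij = (a_js + a_jd) / 2` for earlier j.
#' Unknown parents contribute zero (treated as unrelated, non-inbred
#' founders). Entries are dyadic rationals; the diagonal is `1 + F_i` where
#' `F_i` is the inbreeding coefficient.
#'
#' @param pedigree A pedigree data frame; sorted with [sort_pedigree()] if
#'   not already parent-first.
#' @return An `a_matrix` object: a symmetric numeric matrix with genotype ids
#'   as dimnames.
#' @export
build_a_matrix <- function(pedigree) {
  pedigree <- sort_pedigree(pedigree)
  a <- extend_a_matrix(matrix(0, 0, 0), pedigree)
  class(a) <- c("a_matrix", class(a))
  a
}

#' Principal components of a relationship matrix
#'
#' Column-centers the A-matrix and extracts per-genotype scores on the
#' leading principal components, for diversity biplots of a breeding
#' population.
#'
#' @param a An A-matrix from [build_a_matrix()] (or any symmetric matrix with
#'   genotype dimnames).
#' @param n_components Number of components to return (truncated to the rank
#'   of the centered matrix, with a warning).
#' @return A list with `scores` (tibble: genotype, PC columns) and
#'   `explained` (variance fractions for all components, non-increasing,
#'   summing to 1).
#' @export
pca_on_a <- function(a, n_components = 2) {
  x <- sweep(unclass(a), 2, colMeans(a))
  p <- prcomp(x, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2
  keep <- ev > max(ev) * 1e-12
  expl <- ev / sum(ev)
  rank <- sum(keep)
  if (n_components > rank) {
    warn(sprintf("n_components = %d exceeds rank %d; truncated",
                 n_components, rank))
    n_components <- rank
  }
  scores <- as_tibble(p$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(genotype = rownames(a)), scores)
  list(scores = scores, explained = expl)
}

#' @importFrom stats prcomp
NULL
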