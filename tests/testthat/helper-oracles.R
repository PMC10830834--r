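# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# Random biparental pedigree: founders first, then individuals picking two
# (possibly identical, allowing selfing) parents among earlier entries.
random_pedigree <- function(n = 30, n_founders = 8, p_self = 0.05) {
  id <- sprintf("I%02d", seq_len(n))
  pf <- pm <- rep("0", n)
  for (i in (n_founders + 1):n) {
    s <- sample(i - 1L, 1)
    d <- if (runif(1) < p_self) s else sample(i - 1L, 1)
    pf[i] <- id[s]; pm[i] <- id[d]
  }
  tibble::tibble(genotype = id, parent_f = pf, parent_m = pm)
}

# Gene-dropping Monte Carlo estimate of the additive relationship matrix:
# drop two distinct alleles per founder down the pedigree, estimate
# relationship as twice the realized coancestry (mean fraction of the four
# allele comparisons that are identical by descent). Returns the estimate
# and the per-entry Monte-Carlo standard error.
gene_drop_a <- function(pedigree, n_drops = 1e5) {
  ids <- as.character(pedigree$genotype)
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  A1 <- matrix(0L, n_drops, n)
  A2 <- matrix(0L, n_drops, n)
  for (i in seq_len(n)) {
    s <- pedigree$parent_f[i]; d <- pedigree$parent_m[i]
    if (s %in% c("0", "", NA)) {
      A1[, i] <- 2L * i - 1L
    } else {
      si <- idx[[s]]
      pick <- stats::runif(n_drops) < 0.5
      A1[, i] <- ifelse(pick, A1[, si], A2[, si])
    }
    if (d %in% c("0", "", NA)) {
      A2[, i] <- 2L * i
    } else {
      di <- idx[[d]]
      pick <- stats::runif(n_drops) < 0.5
      A2[, i] <- ifelse(pick, A1[, di], A2[, di])
    }
  }
  est <- matrix(0, n, n, dimnames = list(ids, ids))
  se <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        x <- 1 + (A1[, i] == A2[, i])
      } else {
        x <- 0.5 * ((A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
                    (A2[, i] == A1[, j]) + (A2[, i] == A2[, j]))
      }
      est[i, j] <- est[j, i] <- mean(x)
      se[i, j] <- se[j, i] <- stats::sd(x) / sqrt(n_drops)
    }
  }
  list(est = est, se = se)
}

# Dense joint-covariance GLS / conditional-expectation oracle for the MME:
# V = sum_k sigma2_k Z_k G_k Z_k' + sigma2_e W^-1.
gls_oracle <- function(dm, sigma2) {
  n <- length(dm$y)
  V <- diag(sigma2[["residual"]] / dm$w, n)
  for (term in names(dm$Z)) {
    Zk <- dm$Z[[term]]
    Gk <- dm$G[[term]]
    V <- V + sigma2[[term]] *
      (if (is.null(Gk)) tcrossprod(Zk) else Zk %*% Gk %*% t(Zk))
  }
  Vi <- solve(V)
  X <- dm$X
  b <- drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% dm$y))
  res <- dm$y - X %*% b
  u <- lapply(names(dm$Z), function(term) {
    Zk <- dm$Z[[term]]; Gk <- dm$G[[term]]
    GZt <- if (is.null(Gk)) t(Zk) else Gk %*% t(Zk)
    drop(sigma2[[term]] * GZt %*% Vi %*% res)
  })
  names(u) <- names(dm$Z)
  list(b = b, u = u)
}

# Balanced one-way random-effects data plus its ANOVA method-of-moments
# variance estimates.
balanced_oneway <- function(g, r, s2g, s2e) {
  gid <- rep(sprintf("g%03d", seq_len(g)), each = r)
  y <- rep(stats::rnorm(g, 0, sqrt(s2g)), each = r) +
    stats::rnorm(g * r, 0, sqrt(s2e))
  gm <- tapply(y, gid, mean)
  msb <- r * stats::var(gm)
  msw <- sum((y - rep(gm, each = r))^2) / (g * r - g)
  list(data = tibble::tibble(gid = gid, y = y),
       mom = c(s2g = (msb - msw) / r, s2e = msw))
}

# Balanced single-season RCBD phenotype slice in the pipeline's column
# layout.
rcbd_slice <- function(g = 15, r = 3, s2g = 40000, s2e = 90000, s2r = 5000,
                       mu = 2500, year = 2001, season = "DS",
                       beta_dtf = 0, dtf_mean = 90) {
  d <- tidyr::expand_grid(genotype = sprintf("g%03d", seq_len(g)),
                          rep = as.character(seq_len(r)))
  d$year <- year; d$season <- season; d$location <- "L1"
  d$design <- "rcbd"; d$block <- d$rep
  d$row <- NA_character_; d$col <- NA_character_
  d$dtf <- as.integer(round(stats::rnorm(nrow(d), dtf_mean, 5)))
  gv <- stats::rnorm(g, 0, sqrt(s2g))
  rv <- stats::rnorm(r, 0, sqrt(s2r))
  d$yield_kg_ha <- mu + gv[match(d$genotype, sprintf("g%03d", seq_len(g)))] +
    rv[as.integer(d$rep)] + beta_dtf * (d$dtf - dtf_mean) +
    stats::rnorm(nrow(d), 0, sqrt(s2e))
  d$plot_id <- sprintf("P%05d", seq_len(nrow(d)))
  d
}

# tiny default simulation shared by several tests (kept small for speed)
tiny_sim_config <- function(seed = 7, ...) {
  sim_config(n_founders = 12, n_years_crossing = 4, crosses_per_year = 8,
             n_trial_years = 4, entries_per_trial = 24, seed = seed, ...)
}
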