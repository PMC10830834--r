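#' Specify a linear mixed model
#'
#' Describes a weighted linear mixed model
#' `y = X b + sum_k Z_k u_k + e`, with `u_k ~ N(0, sigma2_k G_k)` where
#' `G_k` is either the identity (`"iid"`) or a supplied covariance matrix
#' (e.g. a pedigree A-matrix), and `e ~ N(0, sigma2_e W^-1)` for known
#' observation weights `W` (precisions relative to `sigma2_e`).
#'
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect columns. Character/factor
#'   columns enter as treatment-coded factors (first observed level as
#'   reference); numeric columns as covariates. An intercept is always
#'   included.
#' @param random Named list of random terms; each element is either `"iid"`
#'   or a symmetric covariance matrix whose dimnames index the term's
#'   levels.
#' @param weights Optional name of a column of strictly positive
#'   observation weights (inverse squared standard errors in the two-stage
#'   pipeline).
#' @return A `model_spec` object.
#' @export
model_spec <- function(response, fixed = character(), random = list(),
                       weights = NULL) {
  if (length(random) > 0 && is.null(names(random))) {
    abort("`random` must be a named list keyed by column name")
  }
  both <- intersect(fixed, names(random))
  if (length(both) > 0) {
    abort(sprintf("term(s) both fixed and random: %s",
                  paste(both, collapse = ", ")))
  }
  structure(list(response = response, fixed = fixed, random = random,
                 weights = weights),
            class = "model_spec")
}

#' Build design matrices for a mixed model
#'
#' Constructs the full-rank fixed design matrix (treatment coding, aliased
#' columns dropped in pivot order) and one incidence block per random term.
#' Rows with a missing response, missing fixed covariate or missing fixed
#' factor level are dropped and logged; a missing level of a *random*
#' factor yields a zero incidence row (the term simply does not apply to
#' that plot, as for blocking factors of other designs).
#'
#' @param table A data frame.
#' @param spec A [model_spec()].
#' @return A list with elements `y`, `X`, `Z` (list of incidence matrices),
#'   `G` (covariance or `NULL` per term), `w` (weights), `kept` (row
#'   indices used), and a `log` of drops.
#' @export
build_design <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  assert_columns(table, c(spec$response, spec$fixed, names(spec$random),
                          spec$weights), "model frame")
  df <- as.data.frame(table)
  log <- character()

  y <- df[[spec$response]]
  keep <- !is.na(y)

  fixed <- spec$fixed
  is_factor_col <- function(col) is.character(df[[col]]) || is.factor(df[[col]])
  for (col in fixed) keep <- keep & !is.na(df[[col]])
  if (!is.null(spec$weights)) keep <- keep & !is.na(df[[spec$weights]])
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    log <- c(log, sprintf("dropped %d row(s) with missing response/fixed/weight", n_drop))
  }
  df <- df[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n == 0) abort("no usable rows after drops", class = "breedgain_model_error")

  # covariates constant after drops are removed (not estimable with intercept)
  for (col in fixed) {
    if (!is_factor_col(col) && length(unique(df[[col]])) == 1L) {
      warn(sprintf("covariate '%s' is constant after row drops; term removed", col))
      fixed <- setdiff(fixed, col)
      log <- c(log, sprintf("removed constant covariate '%s'", col))
    }
  }
  # single-level fixed factors carry no contrast
  for (col in fixed) {
    if (is_factor_col(col) && length(unique(df[[col]])) == 1L) {
      fixed <- setdiff(fixed, col)
      log <- c(log, sprintf("removed single-level fixed factor '%s'", col))
    }
  }

  for (col in fixed) {
    if (is_factor_col(col)) {
      df[[col]] <- factor(as.character(df[[col]]),
                          levels = unique(as.character(df[[col]])))
    }
  }
  X <- if (length(fixed) == 0) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    model.matrix(stats::reformulate(fixed, intercept = TRUE), data = df)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    log <- c(log, sprintf("dropped aliased fixed column(s): %s",
                          paste(dropped, collapse = ", ")))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }

  Z <- list()
  G <- list()
  for (term in names(spec$random)) {
    cov <- spec$random[[term]]
    lev_obs <- unique(as.character(df[[term]]))
    lev_obs <- lev_obs[!is.na(lev_obs)]
    if (is.matrix(cov)) {
      levels <- rownames(cov)
      missing <- setdiff(lev_obs, levels)
      if (length(missing) > 0) {
        abort(sprintf(
          "covariance matrix for '%s' is missing level(s): %s",
          term, paste(head(missing, 10), collapse = ", ")
        ), class = "breedgain_model_error")
      }
    } else {
      levels <- lev_obs
      cov <- NULL
    }
    if (length(levels) < 2) {
      log <- c(log, sprintf("random term '%s' has < 2 levels; removed", term))
      next
    }
    zi <- matrix(0, n, length(levels), dimnames = list(NULL, levels))
    obs <- as.character(df[[term]])
    ok <- !is.na(obs)
    zi[cbind(which(ok), match(obs[ok], levels))] <- 1
    Z[[term]] <- zi
    G[[term]] <- cov
  }

  w <- if (is.null(spec$weights)) rep(1, n) else df[[spec$weights]]
  if (any(w <= 0)) abort("weights must be strictly positive",
                         class = "breedgain_model_error")
  list(y = y, X = X, Z = Z, G = G, w = w, kept = which(keep),
       data = as_tibble(df), log = log)
}

# Precompute per-term covariance inverses and log-determinants (unscaled
# structures G0_k); an A-matrix that is numerically semi-definite gets a
# 1e-8 diagonal jitter, logged.
prep_gstruct <- function(dm) {
  out <- list()
  for (term in names(dm$Z)) {
    cov <- dm$G[[term]]
    q <- ncol(dm$Z[[term]])
    if (is.null(cov)) {
      out[[term]] <- list(q = q, ginv = NULL, logdet = 0, jitter = FALSE)
    } else {
      ch <- tryCatch(chol(cov), error = function(e) NULL)
      jitter <- FALSE
      if (is.null(ch)) {
        ch <- chol(cov + diag(1e-8 * mean(diag(cov)), nrow(cov)))
        jitter <- TRUE
      }
      out[[term]] <- list(q = q, ginv = chol2inv(ch),
                          logdet = 2 * sum(log(diag(ch))), jitter = jitter)
    }
  }
  out
}

# One-off cross-products for a design: everything in the likelihood that
# does not depend on the variance components.
prep_crossprods <- function(dm) {
  M <- do.call(cbind, c(list(dm$X), unname(dm$Z)))
  w <- dm$w
  list(MtWM = crossprod(M * sqrt(w)), MtWy = drop(crossprod(M, w * dm$y)),
       yWy = sum(dm$y^2 * w), logsumw = sum(log(w)),
       n = length(dm$y), p = ncol(dm$X))
}

# Assemble and factor Henderson's MME for given variance components.
# Returns solution, inverse coefficient matrix pieces and the REML
# log-likelihood. sigma2: named c(<terms>, residual = ...).
mme_engine <- function(dm, gs, sigma2, want_inverse = TRUE, cp = NULL) {
  if (is.null(cp)) cp <- prep_crossprods(dm)
  n <- cp$n; p <- cp$p
  s2e <- sigma2[["residual"]]
  terms <- names(dm$Z)
  C <- cp$MtWM / s2e
  rhs <- cp$MtWy / s2e
  off <- p
  idx <- list()
  logdetG <- 0
  for (term in terms) {
    q <- gs[[term]]$q
    id <- off + seq_len(q)
    idx[[term]] <- id
    s2k <- sigma2[[term]]
    if (is.null(gs[[term]]$ginv)) {
      C[cbind(id, id)] <- C[cbind(id, id)] + 1 / s2k
    } else {
      C[id, id] <- C[id, id] + gs[[term]]$ginv / s2k
    }
    logdetG <- logdetG + q * log(s2k) + gs[[term]]$logdet
    off <- off + q
  }
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    abort("mixed-model equations are singular (rank-deficient fixed block); check for confounded terms",
          class = "breedgain_model_error")
  }
  sol <- backsolve(ch, forwardsolve(t(ch), rhs))
  yPy <- cp$yWy / s2e - sum(sol * rhs)
  logdetC <- 2 * sum(log(diag(ch)))
  logdetR <- n * log(s2e) - cp$logsumw
  reml <- -0.5 * (logdetR + logdetG + logdetC + yPy + (n - p) * log(2 * pi))
  out <- list(sol = sol, idx = idx, p = p, yPy = yPy, reml = reml, chol = ch)
  if (want_inverse) out$Cinv <- chol2inv(ch)
  out
}

#' Estimate variance components by REML
#'
#' Maximizes the restricted log-likelihood over the per-term and residual
#' variances, evaluated through the factorization of Henderson's
#' mixed-model-equation coefficient matrix. A bounded quasi-Newton search on
#' the log-variances is followed by EM-REML polishing iterations, whose
#' fixed point is the exact REML stationary point; components that reach the
#' floor (1e-8 times the response variance) are clamped and flagged. The
#' result is deterministic given the inputs.
#'
#' @param dm Design matrices from [build_design()].
#' @param max_iter Maximum EM polishing iterations.
#' @param tol Relative-change convergence tolerance for the EM polish.
#' @param optim_maxit,factr Quasi-Newton iteration cap and `optim`
#'   L-BFGS-B `factr`; the defaults give high-precision optima, looser
#'   values suit fits whose exact components are incidental (e.g. the
#'   outlier screen's working models).
#' @return A `variance_components` list: `sigma2` (named vector including
#'   `residual`), `reml_loglik`, `convergence`, `n_iterations`,
#'   `boundary` flags.
#' @export
reml_fit <- function(dm, max_iter = 300, tol = 1e-9,
                     optim_maxit = 200, factr = 1e4) {
  y <- dm$y
  n <- length(y); p <- ncol(dm$X)
  if (n - p < 1) abort("no residual degrees of freedom",
                       class = "breedgain_model_error")
  gs <- prep_gstruct(dm)
  cp <- prep_crossprods(dm)
  terms <- names(dm$Z)
  K <- length(terms)
  vy <- var(y) * sum(dm$w) / length(dm$w)  # rough scale in residual units
  if (!is.finite(vy) || vy <= 0) vy <- max(abs(y), 1)
  floor_v <- 1e-8 * vy

  # deterministic method-of-moments-flavoured start: split the WLS residual
  # variance equally over the residual and the random terms
  fitw <- stats::lm.wfit(dm$X, y, dm$w)
  v0 <- sum(dm$w * fitw$residuals^2) / max(n - p, 1)
  if (v0 <= floor_v) v0 <- max(vy, floor_v * 10)

  if (K == 0) {
    s2 <- c(residual = max(v0, floor_v))
    eng <- mme_engine(dm, gs, s2, want_inverse = FALSE, cp = cp)
    return(structure(list(sigma2 = s2, reml_loglik = eng$reml,
                          convergence = TRUE, n_iterations = 0,
                          boundary = c(residual = v0 <= floor_v)),
                     class = "variance_components"))
  }

  start <- c(rep(v0 / 2, K) / K, v0 / 2)
  names(start) <- c(terms, "residual")
  nll <- function(logs2) {
    s2 <- setNames(exp(logs2), c(terms, "residual"))
    eng <- tryCatch(mme_engine(dm, gs, s2, want_inverse = FALSE, cp = cp),
                    error = function(e) NULL)
    if (is.null(eng) || !is.finite(eng$reml)) return(1e10)
    -eng$reml
  }
  opt <- stats::optim(log(start), nll, method = "L-BFGS-B",
                      lower = log(floor_v), upper = log(vy * 1e6),
                      control = list(maxit = optim_maxit, factr = factr))
  s2 <- setNames(exp(opt$par), c(terms, "residual"))

  # EM-REML polish: sigma2_k <- (u'G0inv u + tr(G0inv C^kk)) / q_k;
  # sigma2_e <- sigma2_e * y'Py / (n - p). Fixed point = REML optimum.
  iter <- 0
  converged <- FALSE
  repeat {
    iter <- iter + 1
    eng <- mme_engine(dm, gs, s2, want_inverse = TRUE, cp = cp)
    new <- s2
    for (term in terms) {
      id <- eng$idx[[term]]
      u <- eng$sol[id]
      gk <- gs[[term]]
      if (is.null(gk$ginv)) {
        val <- (sum(u^2) + sum(diag(eng$Cinv)[id])) / gk$q
      } else {
        val <- (drop(t(u) %*% gk$ginv %*% u) +
                  sum(gk$ginv * eng$Cinv[id, id])) / gk$q
      }
      new[[term]] <- max(val, floor_v)
    }
    new[["residual"]] <- max(s2[["residual"]] * eng$yPy / (n - p), floor_v)
    delta <- max(abs(new - s2) / pmax(s2, floor_v))
    s2 <- new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  eng <- mme_engine(dm, gs, s2, want_inverse = FALSE, cp = cp)
  structure(list(sigma2 = s2, reml_loglik = eng$reml,
                 convergence = converged || opt$convergence == 0,
                 n_iterations = iter,
                 boundary = s2 <= floor_v * (1 + 1e-12)),
            class = "variance_components")
}

#' Solve Henderson's mixed-model equations
#'
#' Given variance components, assembles and solves the MME with `R^-1`
#' weights and `G^-1 = blockdiag(sigma2_k^-1 G0_k^-1)`. Fixed-effect
#' standard errors and random-level prediction error variances (PEV) come
#' from the corresponding diagonal blocks of the inverse coefficient
#' matrix; the full PEV block per random term is retained for
#' pairwise-difference (Cullis) computations.
#'
#' @param dm Design matrices from [build_design()].
#' @param vc A `variance_components` object (or a named sigma2 vector
#'   including `residual`).
#' @return An `mme_fit` object: `fixed` tibble (term, estimate, se),
#'   `random` list of tibbles (level, blup, pev), `pev_block` list of full
#'   PEV matrices, `vc`, `reml_loglik`, `fitted`.
#' @export
solve_mme <- function(dm, vc) {
  sigma2 <- if (inherits(vc, "variance_components")) vc$sigma2 else vc
  gs <- prep_gstruct(dm)
  eng <- mme_engine(dm, gs, sigma2, want_inverse = TRUE)
  p <- eng$p
  fixed <- tibble(term = colnames(dm$X),
                  estimate = eng$sol[seq_len(p)],
                  se = sqrt(pmax(diag(eng$Cinv)[seq_len(p)], 0)))
  random <- list()
  pev_block <- list()
  for (term in names(eng$idx)) {
    id <- eng$idx[[term]]
    pb <- eng$Cinv[id, id, drop = FALSE]
    random[[term]] <- tibble(level = colnames(dm$Z[[term]]),
                             blup = eng$sol[id],
                             pev = pmax(diag(pb), 0))
    pev_block[[term]] <- pb
  }
  M <- do.call(cbind, c(list(dm$X), unname(dm$Z)))
  structure(list(fixed = fixed, random = random, pev_block = pev_block,
                 vc = if (inherits(vc, "variance_components")) vc else
                   structure(list(sigma2 = sigma2, convergence = NA),
                             class = "variance_components"),
                 fixed_cov = eng$Cinv[seq_len(p), seq_len(p), drop = FALSE],
                 reml_loglik = eng$reml,
                 fitted = drop(M %*% eng$sol)),
            class = "mme_fit")
}

# Mean variance of a pairwise difference between the BLUPs of one random
# term: vbar = 2 (q tr(P) - sum(P)) / (q (q - 1)) with P the term's full
# PEV block.
vbar_blup <- function(fit, term) {
  P <- fit$pev_block[[term]]
  if (is.null(P)) abort(sprintf("no PEV block for term '%s'", term))
  q <- nrow(P)
  if (q < 2) abort("need at least 2 levels for a pairwise difference")
  2 * (q * sum(diag(P)) - sum(P)) / (q * (q - 1))
}
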