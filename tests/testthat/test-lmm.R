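test_that("design construction codes factors and incidence as specified", {
  df <- tibble::tibble(y = rnorm(12),
                       f = rep(letters[1:4], 3),
                       x = rnorm(12))
  dm0 <- build_design(df, model_spec("y"))
  expect_equal(unname(dm0$X), matrix(1, 12, 1))           # intercept only

  dm1 <- build_design(df, model_spec("y", fixed = "f"))
  expect_equal(ncol(dm1$X), 4)                            # 1 + (k-1)

  # alpha-lattice style: rep + block nested in rep, 3 reps x 4 blocks
  al <- tidyr::expand_grid(rep = as.character(1:3), block = as.character(1:4),
                           plot = 1:2)
  al$blk <- paste(al$rep, al$block)
  al$y <- rnorm(nrow(al))
  dm2 <- build_design(al, model_spec("y", random = list(rep = "iid",
                                                        blk = "iid")))
  expect_equal(dim(dm2$Z$rep), c(24, 3))
  expect_equal(dim(dm2$Z$blk), c(24, 12))
  expect_true(all(rowSums(dm2$Z$rep) == 1))
  expect_true(all(rowSums(dm2$Z$blk) == 1))
  # each block incidence column has exactly its 2 plots
  expect_true(all(colSums(dm2$Z$blk) == 2))

  # missing random level = zero incidence row, not a dropped record
  al$blk[1] <- NA
  dm3 <- build_design(al, model_spec("y", random = list(blk = "iid")))
  expect_equal(nrow(dm3$data), 24)
  expect_equal(sum(dm3$Z$blk[1, ]), 0)

  # constant covariate removed with a warning
  df$cx <- 1
  expect_warning(build_design(df, model_spec("y", fixed = "cx")), "constant")
})

test_that("MME with no random terms reduces to weighted least squares", {
  set.seed(101)
  df <- tibble::tibble(y = rnorm(40, 10), x = rnorm(40),
                       f = sample(letters[1:3], 40, TRUE),
                       w = runif(40, 0.5, 2))
  dm <- build_design(df, model_spec("y", fixed = c("f", "x"), weights = "w"))
  fit <- solve_mme(dm, c(residual = 2.3))
  X <- dm$X
  b <- solve(crossprod(X * sqrt(dm$w)), crossprod(X, dm$w * dm$y))
  expect_lt(max(abs(fit$fixed$estimate - b)), 1e-10)
})

test_that("balanced one-way BLUP equals the shrunken group mean", {
  set.seed(102)
  g <- 8; r <- 4; s2g <- 5; s2e <- 3
  d <- tibble::tibble(gid = rep(letters[1:g], each = r))
  d$y <- rep(rnorm(g, 0, sqrt(s2g)), each = r) + rnorm(g * r, 0, sqrt(s2e))
  dm <- build_design(d, model_spec("y", random = list(gid = "iid")))
  fit <- solve_mme(dm, c(gid = s2g, residual = s2e))
  lam <- s2e / s2g
  gm <- tapply(d$y, d$gid, mean)
  shrunk <- (gm - mean(d$y)) * r / (r + lam)
  expect_equal(fit$random$gid$blup,
               as.numeric(shrunk[fit$random$gid$level]),
               tolerance = 1e-10)
})

test_that("MME solutions equal the dense GLS/conditional-expectation oracle", {
  set.seed(103)
  for (case in 1:10) {
    n <- sample(20:50, 1)
    df <- tibble::tibble(
      y = rnorm(n), x = rnorm(n),
      f1 = sample(letters[1:5], n, TRUE),
      f2 = sample(LETTERS[1:4], n, TRUE),
      w = runif(n, 0.5, 2)
    )
    # pedigree covariance on f1 in half the cases
    use_ped <- case %% 2 == 0
    G1 <- if (use_ped) {
      ped <- tibble::tibble(genotype = letters[1:5],
                            parent_f = c("0", "0", "a", "a", "c"),
                            parent_m = c("0", "0", "b", "b", "b"))
      unclass(build_a_matrix(ped))
    } else "iid"
    dm <- build_design(df, model_spec("y", fixed = "x",
                                      random = list(f1 = G1, f2 = "iid"),
                                      weights = "w"))
    s2 <- c(f1 = runif(1, 0.3, 2), f2 = runif(1, 0.3, 2),
            residual = runif(1, 0.5, 2))
    fit <- solve_mme(dm, s2)
    or <- gls_oracle(dm, s2)
    expect_lt(max(abs(fit$fixed$estimate - or$b)), 1e-8)
    for (term in names(or$u)) {
      u_or <- or$u[[term]][fit$random[[term]]$level]
      expect_lt(max(abs(fit$random[[term]]$blup - u_or)), 1e-8)
    }
  }
})

test_that("REML equals ANOVA method-of-moments on balanced one-way data", {
  set.seed(104)
  for (case in 1:5) {
    g <- sample(8:20, 1); r <- sample(3:6, 1)
    ow <- balanced_oneway(g, r, s2g = runif(1, 2, 20), s2e = runif(1, 1, 10))
    if (ow$mom[["s2g"]] <= 0) next  # boundary case: REML clamps instead
    dm <- build_design(ow$data, model_spec("y", random = list(gid = "iid")))
    vc <- reml_fit(dm)
    expect_lt(abs(vc$sigma2[["gid"]] - ow$mom[["s2g"]]) / ow$mom[["s2g"]], 1e-6)
    expect_lt(abs(vc$sigma2[["residual"]] - ow$mom[["s2e"]]) / ow$mom[["s2e"]], 1e-6)
    expect_true(vc$convergence)
  }
})

test_that("REML recovers simulated variance components on average", {
  set.seed(105)
  s2g <- 40000; s2e <- 90000
  est <- t(vapply(1:40, function(i) {
    ow <- balanced_oneway(g = 100, r = 5, s2g = s2g, s2e = s2e)
    dm <- build_design(ow$data, model_spec("y", random = list(gid = "iid")))
    vc <- reml_fit(dm)
    c(vc$sigma2[["gid"]], vc$sigma2[["residual"]])
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - s2g) / s2g, 0.05)
  expect_lt(abs(mean(est[, 2]) - s2e) / s2e, 0.05)
})

test_that("zero within-group variance drives the residual to its floor", {
  d <- tibble::tibble(gid = rep(letters[1:6], each = 3))
  d$y <- rep(c(1, 5, 9, 2, 7, 4), each = 3)
  dm <- build_design(d, model_spec("y", random = list(gid = "iid")))
  vc <- reml_fit(dm)
  expect_true(vc$boundary[["residual"]])
  expect_lt(vc$sigma2[["residual"]], 1e-6 * var(d$y))
})

test_that("PEV never exceeds the prior variance and flows through A", {
  set.seed(106)
  ped <- tibble::tibble(
    genotype = c("p1", "p2", "k1", "k2", "ghost"),
    parent_f = c("0", "0", "p1", "p1", "p1"),
    parent_m = c("0", "0", "p2", "p2", "p2")
  )
  A <- unclass(build_a_matrix(ped))
  df <- tibble::tibble(gid = rep(c("p1", "p2", "k1", "k2"), each = 4))
  df$y <- rnorm(16, 5)
  s2 <- c(gid = 2, residual = 1)
  dm <- build_design(df, model_spec("y", random = list(gid = A)))
  fit <- solve_mme(dm, s2)
  g <- fit$random$gid
  prior <- s2[["gid"]] * diag(A)[g$level]
  expect_true(all(g$pev <= prior + 1e-8))
  ghost <- g[g$level == "ghost", ]
  expect_true(is.finite(ghost$blup))
  expect_lt(ghost$pev, s2[["gid"]] * A["ghost", "ghost"])  # informed by kin
})

test_that("scale equivariance and coding invariance hold", {
  set.seed(107)
  df <- tibble::tibble(y = rnorm(30, 3),
                       f = sample(letters[1:5], 30, TRUE),
                       g = sample(LETTERS[1:6], 30, TRUE),
                       w = runif(30, 0.5, 2))
  spec <- model_spec("y", fixed = "f", random = list(g = "iid"),
                     weights = "w")
  dm <- build_design(df, spec)
  f1 <- solve_mme(dm, c(g = 1.5, residual = 2))
  # rescaling weights and sigma2_e together leaves R, hence predictions,
  # unchanged
  df2 <- dplyr::mutate(df, w = 2 * w)
  dm2 <- build_design(df2, spec)
  f2 <- solve_mme(dm2, c(g = 1.5, residual = 4))
  expect_equal(f2$fixed$estimate, f1$fixed$estimate, tolerance = 1e-10)
  expect_equal(f2$random$g$blup, f1$random$g$blup, tolerance = 1e-10)

  # REML log-likelihood invariant to the fixed-factor level order
  df3 <- df[order(df$f, decreasing = TRUE), ]
  dm3 <- build_design(df3, spec)
  vc1 <- reml_fit(dm)
  vc3 <- reml_fit(dm3)
  expect_equal(vc1$reml_loglik, vc3$reml_loglik, tolerance = 1e-6)
})

test_that("REML matches lme4 on an expressible random-intercept model", {
  skip_if_not_installed("lme4")
  set.seed(108)
  d <- tibble::tibble(g = rep(sprintf("g%02d", 1:15), each = 4),
                      x = rnorm(60))
  d$y <- 2 + 0.5 * d$x + rep(rnorm(15, 0, 1.4), each = 4) + rnorm(60, 0, 0.8)
  dm <- build_design(d, model_spec("y", fixed = "x",
                                   random = list(g = "iid")))
  vc <- reml_fit(dm)
  lfit <- lme4::lmer(y ~ x + (1 | g), data = d, REML = TRUE)
  lvc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(vc$sigma2[["g"]], lvc$vcov[lvc$grp == "g"], tolerance = 1e-4)
  expect_equal(vc$sigma2[["residual"]], lvc$vcov[lvc$grp == "Residual"],
               tolerance = 1e-4)
  fit <- solve_mme(dm, vc)
  expect_equal(fit$fixed$estimate, unname(lme4::fixef(lfit)),
               tolerance = 1e-4)
})
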