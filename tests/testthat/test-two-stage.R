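test_that("balanced RCBD stage-1 BLUEs equal raw genotype means", {
  set.seed(71)
  d <- rcbd_slice(g = 12, r = 3, s2r = 0, beta_dtf = 0)
  s1 <- stage1_by_year(d, use_dtf_covariate = FALSE)
  raw <- tapply(d$yield_kg_ha, d$genotype, mean)
  b <- s1$blues
  expect_lt(max(abs(b$blue - raw[b$genotype])), 1e-6)
  expect_lt(diff(range(b$se)), 1e-8)                 # all SEs equal
  expect_equal(b$weight, 1 / b$se^2)                 # definitional identity
})

test_that("the DTF covariate estimate recovers the simulated slope", {
  set.seed(72)
  beta <- -30
  d <- rcbd_slice(g = 60, r = 3, beta_dtf = beta, s2e = 40000)
  df <- add_blocking_columns(d)
  spec <- model_spec("yield_kg_ha", fixed = c("genotype", "dtf"),
                     random = list(.rep = "iid"))
  dm <- build_design(df, spec)
  vc <- reml_fit(dm)
  fit <- solve_mme(dm, vc)
  est <- fit$fixed[fit$fixed$term == "dtf", ]
  expect_lt(abs(est$estimate - beta), 2 * est$se)
})

test_that("Cullis heritability reduces to the entry-mean form when balanced", {
  set.seed(73)
  for (pars in list(c(40000, 90000, 3), c(10000, 120000, 2),
                    c(80000, 40000, 4))) {
    d <- rcbd_slice(g = 15, r = pars[3], s2g = pars[1], s2e = pars[2])
    h <- cullis_h2(d, use_dtf_covariate = FALSE,
                   vc = c(genotype = pars[1], .rep = 5000,
                          residual = pars[2]))
    expect_equal(h$h2, pars[1] / (pars[1] + pars[2] / pars[3]),
                 tolerance = 1e-6)
  }
})

test_that("Cullis heritability approaches 1 as error vanishes", {
  set.seed(74)
  d <- rcbd_slice(g = 15, r = 2, s2g = 40000, s2e = 1e-6, s2r = 0)
  h <- cullis_h2(d, use_dtf_covariate = FALSE)
  expect_gt(h$h2, 1 - 1e-3)
})

test_that("no genetic signal drives heritability to zero with a flag", {
  set.seed(75)
  d <- rcbd_slice(g = 80, r = 3, s2g = 0, s2e = 50000, s2r = 0)
  h <- cullis_h2(d, use_dtf_covariate = FALSE)
  expect_lt(h$h2, 0.3)  # null sigma2_g: estimate is sampling noise only
  # forcing the boundary reports exactly zero with the flag
  d0 <- rcbd_slice(g = 12, r = 3, s2g = 0, s2e = 1, s2r = 0)
  d0$yield_kg_ha <- rep(tapply(d0$yield_kg_ha, d0$rep, mean)[d0$rep])
  h0 <- cullis_h2(d0, use_dtf_covariate = FALSE)
  expect_true(h0$boundary)
  expect_equal(h0$h2, 0)
})

test_that("stage-2 reliability follows the PEV identity and clamps", {
  # arithmetic of r = 1 - PEV / sigma2_g on a synthetic stage-2 output
  s2g <- 100
  pev <- c(0, 60, 100, 140)
  r <- pmin(1, pmax(0, 1 - pev / s2g))
  expect_equal(r, c(1, 0.4, 0, 0))
})

test_that("stage 2 is shift-equivariant and rewards repeated testing", {
  set.seed(76)
  sim <- simulate_program(tiny_sim_config(seed = 23))
  qc <- run_qc(sim$phenotypes)
  s1 <- stage1_by_year(qc$data)
  a <- build_a_matrix(sim$pedigree)
  s2 <- stage2_blup(s1, a)

  # adding a constant to all BLUEs shifts values, not deviations or PEVs
  s1b <- s1
  s1b$blues$blue <- s1$blues$blue + 500
  s2b <- stage2_blup(s1b, a)
  expect_equal(s2b$values$pev, s2$values$pev, tolerance = 1e-6)
  dev_a <- s2$values$breeding_value - mean(s2$values$breeding_value)
  dev_b <- s2b$values$breeding_value - mean(s2b$values$breeding_value)
  expect_equal(dev_b, dev_a, tolerance = 1e-4)

  # checks observed every year are at least as reliable as any
  # once-observed genotype
  v <- s2$values
  checks <- v[v$n_years == max(v$n_years), ]
  once <- v[v$n_years == 1, ]
  expect_gte(min(checks$reliability), max(once$reliability) - 1e-5)

  # every genotype with a stage-1 BLUE has a breeding value
  expect_true(all(unique(s1$blues$genotype) %in% v$genotype))
})

test_that("a pedigree lowers normalized PEV for sparsely tested genotypes", {
  set.seed(77)
  sim <- simulate_program(tiny_sim_config(seed = 29))
  qc <- run_qc(sim$phenotypes)
  s1 <- stage1_by_year(qc$data)
  a <- build_a_matrix(sim$pedigree)
  # same fixed components for both structures so only the covariance of
  # the genotype term differs
  s2g <- 40000; s2e <- 1
  blues <- dplyr::mutate(s1$blues, year = as.character(year))
  fit_with <- function(G) {
    dm <- build_design(blues, model_spec("blue", fixed = "year",
                                         random = list(genotype = G),
                                         weights = "weight"))
    solve_mme(dm, c(genotype = s2g, residual = s2e))
  }
  f_ped <- fit_with(unclass(a))
  f_iid <- fit_with("iid")
  nrec <- table(blues$genotype)
  few <- names(nrec)[nrec == 1]
  gp <- f_ped$random$genotype
  gi <- f_iid$random$genotype
  prior <- s2g * diag(a)[gp$level]
  rel_ped <- 1 - gp$pev[gp$level %in% few] / prior[gp$level %in% few]
  rel_iid <- 1 - gi$pev[gi$level %in% few] / s2g
  # kin information raises the normalized accuracy of one-record genotypes
  expect_gt(mean(rel_ped), mean(rel_iid))
})

test_that("missing pedigree entries are reported by name", {
  set.seed(78)
  blues <- tibble::tibble(year = rep(2001:2002, each = 3),
                          genotype = rep(c("a", "b", "zz"), 2),
                          blue = rnorm(6, 2500, 100), se = 50)
  blues$weight <- 1 / blues$se^2
  ped <- tibble::tibble(genotype = c("a", "b"), parent_f = "0",
                        parent_m = "0")
  expect_error(stage2_blup(blues, build_a_matrix(ped)), "zz")
})

test_that("noise-free campaign recovers true values up to a constant shift", {
  # the residual variance clamps at its 1e-8 x var(y) floor here, so the
  # mixed-model equations are conditioned at ~1e8 and factorization
  # rounding of a few 1e-6 kg/ha is the attainable accuracy
  cfg <- tiny_sim_config(seed = 31, sigma2_e_range = c(0, 0), sigma2_env = 0,
                         sigma2_rep = 0, sigma2_block = 0, sigma2_row = 0,
                         sigma2_col = 0, beta_dtf = 0, missing_rate = 0,
                         outlier_rate = 0, mu_yield = 0)
  sim <- simulate_program(cfg)
  s1 <- stage1_by_year(sim$phenotypes, use_dtf_covariate = FALSE)
  a <- build_a_matrix(sim$pedigree)
  s2 <- stage2_blup(s1, a)
  v <- s2$values[s2$values$phenotyped, ]
  dev <- v$breeding_value - sim$truth$true_bv[v$genotype]
  expect_lt(max(abs(dev - mean(dev))), 1e-5)
})
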