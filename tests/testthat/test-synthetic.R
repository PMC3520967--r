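test_that("covariate generation is seed-deterministic with the requested correlation", {
  sc <- scenario_config(seed = 101L)
  a <- generate_covariates(sc)
  b <- generate_covariates(sc)
  expect_identical(a, b)
  expect_false(identical(a$abundance$x,
                         generate_covariates(sc, seed = 102L)$abundance$x))

  # independent covariates: loose bound on sample correlations at n = 245
  sc0 <- scenario_config(rho = 0, n_abund_cov = 6L,
                         beta = c(0.75, 0.5, 0, 0, 0, 0), seed = 55L)
  r0 <- cor(generate_covariates(sc0)$abundance$x)
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.15)

  # a strongly correlated pair lands near its target
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.8
  sc2 <- scenario_config(n_abund_cov = 3L, beta = c(0.5, 0, 0), rho = R,
                         seed = 56L)
  r2 <- cor(generate_covariates(sc2)$abundance$x)[1, 2]
  expect_gt(r2, 0.6); expect_lt(r2, 0.95)

  # non-positive-definite structure is refused
  Rbad <- matrix(0.99, 3, 3); Rbad[1, 2] <- Rbad[2, 1] <- -0.99; diag(Rbad) <- 1
  expect_error(generate_covariates(scenario_config(
    n_abund_cov = 3L, beta = rep(0, 3), rho = Rbad)), "positive definite")
})

test_that("detection intercepts are solved to hit the median-p target", {
  sc <- scenario_config(seed = 77L)
  cov <- generate_covariates(sc)
  for (m in sc$method_names) {
    a <- cov$alpha[[m]]
    eta <- a[[1]] + a[[2]] * cov$detection[[m]]$v$effort +
      a[[3]] * cov$detection[[m]]$v$time
    expect_equal(median(plogis(eta)), sc$det_p_target[[m]],
                 tolerance = 1e-8)
  }
})

test_that("latent population matches its generative law", {
  # no covariates: mean of N across sites near exp(beta0) = 3
  sc <- scenario_config(n_abund_cov = 0L, beta = numeric(0), beta0 = log(3),
                        seed = 9L)
  cov <- generate_covariates(sc)
  N <- simulate_population(sc, cov$abundance)
  expect_gt(mean(N), 2.4); expect_lt(mean(N), 3.6)

  # an extreme negative intercept empties the landscape
  sc0 <- scenario_config(n_abund_cov = 0L, beta = numeric(0), beta0 = -20,
                         seed = 9L)
  expect_true(all(simulate_population(sc0, cov$abundance) == 0L))

  # overflow guard
  schuge <- scenario_config(n_abund_cov = 0L, beta = numeric(0), beta0 = 30,
                            seed = 9L)
  expect_error(simulate_population(schuge, cov$abundance), "1e6")

  # zero mixing fraction reduces to the homogeneous path bitwise
  sc_h <- scenario_config(mixing_fraction = 0, seed = 12L)
  cov_h <- generate_covariates(sc_h)
  N1 <- simulate_population(sc_h, cov_h$abundance, seed = 40L)
  N2 <- simulate_population(sc_h, cov_h$abundance, seed = 40L)
  expect_identical(N1, N2)
  expect_true(all(attr(N1, "subgroups")[, "B"] == 0L))
})

test_that("counts respect conservation, calibration and the effort mask", {
  sc <- scenario_config(seed = 21L)
  cov <- generate_covariates(sc)
  N <- simulate_population(sc, cov$abundance)
  cd <- simulate_counts(sc, N, cov)

  # conservation: every observed count bounded by its site's abundance
  for (m in sc$method_names)
    expect_true(all(cd$counts[[m]] <= as.integer(N), na.rm = TRUE))

  # all-zero detection gives all-zero counts
  sc0 <- sc; sc0$susceptibility[] <- 0
  cd0 <- simulate_counts(sc0, N, cov)
  expect_true(all(cd0$counts[[1]] == 0L, na.rm = TRUE))

  # effort mask: configured fraction of sites, within one site
  frac_masked <- mean(rowSums(!is.na(cd$counts[[2]])) == 0L)
  expect_lt(abs(frac_masked * sc$n_sites -
                round(sc$missing_frac_m2 * sc$n_sites)), 1.5)

  # binomial calibration: total detections near their expectation over
  # ~2000 site-occasions per method
  for (m in sc$method_names) {
    a <- cov$alpha[[m]]
    p <- plogis(a[[1]] + a[[2]] * cov$detection[[m]]$v$effort +
                a[[3]] * cov$detection[[m]]$v$time)
    obs <- !is.na(cd$counts[[m]])
    mu <- sum((as.integer(N) * p)[obs])
    v <- sum((as.integer(N) * p * (1 - p))[obs])
    expect_lt(abs(sum(cd$counts[[m]][obs]) - mu), 3 * sqrt(v) + 1)
  }
})

test_that("subgroup susceptibility zeros are structural", {
  sc <- scenario_presets("heterogeneous_subpopulations", seed = 31L)
  cov <- generate_covariates(sc)
  N <- simulate_population(sc, cov$abundance)
  cd <- simulate_counts(sc, N, cov)
  # removing invisible subgroup B leaves method-1 counts unchanged (same seed)
  N_onlyA <- N
  attr(N_onlyA, "subgroups")[, "B"] <- 0L
  cd_A <- simulate_counts(sc, N_onlyA, cov)
  expect_identical(cd$counts$hair_trap, cd_A$counts$hair_trap)
  # method 2 sees subgroup B, so its counts must differ somewhere
  expect_false(identical(cd$counts$bear_rub, cd_A$counts$bear_rub))
})

test_that("presets are named, complete and round-trip through YAML", {
  expect_setequal(scenario_presets(),
                  c("shared_population", "heterogeneous_subpopulations"))
  expect_error(scenario_presets("nope"), "shared_population")
  sh <- scenario_presets("shared_population", seed = 3L)
  expect_equal(sh$missing_frac_m2, 0)
  expect_equal(sum(sh$beta != 0), 2L)
  het <- scenario_presets("heterogeneous_subpopulations", seed = 3L)
  expect_equal(unname(het$susceptibility["B", "hair_trap"]), 0)
  expect_gt(het$mixing_fraction, 0)

  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(het, path)
  back <- read_scenario_config(path)
  expect_equal(back, het, tolerance = 1e-12)

  # the full simulated dataset is reproducible from the round-tripped config
  s1 <- simulate_scenario(het)
  s2 <- simulate_scenario(back)
  expect_identical(s1$data$counts, s2$data$counts)
})
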