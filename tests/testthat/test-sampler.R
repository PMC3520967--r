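test_that("saved-draw bookkeeping follows (n_iter - burn_in) / thin", {
  expect_equal(n_saved(sampler_config()), 9000L)
  expect_equal(n_saved(sampler_config(n_iter = 110L, burn_in = 100L,
                                      thin = 10L)), 1L)
  cd <- toy_data()
  fit <- run_mcmc(cd, toy_design(), toy_det_designs(),
                  sampler_config(n_iter = 110L, burn_in = 100L, thin = 10L,
                                 n_chains = 2L, seed = 3L))
  expect_equal(vapply(fit$chains, nrow, 1L), c(1L, 1L))
  expect_error(sampler_config(n_iter = 100L, burn_in = 100L), "burn_in")
})

test_that("identical configurations give bitwise-identical draws", {
  cd <- toy_data()
  cfg <- sampler_config(n_iter = 600L, burn_in = 100L, thin = 5L,
                        n_chains = 2L, seed = 42L)
  f1 <- run_mcmc(cd, toy_design(), toy_det_designs(), cfg)
  f2 <- run_mcmc(cd, toy_design(), toy_det_designs(), cfg)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$N_chains, f2$N_chains)
  # a different seed moves the draws
  f3 <- run_mcmc(cd, toy_design(), toy_det_designs(),
                 sampler_config(n_iter = 600L, burn_in = 100L, thin = 5L,
                                n_chains = 2L, seed = 43L))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("latent draws never violate the observed-count lower bound", {
  cd <- toy_data()
  cfg <- sampler_config(n_iter = 3000L, burn_in = 500L, thin = 2L,
                        n_chains = 2L, seed = 9L, step_N = 5L)
  fit <- run_mcmc(cd, toy_design(), toy_det_designs(), cfg)
  lb <- max_observed(cd)
  Nd <- pooled_N(fit)
  for (i in seq_len(ncol(Nd)))
    expect_gte(min(Nd[, i]), lb[i])
})

test_that("near-certain detection concentrates the chain at N = y", {
  y <- matrix(3L, 1, 3)
  cd <- count_data(list(m1 = y, m2 = matrix(c(3L, NA, NA), 1, 3)))
  ad <- abundance_design(matrix(numeric(0), 1, 0))
  dd <- list(m1 = detection_design(1L, 3L), m2 = detection_design(1L, 3L))
  fit <- run_mcmc(cd, ad, dd,
                  sampler_config(n_iter = 4000L, burn_in = 1000L, thin = 2L,
                                 n_chains = 1L, seed = 5L),
                  sample_detection = FALSE,
                  init = list(alpha = list(m1 = 20, m2 = 20)))
  expect_gt(mean(pooled_N(fit) == 3L), 0.999)
})

test_that("with a flat likelihood every parameter type recovers its prior", {
  # covariate column identically zero -> beta_j's likelihood is flat;
  # method 2 fully masked -> its detection coefficients see no data
  set.seed(31)
  y1 <- matrix(rbinom(40, 4, 0.4), 20, 2)
  cd <- count_data(list(m1 = y1, m2 = matrix(NA_integer_, 20, 2)))
  X <- matrix(0, 20, 1, dimnames = list(NULL, "null"))
  ad <- abundance_design(X, standardize = FALSE)
  dd <- list(m1 = detection_design(20L, 2L),
             m2 = detection_design(20L, 2L,
                                   covariates = list(eff = rnorm(20))))
  cfg <- sampler_config(n_iter = 300000L, burn_in = 10000L, thin = 100L,
                        n_chains = 1L, seed = 77L, prior_sd_coef = 2)
  fit <- run_mcmc(cd, ad, dd, cfg)
  d <- pooled_draws(fit)
  # Kolmogorov-Smirnov against the Normal(0, prior sd) coefficient prior
  expect_gt(ks.test(d[, "b_null"], "pnorm", 0, 2)$p.value, 0.01)
  expect_gt(ks.test(d[, "a0_m2"], "pnorm", 0, 2)$p.value, 0.01)
  expect_gt(ks.test(d[, "a_m2_eff"], "pnorm", 0, 2)$p.value, 0.01)
  # indicator's full conditional is exactly the prior inclusion probability
  w <- d[, "w_null"]
  expect_lt(abs(mean(w) - 0.5), 3 * sqrt(0.25 / (length(w) / 2)))
})

test_that("coefficient acceptance rates land in the adapted band", {
  sim <- simulate_scenario(scenario_config(n_sites = 80L, n_abund_cov = 3L,
                                           beta = c(0.75, 0.5, 0),
                                           missing_frac_m2 = 0, seed = 2L))
  fit <- run_mcmc(sim$data, sim$abundance, sim$detection,
                  sampler_config(n_iter = 8000L, burn_in = 4000L, thin = 4L,
                                 n_chains = 1L, seed = 21L))
  acc <- fit$accept[[1L]]
  # intercept + the two well-identified slopes
  expect_true(all(acc$coef[1:3] >= 0.15 & acc$coef[1:3] <= 0.6))
  expect_true(all(acc$alpha >= 0.1 & acc$alpha <= 0.6))
  expect_true(acc$N > 0.1 && acc$N < 0.7)
})

test_that("duplicate covariates get exchangeable inclusion weights", {
  set.seed(8)
  z <- rnorm(40)
  X <- cbind(dup1 = z, dup2 = z)
  sc <- scenario_config(n_sites = 40L, n_abund_cov = 2L, beta = c(0.5, 0),
                        missing_frac_m2 = 0, seed = 14L)
  cov <- generate_covariates(sc)
  cov$abundance <- abundance_design(X)  # overwrite with the duplicated pair
  latent <- simulate_population(sc, cov$abundance)
  cd <- simulate_counts(sc, latent, cov)
  fit <- run_mcmc(cd, cov$abundance, cov$detection,
                  sampler_config(n_iter = 60000L, burn_in = 5000L, thin = 5L,
                                 n_chains = 3L, seed = 6L))
  wts <- variable_weights(fit)
  expect_lt(abs(wts[["dup1"]] - wts[["dup2"]]), 0.05)
})

test_that("single-kernel sweeps move only their own block of the state", {
  cd <- toy_data(); ad <- toy_design(); dd <- toy_det_designs()
  st <- list(beta0 = 0.2, beta = 0.1, w = 1L,
             alpha = list(m1 = 0.1, m2 = -0.2), N = c(2L, 2L, 3L))
  set.seed(1)
  s1 <- mcmc_sweep(cd, ad, dd, st, kernel = "latent", n_sweeps = 50L)
  expect_identical(s1$beta0, st$beta0)
  expect_identical(unname(s1$alpha$m1), 0.1)
  expect_true(all(s1$N >= max_observed(cd)))
  set.seed(1)
  s2 <- mcmc_sweep(cd, ad, dd, st, kernel = "coefficients", n_sweeps = 50L)
  expect_identical(s2$N, st$N)
  expect_false(identical(s2$beta0, st$beta0))
  set.seed(1)
  s3 <- mcmc_sweep(cd, ad, dd, st, kernel = "detection", n_sweeps = 50L)
  expect_identical(s3$beta0, st$beta0)
  expect_false(identical(s3$alpha, st$alpha))
})

test_that("non-finite initialization is reported with the offending site", {
  cd <- toy_data()
  X <- matrix(c(1, 2, 1e6), 3, 1, dimnames = list(NULL, "huge"))
  ad <- abundance_design(X, standardize = FALSE)
  expect_error(run_mcmc(cd, ad, toy_det_designs(),
                        sampler_config(n_iter = 20L, burn_in = 10L,
                                       thin = 1L, n_chains = 1L, seed = 1L),
                        init = list(beta0 = 0, beta = 1, w = 1L)),
               "non-finite expected abundance")
})
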