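mk_summary <- function(med, label = "x") {
  out <- data.frame(site = seq_along(med), median_N = as.integer(med),
                    relative_abundance = if (max(med) > 0) med / max(med)
                                         else rep(0, length(med)))
  class(out) <- c("abundance_summary", "data.frame")
  attr(out, "label") <- label
  out
}

test_that("prediction correlation is Pearson on the medians", {
  a <- mk_summary(c(1, 2, 3, 4))
  expect_equal(prediction_correlation(a, a), 1)
  expect_equal(prediction_correlation(a, mk_summary(c(2, 4, 6, 8))), 1)
  # direct formula evaluation: (1,2,3,4) vs (2,1,4,3)
  expect_equal(prediction_correlation(a, mk_summary(c(2, 1, 4, 3))), 0.6)
  expect_error(prediction_correlation(a, mk_summary(c(1, 2, 3))),
               "same sites")
  expect_error(prediction_correlation(a, mk_summary(c(2, 2, 2, 2))),
               "zero variance")
})

test_that("relative abundance scales to [0,1] with max exactly 1", {
  s <- mk_summary(c(0, 3, 12, 6))
  expect_equal(max(s$relative_abundance), 1)
  expect_equal(s$relative_abundance, c(0, 0.25, 1, 0.5))
  # invariance to a positive rescaling of the medians
  s2 <- mk_summary(c(0, 3, 12, 6) * 7)
  expect_equal(s$relative_abundance, s2$relative_abundance)
})

test_that("change classification follows the sign logic", {
  # combined equal to both singles: everything is no-change
  r <- classify_change(c(0.1, 0.5, 1), c(0.1, 0.5, 1), c(0.1, 0.5, 1))
  expect_true(all(r$category == "no_change"))
  # the worked sign example
  r1 <- classify_change(0.2, 0.8, 0.5)
  expect_equal(as.character(r1$category), "opposite_up_down")
  expect_equal(r1$d_add_method2, 0.3)
  expect_equal(r1$d_add_method1, -0.3)
  # antisymmetry under swapping the single-method inputs
  r2 <- classify_change(0.8, 0.2, 0.5)
  expect_equal(as.character(r2$category), "opposite_down_up")
  expect_error(classify_change(c(0.1, 0.2), 0.1, 0.1), "equal length")
})

test_that("classification counts match a brute-force sign table", {
  set.seed(33)
  m1 <- runif(200); m2 <- runif(200); cb <- runif(200)
  got <- table(classify_change(m1, m2, cb, tol = 1e-6)$category)
  d1 <- cb - m1; d2 <- cb - m2
  brute <- c(
    opposite_up_down = sum(d1 > 0 & d2 < 0),
    opposite_down_up = sum(d1 < 0 & d2 > 0),
    concordant = sum(!(d1 > 0 & d2 < 0) & !(d1 < 0 & d2 > 0) &
                     (abs(d1) >= 1e-6 | abs(d2) >= 1e-6)),
    no_change = sum(abs(d1) < 1e-6 & abs(d2) < 1e-6))
  expect_equal(as.vector(got[names(brute)]), unname(brute))
})

test_that("lower median of integer draws is integer and reproducible", {
  f <- multinmix:::.lower_median
  expect_equal(f(c(1L, 2L, 3L, 4L)), 2L)  # lower of the two middles
  expect_equal(f(c(5L, 1L, 3L)), 3L)
  expect_equal(f(7L), 7L)
})

test_that("masking a method reproduces the single-method fit exactly", {
  sim <- simulate_scenario(scenario_config(n_sites = 25L, n_abund_cov = 2L,
                                           beta = c(0.75, 0),
                                           missing_frac_m2 = 0, seed = 5L))
  cfg <- sampler_config(n_iter = 400L, burn_in = 100L, thin = 5L,
                        n_chains = 1L, seed = 17L)
  three <- fit_three_analyses(sim$data, sim$abundance, sim$detection, cfg)
  m2 <- sim$data$method_names[2L]
  direct <- run_mcmc(mask_method(sim$data, m2), sim$abundance,
                     sim$detection, cfg, select = TRUE)
  expect_identical(three$method1_only$selection$chains, direct$chains)
})

test_that("sites lacking effort in one method are dropped before analysis", {
  sim <- simulate_scenario(scenario_config(n_sites = 30L, n_abund_cov = 2L,
                                           beta = c(0.75, 0),
                                           missing_frac_m2 = 0.3, seed = 6L))
  cfg <- sampler_config(n_iter = 300L, burn_in = 100L, thin = 5L,
                        n_chains = 1L, seed = 18L)
  expect_message(
    three <- fit_three_analyses(sim$data, sim$abundance, sim$detection, cfg),
    "sampled with both methods")
  kept <- rowSums(!is.na(sim$data$counts[[2]])) > 0
  expect_equal(length(three$sites_kept), sum(kept))
  expect_equal(nrow(three$combined$summary), sum(kept))
})

test_that("an empty important set falls back to an intercept-only refit", {
  sim <- simulate_scenario(scenario_config(n_sites = 20L, n_abund_cov = 1L,
                                           beta = 0, missing_frac_m2 = 0,
                                           seed = 7L))
  cfg <- sampler_config(n_iter = 600L, burn_in = 100L, thin = 5L,
                        n_chains = 1L, seed = 19L)
  fit <- refit_reduced(sim$data, sim$abundance, sim$detection,
                       character(0), cfg)
  expect_false(any(grepl("^b_", fit$param_names)))
  expect_true("beta0" %in% fit$param_names)
  s <- abundance_summary(fit, "reduced")
  expect_equal(nrow(s), 20L)
})
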