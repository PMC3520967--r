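# multinmix

Hierarchical N-mixture abundance models for repeated count surveys that use
**two independent detection methods** — e.g. systematic baited hair traps
and opportunistically monitored bear rubs detecting grizzly bears on a
common grid. The package answers a design question wildlife biologists
face whenever several detection methods are available: *should the methods
be analyzed jointly (more data, more precision) or separately (robust to
each method sampling a different segment of the population)?*

## The model

Counts `y[i,t,m]` of individuals at site `i`, occasion `t`, method `m` are
modelled conditional on a latent local abundance:

```
N_i ~ Poisson(lambda_i)            log lambda_i = beta0 + sum_j w_j beta_j x_ij
y_itm | N_i ~ Binomial(N_i, p_itm) logit p_itm  = alpha0_m + sum_k alpha_mk v_mitk
```

with a separate detection component per method, masks for site-occasions
without sampling effort, and Kuo–Mallick indicator variables `w_j ~
Bernoulli(0.5)` giving Bayesian covariate selection: the *variable weight*
of covariate `j` is the fraction of posterior draws with `w_j = 1`
(important when ≥ 0.5), and *model weights* are the posterior frequencies
of exact covariate combinations. Inference is Metropolis-within-Gibbs MCMC
(compiled kernel) over latent abundances, coefficients and indicators,
with Brooks–Gelman–Rubin convergence checks (criterion BGR ≤ 1.01), a
default protocol of 3 chains × 190,000 iterations (burn-in 10,000, thin
20 → 9,000 saved draws per chain), and exact Gibbs/collapsed moves that
keep the weak-detection regime (per-occasion p ≈ 0.06–0.13) well mixed.

The comparison workflow fits each dataset three ways — method 1 only,
method 2 only, combined — then compares important-variable sets, model
weights, coefficient precision, prediction correlations and per-cell
opposite-direction changes in relative abundance. A synthetic-data module
generates surveys with the motivating study's structure (245 cells, 4 + 5
occasions, 15 correlated candidate covariates, low detection), including a
heterogeneous-subpopulations scenario in which each method misses a
different segment of the population.

## Worked example

```r
library(multinmix)

sim <- simulate_scenario(scenario_presets("shared_population", seed = 7))
cfg <- sampler_config(n_iter = 20000, burn_in = 5000, thin = 10,
                      n_chains = 2, seed = 11)
fit <- run_mcmc(sim$data, sim$abundance, sim$detection, cfg)
round(variable_weights(fit)[1:5], 3)
#> cov01 cov02 cov03 cov04 cov05
#> 1.000 1.000 0.018 0.020 0.046
model_weights(fit)[1:2, 1:3]
#>                model weight cumulative
#>         cov01, cov02  0.731      0.731
#>  cov01, cov02, cov15  0.057      0.788
important_variables(variable_weights(fit))
#> [1] "cov01" "cov02"
```

The two covariates simulated with true standardized effects (0.75 and
0.5) carry weight 1.0, the 13 spurious candidates stay below 0.05, and
the best model is the true one with weight 0.73. The three-analysis
comparison on the same data:

```r
three <- fit_three_analyses(sim$data, sim$abundance, sim$detection, cfg)
round(three$correlations, 2)
#>       m1_vs_m2 m1_vs_combined m2_vs_combined
#>           0.98           0.99           0.99
```

Under the `heterogeneous_subpopulations` preset the same workflow
(`analysis/03_fit_heterogeneous.R`) selects *different* variable sets for
the two single-method analyses (hair-trap-only: `cov01`; rub-only:
`cov01, cov03` — each method sees a different subpopulation), the
correlation between the two single-method predictions drops to 0.47, and
the combined analysis concentrates more weight on its top model (0.57)
than either single-method analysis (0.28 / 0.63 at the same lengths — see
`results/scenario_comparison.csv` after running the scripts).

## The analysis workflow

The `analysis/` scripts run the full study end to end and write tables
under `results/`:

```sh
Rscript analysis/01_simulate.R          # build both synthetic surveys (CSV + truth)
Rscript analysis/02_fit_shared.R        # three analyses, shared-population survey
Rscript analysis/03_fit_heterogeneous.R # three analyses, heterogeneous survey
Rscript analysis/04_compare.R           # cross-scenario summary table
```

Outputs per scenario: `variable_weights.csv` (variables × analyses with
importance flags), `model_weights.csv` (best models to cumulative weight
0.5), `abundance_<analysis>.csv` (per-cell median N and relative
abundance), `prediction_changes.csv` (per-cell opposite-impact
classification), `prediction_correlations.csv`, `convergence.csv`, and a
seeded, config-hashed `run.log`.

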