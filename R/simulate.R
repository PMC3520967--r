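#' Scenario configuration for the synthetic-data generator
#'
#' Describes a complete generative model for a two-method repeated-count
#' survey: site covariates with a chosen correlation structure, a sparse set
#' of true abundance effects, per-method detection components calibrated so
#' the median per-occasion detection probability hits a target in the low
#' range typical of noninvasive genetic sampling (~0.06-0.13), optional
#' missing effort for the second method, and an optional two-subpopulation
#' heterogeneity block in which subgroups differ in landscape response and
#' in method-specific detectability (including complete invisibility to one
#' method).
#'
#' @param n_sites Number of sites (grid cells). Default 245.
#' @param occasions Named integer vector of occasions per method. Default
#'   `c(hair_trap = 4, bear_rub = 5)`.
#' @param n_abund_cov Number of candidate abundance covariates. Default 15.
#' @param rho Pairwise correlation among abundance covariates: a scalar
#'   (exchangeable) or a full correlation matrix.
#' @param beta0 True abundance intercept (log scale). Default `log(3)`.
#' @param beta True abundance slopes (length `n_abund_cov`, sparse).
#' @param det_p_target Named per-method target for the median per-occasion
#'   detection probability; the detection intercept is solved numerically
#'   against the realized covariates.
#' @param det_slopes Named list per method of true detection slopes for the
#'   generated covariates (`effort`, `time`).
#' @param missing_frac_m2 Fraction of sites with no effort for the second
#'   method (default 0.31, the generic scenario; presets use 0 to mirror an
#'   analysis restricted to sites sampled by both methods).
#' @param mixing_fraction Fraction of expected abundance contributed by
#'   subpopulation B (0 = homogeneous population).
#' @param beta_B Abundance slopes for subpopulation B (defaults to `beta`).
#' @param susceptibility 2 x n_methods matrix (rows: subgroups A, B) of
#'   method susceptibilities in `[0, 1]`: the probability that a member of
#'   the subgroup is detectable at all by that method, multiplying the
#'   per-occasion detection probability.
#' @param seed Master seed for the scenario.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = 245L,
                            occasions = c(hair_trap = 4L, bear_rub = 5L),
                            n_abund_cov = 15L,
                            rho = 0.3,
                            beta0 = log(3),
                            beta = NULL,
                            det_p_target = c(hair_trap = 0.07,
                                             bear_rub = 0.13),
                            det_slopes = list(
                              hair_trap = c(effort = 0.3, time = -0.2),
                              bear_rub = c(effort = 0.3, time = -0.2)),
                            missing_frac_m2 = 0.31,
                            mixing_fraction = 0,
                            beta_B = NULL,
                            susceptibility = NULL,
                            seed = 1L) {
  n_abund_cov <- as.integer(n_abund_cov)
  if (is.null(beta))  # 2 truly active candidates by default
    beta <- if (n_abund_cov >= 2L) c(0.75, 0.5, rep(0, n_abund_cov - 2L))
            else rep(0, n_abund_cov)
  stopifnot(n_sites >= 1L, length(occasions) == 2L,
            !is.null(names(occasions)),
            length(beta) == n_abund_cov,
            missing_frac_m2 >= 0, missing_frac_m2 <= 1,
            mixing_fraction >= 0, mixing_fraction <= 1,
            all(det_p_target > 0), all(det_p_target < 1))
  M <- length(occasions)
  if (is.null(beta_B)) beta_B <- beta
  if (length(beta_B) != n_abund_cov)
    stop("`beta_B` must have length n_abund_cov")
  if (is.null(susceptibility)) susceptibility <- matrix(1, 2L, M)
  if (any(susceptibility < 0 | susceptibility > 1))
    stop("susceptibilities must lie in [0, 1]")
  dimnames(susceptibility) <- list(c("A", "B"), names(occasions))
  structure(list(n_sites = as.integer(n_sites),
                 occasions = occasions,
                 method_names = names(occasions),
                 n_abund_cov = n_abund_cov,
                 rho = rho, beta0 = beta0, beta = beta,
                 det_p_target = det_p_target, det_slopes = det_slopes,
                 missing_frac_m2 = missing_frac_m2,
                 mixing_fraction = mixing_fraction, beta_B = beta_B,
                 susceptibility = susceptibility,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Named scenario presets
#'
#' `"shared_population"`: both methods sample the whole population; 2 of 15
#' candidate covariates truly act on abundance (standardized effects 0.75
#' and 0.5). `"heterogeneous_subpopulations"`: half of the expected
#' abundance comes from a subgroup that is invisible to the first method and
#' responds to a different covariate, the mechanism by which two methods can
#' sample different segments of a population.
#'
#' @param name Preset name; omit to list available presets.
#' @param ... Overrides passed to [scenario_config()] (e.g. `seed`).
#' @return A `scenario_config` (or names of presets if `name` missing).
#' @export
scenario_presets <- function(name, ...) {
  presets <- c("shared_population", "heterogeneous_subpopulations")
  if (missing(name)) return(presets)
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  if (name == "shared_population") {
    scenario_config(missing_frac_m2 = 0, ...)
  } else {
    beta_A <- c(0.75, rep(0, 14L))
    beta_B <- c(0, 0, 0.75, rep(0, 12L))
    # each method under-samples a different segment: subgroup B is invisible
    # to the systematic method, subgroup A is under-detected by the
    # opportunistic one
    susc <- matrix(c(1, 0.4,
                     0, 1),
                   2L, 2L, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("hair_trap", "bear_rub")))
    scenario_config(beta = beta_A, beta_B = beta_B,
                    mixing_fraction = 0.5, susceptibility = susc,
                    missing_frac_m2 = 0, ...)
  }
}

#' Generate site and detection covariates for a scenario
#'
#' Abundance covariates are multivariate normal with the configured pairwise
#' correlation. Each method gets an `effort` covariate (site-level, skewed
#' like trap counts or rub-days) and a `time` covariate (an occasion-level
#' Julian-day analogue, constant across sites). The true detection
#' intercepts are solved numerically on the realized covariates so the
#' median per-occasion detection probability equals the configured target.
#'
#' @param config A `scenario_config`.
#' @param seed Seed (defaults to `config$seed`).
#' @return List with `abundance` (an `abundance_design`), `detection` (named
#'   list of `detection_design`), and `alpha` (named list of true detection
#'   coefficient vectors, intercept first).
#' @export
generate_covariates <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_sites; J <- config$n_abund_cov
  if (J > 0L) {
    R <- config$rho
    if (!is.matrix(R)) {
      R <- matrix(config$rho, J, J); diag(R) <- 1
    }
    if (!all(dim(R) == c(J, J))) stop("correlation matrix must be J x J")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
      stop("covariate correlation structure is not positive definite")
    L <- chol(R)
    X <- matrix(stats::rnorm(n * J), n, J) %*% L
    colnames(X) <- sprintf("cov%02d", seq_len(J))
  } else {
    X <- matrix(numeric(0), n, 0L)
  }
  abund <- abundance_design(X, standardize = TRUE)

  detection <- list(); alpha <- list()
  for (m in config$method_names) {
    Tm <- config$occasions[[m]]
    effort <- exp(stats::rnorm(n, 0, 0.5))         # skewed, positive
    time <- seq(0, 1, length.out = Tm)             # Julian-day analogue
    dd <- detection_design(n, Tm,
                           covariates = list(effort = effort, time = time),
                           standardize = TRUE)
    sl <- config$det_slopes[[m]]
    eta_cov <- sl[["effort"]] * dd$v$effort + sl[["time"]] * dd$v$time
    target <- config$det_p_target[[m]]
    a0 <- stats::uniroot(
      function(a) stats::median(stats::plogis(a + eta_cov)) - target,
      interval = c(-15, 15), tol = 1e-10)$root
    detection[[m]] <- dd
    alpha[[m]] <- c(a0, sl[["effort"]], sl[["time"]])
    names(alpha[[m]]) <- c("(intercept)", "effort", "time")
  }
  list(abundance = abund, detection = detection, alpha = alpha)
}

#' Simulate the latent population
#'
#' Homogeneous case: `N_i ~ Poisson(exp(beta0 + x_i beta))`. Heterogeneous
#' case (`mixing_fraction > 0`): two independent Poisson subpopulations with
#' subgroup-specific slopes; subgroup intercepts split the overall expected
#' abundance `exp(beta0)` by the mixing fraction, and `N_i` is the sum.
#'
#' @param config A `scenario_config`.
#' @param abund_design The `abundance_design` from [generate_covariates()].
#' @param seed Seed (defaults to `config$seed + 1`).
#' @return Integer vector of class `latent_abundance` with attribute
#'   `subgroups`: an `n_sites x 2` matrix of per-subgroup counts.
#' @export
simulate_population <- function(config, abund_design,
                                seed = config$seed + 1L) {
  set.seed(seed)
  x <- abund_design$x
  f <- config$mixing_fraction
  lam_of <- function(b0, b) {
    lam <- exp(b0 + drop(x %*% b))
    if (any(lam > 1e6))
      stop("expected abundance exceeds 1e6; lower beta0 or the effect sizes")
    lam
  }
  if (f == 0) {
    N_A <- stats::rpois(config$n_sites, lam_of(config$beta0, config$beta))
    N_B <- rep(0L, config$n_sites)
  } else {
    N_A <- stats::rpois(config$n_sites,
                        lam_of(config$beta0 + log1p(-f), config$beta))
    N_B <- stats::rpois(config$n_sites,
                        lam_of(config$beta0 + log(f), config$beta_B))
  }
  N <- as.integer(N_A + N_B)
  structure(N, subgroups = cbind(A = as.integer(N_A), B = as.integer(N_B)),
            class = "latent_abundance")
}

#' Simulate observed counts given the latent population
#'
#' Each subgroup member at a site is detected on a given occasion with
#' probability `susceptibility[subgroup, method] * p_m(i, t)`; subgroup
#' counts are summed, so a subgroup with susceptibility 0 for a method is a
#' structural zero in that method's counts. The configured fraction of sites
#' is then stripped of all effort for the second method (counts set to
#' `NA`).
#'
#' @param config A `scenario_config`.
#' @param latent A `latent_abundance` from [simulate_population()].
#' @param detection The `detection`+`alpha` list from
#'   [generate_covariates()] (the full return value is accepted).
#' @param seed Seed (defaults to `config$seed + 2`).
#' @return A `count_data` object.
#' @export
simulate_counts <- function(config, latent, detection,
                            seed = config$seed + 2L) {
  if (!is.null(detection$detection)) {
    alpha <- detection$alpha
    detection <- detection$detection
  } else stop("pass the list returned by generate_covariates()")
  set.seed(seed)
  n <- config$n_sites
  sub <- attr(latent, "subgroups")
  if (is.null(sub)) sub <- cbind(A = as.integer(latent), B = 0L)
  counts <- list()
  for (mi in seq_along(config$method_names)) {
    m <- config$method_names[mi]
    Tm <- config$occasions[[m]]
    dd <- detection[[m]]
    a <- alpha[[m]]
    eta <- a[[1L]] + a[[2L]] * dd$v$effort + a[[3L]] * dd$v$time
    p <- stats::plogis(eta)
    y <- matrix(0L, n, Tm)
    for (g in 1:2) {
      s <- config$susceptibility[g, m]
      if (s == 0 || all(sub[, g] == 0L)) next
      y <- y + matrix(stats::rbinom(n * Tm, rep(sub[, g], Tm),
                                    as.vector(p) * s), n, Tm)
    }
    counts[[m]] <- y
  }
  if (config$missing_frac_m2 > 0) {
    m2 <- config$method_names[2L]
    n_miss <- round(config$missing_frac_m2 * n)
    miss <- sample.int(n, n_miss)
    counts[[m2]][miss, ] <- NA_integer_
  }
  count_data(counts)
}

#' Simulate a complete scenario dataset
#'
#' Convenience wrapper chaining [generate_covariates()],
#' [simulate_population()] and [simulate_counts()], with the truth bundled
#' for recovery tests.
#'
#' @param config A `scenario_config` or preset name.
#' @param seed Master seed override (defaults to `config$seed`).
#' @return List with `data` (a `count_data`), `abundance`
#'   (`abundance_design`), `detection` (list of `detection_design`), and
#'   `truth` (list: `beta0`, `beta`, `beta_B`, `w` = which slopes are truly
#'   nonzero in either subgroup, `alpha`, `N`, `subgroups`).
#' @export
simulate_scenario <- function(config, seed = NULL) {
  if (is.character(config)) config <- scenario_presets(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cov <- generate_covariates(config)
  latent <- simulate_population(config, cov$abundance)
  data <- simulate_counts(config, latent, cov)
  active <- config$beta != 0 |
    (config$mixing_fraction > 0 & config$beta_B != 0)
  list(data = data, abundance = cov$abundance, detection = cov$detection,
       truth = list(beta0 = config$beta0, beta = config$beta,
                    beta_B = config$beta_B, w = as.integer(active),
                    alpha = cov$alpha, N = as.integer(latent),
                    subgroups = attr(latent, "subgroups")),
       config = config)
}
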