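#' MCMC sampler configuration
#'
#' Defaults follow the study protocol: 190,000 iterations of which the first
#' 10,000 are burn-in, keeping every 20th post-burn-in sample, i.e. 9,000
#' saved draws per chain, with 3 chains for the convergence diagnostic.
#'
#' @param n_iter Total iterations per chain (including burn-in).
#' @param burn_in Burn-in iterations (discarded; proposal scales adapt only
#'   here).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param n_chains Number of chains (>= 2 needed for the BGR diagnostic).
#' @param seed Master seed; chain `c` uses `seed + c - 1`.
#' @param prop_sd_coef Initial random-walk sd for abundance coefficients.
#' @param prop_sd_alpha Initial random-walk sd for detection coefficients.
#' @param step_N Latent-abundance proposal step: `N' = N +/- U{1..step_N}`.
#' @param adapt_window Iterations between proposal-scale adaptations during
#'   burn-in (0 disables adaptation).
#' @param prior_sd_coef Normal prior sd for every coefficient (standardized
#'   covariates assumed).
#' @param prior_pi Prior inclusion probability for each indicator.
#' @param save_N Save latent abundance draws? Needed for abundance summaries.
#' @param gibbs_N Follow the latent random-walk move with an exact Gibbs
#'   refresh of each `N_i` from its enumerated full conditional. This
#'   removes the slow drift along the abundance-detection ridge that appears
#'   when per-occasion detection is weak; disable only for kernel-level
#'   diagnostics.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_iter = 190000L, burn_in = 10000L, thin = 20L,
                           n_chains = 3L, seed = 1L,
                           prop_sd_coef = 0.5, prop_sd_alpha = 0.5,
                           step_N = 5L, adapt_window = 100L,
                           prior_sd_coef = 3.16, prior_pi = 0.5,
                           save_N = TRUE, gibbs_N = TRUE) {
  stopifnot(n_iter >= 1L, burn_in >= 0L, burn_in < n_iter, thin >= 1L,
            n_chains >= 1L, step_N >= 1L,
            prior_pi > 0, prior_pi < 1, prior_sd_coef > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed),
                 prop_sd_coef = prop_sd_coef, prop_sd_alpha = prop_sd_alpha,
                 step_N = as.integer(step_N),
                 adapt_window = as.integer(adapt_window),
                 prior_sd_coef = prior_sd_coef, prior_pi = prior_pi,
                 save_N = isTRUE(save_N), gibbs_N = isTRUE(gibbs_N)),
            class = "sampler_config")
}

#' Number of saved draws per chain implied by a sampler configuration
#' @param config A `sampler_config`.
#' @return Integer: `floor((n_iter - burn_in) / thin)`.
#' @export
n_saved <- function(config) {
  (config$n_iter - config$burn_in) %/% config$thin
}

.param_names <- function(abund_design, det_designs, method_names) {
  cn <- abund_design$covariate_names
  nm <- c("beta0",
          if (length(cn)) paste0("b_", cn),
          if (length(cn)) paste0("w_", cn))
  for (m in method_names) {
    dk <- det_designs[[m]]$covariate_names
    nm <- c(nm, paste0("a0_", m), if (length(dk)) paste0("a_", m, "_", dk))
  }
  nm
}

.det_v_list <- function(det_designs, method_names)
  lapply(method_names, function(m) unname(det_designs[[m]]$v))

.y_na <- function(data) lapply(data$counts, function(y) y)

#' Fit the multi-method N-mixture model by Metropolis-within-Gibbs MCMC
#'
#' Runs `config$n_chains` chains of the sampler over latent abundances,
#' abundance coefficients, Kuo-Mallick inclusion indicators and per-method
#' detection coefficients. Fully reproducible given the config seed:
#' identical configurations give bitwise-identical draws.
#'
#' Initialization: `N_i = max observed count + 1`; each chain's coefficients
#' are drawn overdispersed from Normal(0, 2 x proposal sd); indicators start
#' at independent Bernoulli(prior_pi) draws.
#'
#' @param data A `count_data` object.
#' @param abund_design An `abundance_design` (columns are the candidate
#'   abundance covariates).
#' @param det_designs Named list of `detection_design`, one per method in
#'   `data`.
#' @param config A `sampler_config`.
#' @param select Sample inclusion indicators? `FALSE` fixes all `w = 1`
#'   (used for reduced refits).
#' @param sample_detection Sample detection coefficients? `FALSE` holds them
#'   at their initial values (exact-inference test harness).
#' @param init Optional named list overriding initial values per chain
#'   (`beta0`, `beta`, `w`, `alpha`, `N`); applied identically to all chains.
#' @return An object of class `mn_fit`: chains of parameter draws, latent
#'   abundance draws, acceptance rates, the config, and naming metadata.
#' @export
run_mcmc <- function(data, abund_design, det_designs, config = sampler_config(),
                     select = TRUE, sample_detection = TRUE, init = NULL) {
  stopifnot(inherits(data, "count_data"),
            inherits(abund_design, "abundance_design"),
            inherits(config, "sampler_config"))
  n <- n_sites(data)
  if (nrow(abund_design$x) != n)
    stop("abundance design has ", nrow(abund_design$x),
         " rows but data has ", n, " sites")
  miss <- setdiff(data$method_names, names(det_designs))
  if (length(miss))
    stop("missing detection design(s) for method(s): ",
         paste(miss, collapse = ", "))
  for (m in data$method_names) {
    dd <- det_designs[[m]]
    if (dd$n_sites != n || dd$n_occasions != ncol(data$counts[[m]]))
      stop("detection design for '", m, "' does not match the count data")
  }
  J <- ncol(abund_design$x)
  lb <- max_observed(data)
  pn <- .param_names(abund_design, det_designs, data$method_names)
  Vl <- .det_v_list(det_designs, data$method_names)
  Kd <- vapply(data$method_names,
               function(m) length(det_designs[[m]]$v), 1L)

  chains <- vector("list", config$n_chains)
  Nchains <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)
  finals <- vector("list", config$n_chains)
  seeds <- config$seed + seq_len(config$n_chains) - 1L

  for (ch in seq_len(config$n_chains)) {
    set.seed(seeds[ch])
    i_beta0 <- stats::rnorm(1, 0, 2 * config$prop_sd_coef)
    i_beta <- stats::rnorm(J, 0, 2 * config$prop_sd_coef)
    i_w <- if (select) stats::rbinom(J, 1L, config$prior_pi) else rep(1L, J)
    i_alpha <- lapply(seq_along(data$method_names), function(mi)
      stats::rnorm(1L + Kd[mi], 0, 2 * config$prop_sd_alpha))
    i_N <- lb + 1L
    if (!is.null(init)) {
      if (!is.null(init$beta0)) i_beta0 <- init$beta0
      if (!is.null(init$beta))  i_beta  <- init$beta
      if (!is.null(init$w))     i_w     <- as.integer(init$w)
      if (!is.null(init$alpha)) i_alpha <- lapply(data$method_names,
                                                  function(m) init$alpha[[m]])
      if (!is.null(init$N))     i_N     <- as.integer(init$N)
    }
    lam0 <- exp(i_beta0 + if (J) drop(abund_design$x %*% (i_beta * i_w)) else 0)
    if (any(!is.finite(lam0)))
      stop("non-finite expected abundance at initialization (site ",
           which(!is.finite(lam0))[1L], "); check covariate scaling")
    res <- .mcmc_chain(.y_na(data), abund_design$x, Vl,
                       config$prior_sd_coef, config$prior_pi,
                       config$n_iter, config$burn_in, config$thin,
                       select, sample_detection, config$save_N,
                       config$step_N, config$prop_sd_coef,
                       config$prop_sd_alpha, config$adapt_window,
                       i_beta0, as.numeric(i_beta), as.integer(i_w),
                       i_alpha, as.integer(i_N),
                       TRUE, TRUE, isTRUE(config$gibbs_N))
    colnames(res$draws) <- pn
    chains[[ch]] <- res$draws
    Nchains[[ch]] <- if (config$save_N) res$N_draws else NULL
    accept[[ch]] <- list(N = res$accept_N, coef = res$accept_coef,
                         alpha = res$accept_alpha,
                         ridge = res$accept_ridge)
    finals[[ch]] <- res$final_state
  }
  structure(list(chains = chains, N_chains = Nchains,
                 param_names = pn,
                 covariate_names = abund_design$covariate_names,
                 method_names = data$method_names,
                 site_ids = data$site_ids,
                 select = select, config = config, seeds = seeds,
                 accept = accept, final_state = finals),
            class = "mn_fit")
}

#' @export
print.mn_fit <- function(x, ...) {
  cat("mn_fit:", length(x$chains), "chain(s) x", nrow(x$chains[[1L]]),
      "saved draws;", length(x$param_names), "parameters\n")
  cat("  covariate selection:", if (x$select) "on (Kuo-Mallick)" else "off",
      "\n")
  if (length(x$chains) >= 2L) {
    r <- bgr_statistic(x)
    cat("  max BGR over monitored parameters:", signif(max(r), 4), "\n")
  }
  invisible(x)
}

#' Pool post-burn-in draws across chains
#'
#' @param fit An `mn_fit`.
#' @param params Optional character vector of parameter names to keep.
#' @return Matrix of pooled draws (rows = chain-concatenated saved draws).
#' @export
pooled_draws <- function(fit, params = NULL) {
  d <- do.call(rbind, fit$chains)
  if (!is.null(params)) {
    miss <- setdiff(params, colnames(d))
    if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
    d <- d[, params, drop = FALSE]
  }
  d
}

#' Pool latent abundance draws across chains
#' @param fit An `mn_fit` run with `save_N = TRUE`.
#' @return Matrix (pooled draws x sites) of latent abundances.
#' @export
pooled_N <- function(fit) {
  if (is.null(fit$N_chains[[1L]]))
    stop("fit was run with save_N = FALSE; no latent abundance draws")
  do.call(rbind, fit$N_chains)
}

#' Names of the continuously-varying (monitored) parameters of a fit
#'
#' The convergence diagnostic is computed over the continuous parameters
#' (intercepts, slopes); binary indicators are excluded as their chains are
#' near-degenerate whenever a covariate's weight approaches 0 or 1.
#' @param fit An `mn_fit`.
#' @return Character vector of parameter names.
#' @export
monitored_params <- function(fit) {
  grep("^w_", fit$param_names, value = TRUE, invert = TRUE)
}

#' Brooks-Gelman-Rubin convergence diagnostic
#'
#' Default (`method = "interval"`) is the interval-based BGR ratio used by
#' WinBUGS: the width of the pooled-chain central 80% interval divided by
#' the mean within-chain 80% interval width. Exactly 1 when chains are
#' copies of one another; values near 1 indicate between-chain agreement.
#' `method = "psrf"` gives the corrected potential scale reduction factor
#' (between/within variance form with the sampling-variability df
#' correction).
#'
#' @param fit An `mn_fit`, or a list of chain matrices (draws x parameters)
#'   with identical column names.
#' @param params Parameters to monitor; defaults to all continuous
#'   parameters (indicators excluded) for an `mn_fit`, all columns for a
#'   plain list.
#' @param method `"interval"` (WinBUGS-style BGR) or `"psrf"`.
#' @param prob Central interval probability for the interval method.
#' @return Named numeric vector of per-parameter diagnostics.
#' @export
bgr_statistic <- function(fit, params = NULL,
                          method = c("interval", "psrf"), prob = 0.8) {
  method <- match.arg(method)
  if (inherits(fit, "mn_fit")) {
    if (is.null(params)) params <- monitored_params(fit)
    chains <- lapply(fit$chains, function(m) m[, params, drop = FALSE])
  } else {
    chains <- lapply(fit, as.matrix)
    if (!is.null(params))
      chains <- lapply(chains, function(m) m[, params, drop = FALSE])
  }
  m <- length(chains)
  if (m < 2L) stop("the BGR diagnostic needs at least 2 chains")
  n <- nrow(chains[[1L]])
  if (n < 10L) stop("need at least 10 draws per chain")
  P <- ncol(chains[[1L]])
  out <- numeric(P)
  names(out) <- colnames(chains[[1L]])
  lo <- (1 - prob) / 2; hi <- 1 - lo
  for (p in seq_len(P)) {
    x <- vapply(chains, function(ch) ch[, p], numeric(n))  # n x m
    if (method == "interval") {
      wid <- apply(x, 2L, function(v) diff(stats::quantile(v, c(lo, hi),
                                                           names = FALSE)))
      pooled <- diff(stats::quantile(as.vector(x), c(lo, hi), names = FALSE))
      wbar <- mean(wid)
      out[p] <- if (pooled == 0 && wbar == 0) 1 else pooled / wbar
    } else {
      out[p] <- .psrf(x)
    }
  }
  out
}

# Corrected potential scale reduction factor for one parameter.
# x: n draws x m chains.
.psrf <- function(x) {
  n <- nrow(x); m <- ncol(x)
  xbar <- colMeans(x)
  s2 <- apply(x, 2L, stats::var)
  W <- mean(s2)
  B <- n * stats::var(xbar)
  if (W == 0) return(1)
  sig2 <- (n - 1) / n * W + B / n
  Vhat <- sig2 + B / (m * n)
  # df correction (sampling variability of the variance estimate)
  var_V <- ((n - 1) / n)^2 / m * stats::var(s2) +
    ((m + 1) / (m * n))^2 * 2 / (m - 1) * B^2 +
    2 * (m + 1) * (n - 1) / (m * n^2) * n / m *
      (stats::cov(s2, xbar^2) - 2 * mean(xbar) * stats::cov(s2, xbar))
  d <- if (var_V > 0) 2 * Vhat^2 / var_V else Inf
  corr <- if (is.finite(d)) (d + 3) / (d + 1) else 1
  sqrt(corr * Vhat / W)
}

#' Check a fit against the convergence criterion
#'
#' Computes the BGR diagnostic over monitored parameters and warns when the
#' maximum exceeds the threshold (the study's criterion is BGR <= 1.01).
#'
#' @param fit An `mn_fit` with >= 2 chains.
#' @param threshold Convergence threshold (default 1.01).
#' @return Invisibly, a list with per-parameter `bgr`, `max_bgr`, and
#'   logical `converged`.
#' @export
check_convergence <- function(fit, threshold = 1.01) {
  r <- bgr_statistic(fit)
  mx <- max(r)
  conv <- mx <= threshold
  if (!conv)
    warning(sprintf(
      "convergence not reached: max BGR = %.4f > %.2f (worst parameter: %s); lengthen the chains",
      mx, threshold, names(r)[which.max(r)]), call. = FALSE)
  invisible(list(bgr = r, max_bgr = mx, converged = conv))
}

#' Run a single update sweep of one sampler kernel (test harness)
#'
#' Exposes the three Metropolis-within-Gibbs update kernels (latent
#' abundance, coefficients, indicators) one at a time from a given state,
#' mainly for targeted tests of each kernel's invariants.
#'
#' @param data,abund_design,det_designs As in [run_mcmc()].
#' @param state Named list with `beta0`, `beta`, `w`, `alpha` (named list per
#'   method), `N`.
#' @param kernel One of `"latent"`, `"coefficients"`, `"indicators"`,
#'   `"detection"`.
#' @param config A `sampler_config` (proposal scales and priors are used;
#'   lengths are ignored).
#' @param n_sweeps Number of consecutive sweeps of the chosen kernel.
#' @return Updated state list.
#' @export
mcmc_sweep <- function(data, abund_design, det_designs, state,
                       kernel = c("latent", "coefficients", "indicators",
                                  "detection"),
                       config = sampler_config(), n_sweeps = 1L) {
  kernel <- match.arg(kernel)
  Vl <- .det_v_list(det_designs, data$method_names)
  res <- .mcmc_chain(.y_na(data), abund_design$x, Vl,
                     config$prior_sd_coef, config$prior_pi,
                     as.integer(n_sweeps), 0L, 1L,
                     kernel == "indicators", kernel == "detection",
                     FALSE, config$step_N, config$prop_sd_coef,
                     config$prop_sd_alpha, 0L,
                     state$beta0, as.numeric(state$beta),
                     as.integer(state$w),
                     lapply(data$method_names, function(m) state$alpha[[m]]),
                     as.integer(state$N),
                     kernel == "latent", kernel == "coefficients",
                     FALSE)  # single-kernel mode exercises the bare moves
  fs <- res$final_state
  names(fs$alpha) <- data$method_names
  fs
}
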