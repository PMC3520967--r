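#' Expected abundance under the log-linear model
#'
#' lambda_i = exp(beta0 + sum_j w_j * beta_j * x_ij). Covariates whose
#' inclusion indicator is 0 contribute nothing.
#'
#' @param params A `model_params` object.
#' @param design An `abundance_design` whose columns match `params$beta`.
#' @return Positive numeric vector of per-site expected abundances.
#' @export
expected_abundance <- function(params, design) {
  stopifnot(inherits(params, "model_params"),
            inherits(design, "abundance_design"))
  J <- length(params$beta)
  if (ncol(design$x) != J)
    stop("design has ", ncol(design$x), " covariate column(s) but `beta` has ",
         J, " element(s)")
  eta <- rep(params$beta0, nrow(design$x))
  if (J > 0L)
    eta <- eta + drop(design$x %*% (params$beta * params$w))
  exp(eta)
}

#' Per-occasion detection probability under the logit-linear model
#'
#' p = logistic(alpha0_m + sum_k alpha_mk * v_m[site, occasion, k]).
#'
#' @param params A `model_params` object with a detection component for
#'   `method`.
#' @param design A `detection_design` for that method.
#' @param method Method name.
#' @param site Site index (may be a vector).
#' @param occasion Occasion index (same length as `site` or scalar).
#' @return Detection probability strictly inside (0, 1).
#' @export
detection_probability <- function(params, design, method, site, occasion) {
  if (!method %in% names(params$alpha))
    stop("no detection component for method '", method, "'; have: ",
         paste(names(params$alpha), collapse = ", "))
  a <- params$alpha[[method]]
  eta <- rep(a[[1L]], length(site))
  K <- length(design$v)
  if (length(a) != K + 1L)
    stop("detection coefficients for '", method, "' must be intercept + ",
         K, " slope(s)")
  if (K > 0L)
    for (k in seq_len(K))
      eta <- eta + a[[k + 1L]] * design$v[[k]][cbind(site, occasion)]
  p <- stats::plogis(eta)
  # open-interval contract: the binomial likelihood needs 0 < p < 1
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Sentinel used for impossible configurations in accept/reject arithmetic
#' @keywords internal
.NEG_INF <- -1e300

#' Binomial count log-likelihood
#'
#' log Binomial(N, p) pmf at `y`; returns a large negative sentinel rather
#' than `-Inf` when `y > N` so that accept/reject arithmetic never produces
#' NaN.
#'
#' @param y Observed count (nonnegative integer, vectorized).
#' @param N Latent abundance (nonnegative integer).
#' @param p Detection probability in (0, 1).
#' @return Log-likelihood value(s).
#' @export
count_loglik <- function(y, N, p) {
  if (any(y < 0) || any(N < 0)) stop("`y` and `N` must be nonnegative")
  ll <- stats::dbinom(y, N, p, log = TRUE)
  ll[y > N] <- .NEG_INF
  ll
}

#' Joint log-likelihood contribution of one site
#'
#' Poisson(lambda_i) log pmf at `N_i` plus the binomial log-likelihood summed
#' over every observed (occasion, method) cell at the site. Masked cells
#' contribute exactly 0.
#'
#' @param data A `count_data` object.
#' @param N_i Latent abundance at `site`.
#' @param params A `model_params` object.
#' @param abund_design An `abundance_design`.
#' @param det_designs Named list of `detection_design`, one per method.
#' @param site Site index.
#' @return Scalar log-likelihood.
#' @export
site_joint_loglik <- function(data, N_i, params, abund_design, det_designs,
                              site) {
  lam <- expected_abundance(params, abund_design)[site]
  ll <- stats::dpois(N_i, lam, log = TRUE)
  for (m in data$method_names) {
    yrow <- data$counts[[m]][site, ]
    obs <- which(!is.na(yrow))
    if (!length(obs)) next
    p <- detection_probability(params, det_designs[[m]], m,
                               rep(site, length(obs)), obs)
    ll <- ll + sum(count_loglik(yrow[obs], N_i, p))
  }
  max(ll, .NEG_INF)
}

#' Full-data log joint (sum of site contributions)
#'
#' @inheritParams site_joint_loglik
#' @param N Integer vector of latent abundances, one per site.
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(data, N, params, abund_design, det_designs) {
  sum(vapply(seq_len(n_sites(data)), function(i)
    site_joint_loglik(data, N[i], params, abund_design, det_designs, i), 1.0))
}

#' Exact marginal log-likelihood of one site by truncated summation
#'
#' Sums the Poisson-binomial mixture over N from the site's max observed
#' count up to a truncation bound K: log sum_N Poisson(N; lambda_i) *
#' prod Binomial(y | N, p). This is the exact-inference oracle used to test
#' the sampler; it is deterministic.
#'
#' @inheritParams site_joint_loglik
#' @param K Truncation bound; the Poisson tail mass above `K` must be below
#'   `tail_tol` or an error instructs a larger `K`.
#' @param tail_tol Tail-mass tolerance (default 1e-8).
#' @return Scalar log marginal likelihood (<= 0 for proper inputs).
#' @export
marginal_site_loglik <- function(data, params, abund_design, det_designs,
                                 site, K, tail_tol = 1e-8) {
  lb <- max_observed(data)[site]
  if (K < lb) stop("K = ", K, " is below the max observed count ", lb,
                   " at site ", site)
  lam <- expected_abundance(params, abund_design)[site]
  tail <- stats::ppois(K, lam, lower.tail = FALSE)
  if (tail >= tail_tol)
    stop("Poisson tail mass above K = ", K, " is ", signif(tail, 3),
         " >= ", tail_tol, "; increase K")
  Ns <- lb:K
  ll <- stats::dpois(Ns, lam, log = TRUE)
  for (m in data$method_names) {
    yrow <- data$counts[[m]][site, ]
    obs <- which(!is.na(yrow))
    for (t in obs) {
      p <- detection_probability(params, det_designs[[m]], m, site, t)
      ll <- ll + stats::dbinom(yrow[t], Ns, p, log = TRUE)
    }
  }
  mx <- max(ll)
  if (!is.finite(mx)) return(.NEG_INF)
  mx + log(sum(exp(ll - mx)))
}
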