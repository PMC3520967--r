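# Shared fixtures and small numerical helpers.

# A fixed 3-site, 2-method toy dataset (2 + 2 occasions), counts chosen by
# hand so every site has detections and the latent lower bounds differ.
toy_counts <- function() {
  list(m1 = matrix(c(0L, 1L, 2L,
                     1L, 0L, 1L), 3L, 2L),
       m2 = matrix(c(1L, 0L, 1L,
                     0L, 1L, 2L), 3L, 2L))
}

toy_data <- function() count_data(toy_counts())

# site covariate for the toy (already centered/scaled by construction)
toy_design <- function() {
  abundance_design(matrix(c(-1, 0, 1), 3L, 1L,
                          dimnames = list(NULL, "x1")),
                   standardize = FALSE)
}

# intercept-only detection designs for the toy
toy_det_designs <- function() {
  list(m1 = detection_design(3L, 2L),
       m2 = detection_design(3L, 2L))
}

toy_params <- function(beta0 = 0.7, beta1 = 0.8, w = 1L,
                       p1 = 0.3, p2 = 0.4) {
  model_params(beta0 = beta0, beta = beta1, w = w,
               alpha = list(m1 = qlogis(p1), m2 = qlogis(p2)))
}

# a fake mn_fit carrying given chains (for selection-table tests)
fake_fit <- function(chains) {
  structure(list(chains = chains, N_chains = list(NULL),
                 param_names = colnames(chains[[1L]]),
                 covariate_names = sub("^w_", "",
                   grep("^w_", colnames(chains[[1L]]), value = TRUE)),
                 select = TRUE),
            class = "mn_fit")
}

# batch-means Monte Carlo standard error of the mean of one chain
mcse_batch <- function(x, n_batch = 40L) {
  n <- length(x)
  b <- n %/% n_batch
  means <- vapply(seq_len(n_batch), function(k)
    mean(x[((k - 1L) * b + 1L):(k * b)]), 1.0)
  stats::sd(means) / sqrt(n_batch)
}

# MCSE of a pooled-chain mean from per-chain batch-means
mcse_pooled <- function(chains_x) {
  ses <- vapply(chains_x, mcse_batch, 1.0)
  sqrt(sum(ses^2)) / length(ses)
}

# Exact posterior for the 3-site toy with one candidate covariate and fixed
# detection probabilities, by quadrature over (beta0, beta1) and the
# indicator, summing the latent N out by direct enumeration. Everything is
# computed from plain dpois/dbinom so the oracle shares no code with the
# sampler or the package likelihoods.
toy_enum_posterior <- function(counts, x, p1, p2, prior_sd, prior_pi,
                               b0_grid = seq(-4, 4, by = 0.05),
                               b1_grid = seq(-6, 6, by = 0.05),
                               K = 60L) {
  n <- nrow(counts$m1)
  Ns <- 0:K
  # per-site likelihood of the counts given N (detection fixed)
  binlik <- vapply(seq_len(n), function(i) {
    l <- rep(1.0, K + 1L)
    for (t in seq_len(ncol(counts$m1)))
      l <- l * dbinom(counts$m1[i, t], Ns, p1)
    for (t in seq_len(ncol(counts$m2)))
      l <- l * dbinom(counts$m2[i, t], Ns, p2)
    l
  }, numeric(K + 1L))                      # (K+1) x n
  site_marg <- function(lam_i, i)          # vector over param combos
    dpois_mat(lam_i, K) %*% binlik[, i]
  EN_site <- function(lam_i, i) {
    D <- dpois_mat(lam_i, K)
    num <- as.vector((D * rep(Ns, each = length(lam_i))) %*% binlik[, i])
    den <- as.vector(D %*% binlik[, i])
    en <- num / den
    en[den == 0] <- 0  # zero posterior weight there anyway
    en
  }
  # w = 0 branch: beta1 integrates out of the likelihood exactly
  lik0 <- rep(1.0, length(b0_grid))
  EN0 <- matrix(0, length(b0_grid), n)
  for (i in seq_len(n)) {
    lam <- exp(b0_grid)
    lik0 <- lik0 * as.vector(site_marg(lam, i))
    EN0[, i] <- EN_site(lam, i)
  }
  post0 <- dnorm(b0_grid, 0, prior_sd) * lik0 * (1 - prior_pi)
  # w = 1 branch: full (beta0, beta1) grid
  g <- expand.grid(b0 = b0_grid, b1 = b1_grid)
  lik1 <- rep(1.0, nrow(g))
  EN1 <- matrix(0, nrow(g), n)
  for (i in seq_len(n)) {
    lam <- exp(g$b0 + g$b1 * x[i])
    lik1 <- lik1 * as.vector(site_marg(lam, i))
    EN1[, i] <- EN_site(lam, i)
  }
  post1 <- dnorm(g$b0, 0, prior_sd) * dnorm(g$b1, 0, prior_sd) * lik1 *
    prior_pi
  z0 <- sum(post0) * diff(b0_grid[1:2])
  z1 <- sum(post1) * diff(b0_grid[1:2]) * diff(b1_grid[1:2])
  ztot <- z0 + z1
  w0 <- post0 / sum(post0); w1 <- post1 / sum(post1)
  list(
    p_w1 = z1 / ztot,
    E_beta0 = (z0 * sum(w0 * b0_grid) + z1 * sum(w1 * g$b0)) / ztot,
    # beta1 under w = 0 is prior-distributed with mean 0
    E_beta1 = (z1 * sum(w1 * g$b1)) / ztot,
    E_N = (z0 * colSums(w0 * EN0) + z1 * colSums(w1 * EN1)) / ztot)
}

dpois_mat <- function(lam, K)   # length(lam) x (K+1)
  outer(lam, 0:K, function(l, k) dpois(k, l))
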