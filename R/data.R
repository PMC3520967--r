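#' Repeated-count data for a multi-method survey
#'
#' Bundles observed counts of individuals per site (grid cell), sampling
#' occasion and detection method, together with an effort mask. Counts are
#' stored as one matrix per method (sites x occasions); `NA` marks a
#' site-occasion with no sampling effort for that method. Methods may have
#' different numbers of occasions (e.g. 4 hair-trap and 5 bear-rub sessions);
#' the per-method matrices form a ragged structure behind a uniform
#' `(site, occasion, method)` view.
#'
#' @param counts Named list of integer matrices, one per detection method,
#'   each `n_sites x n_occasions(method)`. `NA` = no effort.
#' @param site_ids Optional character/integer vector of site labels; defaults
#'   to rownames of the first matrix or `1:n_sites`.
#' @return An object of class `count_data` with elements `counts` (list of
#'   integer matrices), `site_ids`, `method_names`, `occasions`.
#' @examples
#' y <- list(hair_trap = matrix(c(1, 0, NA, 2), 2, 2),
#'           bear_rub  = matrix(c(0, 3, 1, 0, 0, 1), 2, 3))
#' cd <- count_data(y)
#' n_sites(cd)
#' @export
count_data <- function(counts, site_ids = NULL) {
  if (!is.list(counts) || length(counts) < 1L)
    stop("`counts` must be a non-empty named list of matrices")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("`counts` must be named by detection method")
  counts <- lapply(counts, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    m
  })
  ns <- vapply(counts, nrow, 1L)
  if (length(unique(ns)) != 1L)
    stop("all method count matrices must have the same number of sites (rows)")
  n <- ns[[1L]]
  if (n < 1L) stop("no sites: count matrices have zero rows")
  for (m in names(counts)) {
    y <- counts[[m]]
    if (any(y[!is.na(y)] < 0L))
      stop("negative count in method '", m, "'")
  }
  obs_any <- Reduce(`+`, lapply(counts, function(y) rowSums(!is.na(y))))
  if (any(obs_any == 0L))
    stop("site(s) ", paste(which(obs_any == 0L), collapse = ", "),
         " have no observed (site, occasion, method) entry")
  if (is.null(site_ids)) site_ids <- rownames(counts[[1L]])
  if (is.null(site_ids)) site_ids <- seq_len(n)
  if (length(site_ids) != n) stop("`site_ids` length must equal number of sites")
  structure(
    list(counts = counts,
         site_ids = site_ids,
         method_names = names(counts),
         occasions = vapply(counts, ncol, 1L)),
    class = "count_data")
}

#' @export
print.count_data <- function(x, ...) {
  cat("count_data:", n_sites(x), "sites;",
      paste(sprintf("%s (%d occasions)", x$method_names, x$occasions),
            collapse = ", "), "\n")
  nobs <- vapply(x$counts, function(y) sum(!is.na(y)), 1L)
  cat("  observed site-occasions:",
      paste(sprintf("%s=%d", x$method_names, nobs), collapse = ", "), "\n")
  invisible(x)
}

#' Number of sites in a count_data object
#' @param data A `count_data` object.
#' @return Integer number of sites.
#' @export
n_sites <- function(data) nrow(data$counts[[1L]])

#' Maximum observed count per site across methods and occasions
#'
#' The lower bound that any latent abundance vector must satisfy.
#' @param data A `count_data` object.
#' @return Integer vector, one per site (0 where nothing was ever detected).
#' @export
max_observed <- function(data) {
  mats <- lapply(data$counts, function(y) {
    y[is.na(y)] <- 0L
    apply(y, 1L, max)
  })
  as.integer(Reduce(pmax, mats))
}

#' Mask (drop) all effort for one method
#'
#' Returns a copy of `data` in which every occasion of `method` is marked as
#' unsampled. Used to derive the single-method analyses from a combined
#' dataset.
#' @param data A `count_data` object.
#' @param method Method name to mask.
#' @return A `count_data` object.
#' @export
mask_method <- function(data, method) {
  if (!method %in% data$method_names)
    stop("unknown method '", method, "'; have: ",
         paste(data$method_names, collapse = ", "))
  keep <- setdiff(data$method_names, method)
  obs_keep <- Reduce(`+`, lapply(data$counts[keep],
                                 function(y) rowSums(!is.na(y))))
  if (any(obs_keep == 0L))
    stop("masking '", method, "' would leave site(s) with no observations; ",
         "drop those sites first (see fit_three_analyses)")
  data$counts[[method]][] <- NA_integer_
  data
}

#' Subset a count_data object to a set of sites
#' @param data A `count_data` object.
#' @param sites Integer or logical index over sites.
#' @return A `count_data` object.
#' @export
subset_sites <- function(data, sites) {
  counts <- lapply(data$counts, function(y) y[sites, , drop = FALSE])
  count_data(counts, site_ids = data$site_ids[sites])
}

#' Site-level abundance design matrix
#'
#' Covariates thought to drive local abundance; one value per site, constant
#' over occasions. Standardization (center/scale per column) is applied by
#' default and the transform is stored so new data can be placed on the same
#' scale.
#'
#' @param x Numeric matrix or data frame, sites x covariates, with column
#'   names.
#' @param standardize Center and scale each column? Default `TRUE`.
#' @return An object of class `abundance_design`: `x` (numeric matrix),
#'   `covariate_names`, `center`, `scale`.
#' @export
abundance_design <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) > 0L && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (any(!is.finite(x))) stop("abundance covariates must be finite")
  center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  if (standardize && ncol(x) > 0L) {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    if (any(scale == 0)) {
      # constant columns are left uncentered-unscaled rather than producing NaN
      keep <- scale > 0
      x[, keep] <- sweep(sweep(x[, keep, drop = FALSE], 2L, center[keep]),
                         2L, scale[keep], "/")
      center[!keep] <- 0; scale[!keep] <- 1
    } else {
      x <- sweep(sweep(x, 2L, center), 2L, scale, "/")
    }
  }
  names(center) <- names(scale) <- colnames(x)
  structure(list(x = x, covariate_names = colnames(x),
                 center = center, scale = scale,
                 standardized = isTRUE(standardize)),
            class = "abundance_design")
}

#' Subset an abundance design to a set of covariates
#' @param design An `abundance_design`.
#' @param covariates Character vector of covariate names (may be empty).
#' @return An `abundance_design` restricted to those columns (standardization
#'   record carried along; columns are not re-standardized).
#' @export
subset_design <- function(design, covariates) {
  stopifnot(inherits(design, "abundance_design"))
  miss <- setdiff(covariates, design$covariate_names)
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  out <- design
  out$x <- design$x[, covariates, drop = FALSE]
  out$covariate_names <- covariates
  out$center <- design$center[covariates]
  out$scale <- design$scale[covariates]
  out
}

#' Per-method detection design
#'
#' Detection covariates for one method. Each covariate may be constant over
#' occasions (a site vector), constant over sites (an occasion vector, e.g. a
#' Julian-day analogue), or fully varying (a sites x occasions matrix).
#' Everything is expanded to sites x occasions matrices internally.
#'
#' @param n_sites Number of sites.
#' @param n_occasions Number of occasions for this method.
#' @param covariates Named list of covariates (vector of length `n_sites`,
#'   vector of length `n_occasions`, or `n_sites x n_occasions` matrix). May
#'   be empty for an intercept-only detection component.
#' @param standardize Center/scale each covariate over all site-occasions?
#'   Default `TRUE`.
#' @return Object of class `detection_design`: list `v` of matrices,
#'   `covariate_names`, `n_sites`, `n_occasions`, `center`, `scale`.
#' @export
detection_design <- function(n_sites, n_occasions, covariates = list(),
                             standardize = TRUE) {
  stopifnot(n_sites >= 1L, n_occasions >= 1L)
  if (length(covariates) && (is.null(names(covariates)) ||
                             any(!nzchar(names(covariates)))))
    stop("detection covariates must be named")
  v <- lapply(names(covariates), function(nm) {
    z <- covariates[[nm]]
    if (is.matrix(z)) {
      if (!all(dim(z) == c(n_sites, n_occasions)))
        stop("covariate '", nm, "' matrix must be n_sites x n_occasions")
    } else if (length(z) == n_sites && n_sites != n_occasions) {
      z <- matrix(z, n_sites, n_occasions)
    } else if (length(z) == n_occasions) {
      z <- matrix(z, n_sites, n_occasions, byrow = TRUE)
    } else if (length(z) == n_sites) {
      z <- matrix(z, n_sites, n_occasions)
    } else {
      stop("covariate '", nm, "' has length ", length(z),
           "; expected ", n_sites, " (site) or ", n_occasions, " (occasion)")
    }
    storage.mode(z) <- "double"
    z
  })
  names(v) <- names(covariates)
  center <- numeric(0); scl <- numeric(0)
  if (standardize && length(v)) {
    center <- vapply(v, function(z) mean(z), 1)
    scl <- vapply(v, function(z) stats::sd(as.vector(z)), 1)
    scl[scl == 0 | !is.finite(scl)] <- 1
    v <- mapply(function(z, ce, sc) (z - ce) / sc, v, center, scl,
                SIMPLIFY = FALSE)
  }
  for (nm in names(v))
    if (any(!is.finite(v[[nm]])))
      stop("detection covariate '", nm, "' must be finite")
  structure(list(v = v, covariate_names = names(v),
                 n_sites = as.integer(n_sites),
                 n_occasions = as.integer(n_occasions),
                 center = center, scale = scl,
                 standardized = isTRUE(standardize)),
            class = "detection_design")
}

#' Model parameters for the two-level N-mixture model
#'
#' Abundance side: intercept `beta0` and slopes `beta` on the log scale, with
#' binary inclusion indicators `w` (a covariate contributes only when its
#' indicator is 1). Detection side: per method an intercept and slopes on the
#' logit scale.
#'
#' @param beta0 Abundance intercept (log scale).
#' @param beta Named numeric vector of abundance slopes (may be empty).
#' @param w Integer 0/1 inclusion indicators, same length as `beta`;
#'   defaults to all 1.
#' @param alpha Named list, one element per method, each a numeric vector
#'   whose first element is the detection intercept (logit scale) followed by
#'   slopes named after the detection covariates.
#' @return Object of class `model_params`.
#' @export
model_params <- function(beta0, beta = numeric(0), w = NULL, alpha = list()) {
  beta <- as.numeric(beta)
  if (is.null(w)) w <- rep(1L, length(beta))
  w <- as.integer(w)
  if (length(w) != length(beta)) stop("`w` must match `beta` length")
  if (any(!w %in% c(0L, 1L))) stop("indicators `w` must be 0/1")
  if (!all(is.finite(c(beta0, beta, unlist(alpha)))))
    stop("all coefficients must be finite")
  structure(list(beta0 = as.numeric(beta0), beta = beta, w = w,
                 alpha = alpha),
            class = "model_params")
}

#' Validate a latent abundance vector against observed counts
#'
#' @param N Integer vector of per-site latent abundances.
#' @param data A `count_data` object.
#' @return `N` (invisibly) after checking nonnegativity and the per-site
#'   lower bound `N[i] >= max` observed count at site `i`.
#' @export
validate_latent <- function(N, data) {
  N <- as.integer(N)
  if (length(N) != n_sites(data)) stop("latent N has wrong length")
  if (any(N < 0L)) stop("latent abundance must be nonnegative")
  lb <- max_observed(data)
  bad <- which(N < lb)
  if (length(bad))
    stop("latent N below max observed count at site(s) ",
         paste(bad, collapse = ", "))
  invisible(N)
}
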