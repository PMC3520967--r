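#' Posterior inclusion weight of each candidate covariate
#'
#' The weight of covariate j is the fraction of pooled post-burn-in draws
#' (all chains) in which its inclusion indicator equals 1.
#'
#' @param fit An `mn_fit` run with `select = TRUE`.
#' @return Named numeric vector of weights in `[0, 1]`, one per candidate
#'   covariate.
#' @export
variable_weights <- function(fit) {
  wcols <- grep("^w_", fit$param_names, value = TRUE)
  if (!length(wcols))
    stop("fit has no inclusion indicators (no candidate covariates)")
  d <- pooled_draws(fit, wcols)
  if (nrow(d) == 0L) stop("fit contains no saved draws")
  w <- colMeans(d)
  names(w) <- sub("^w_", "", names(w))
  w
}

#' Posterior model weights (distinct included-covariate sets)
#'
#' Each saved draw defines a "model": the set of covariates whose indicators
#' are 1 (coefficient values are ignored). The weight of a model is the
#' fraction of pooled draws carrying exactly that set. The table is sorted
#' by descending weight (ties broken lexicographically by the model key) and
#' carries cumulative weights; `head_cutoff` controls how many rows count as
#' the reported "best models" (smallest head reaching that cumulative
#' weight).
#'
#' @param fit An `mn_fit` run with `select = TRUE`.
#' @param head_cutoff Cumulative-weight cutoff for the reported head
#'   (default 0.5).
#' @return A data.frame of class `model_weight_table` with columns `model`
#'   (comma-separated sorted covariate names; `"(intercept only)"` for the
#'   empty set), `weight`, `cumulative`, `reported` (logical head flag).
#' @export
model_weights <- function(fit, head_cutoff = 0.5) {
  wcols <- grep("^w_", fit$param_names, value = TRUE)
  if (!length(wcols))
    stop("fit has no inclusion indicators (no candidate covariates)")
  d <- pooled_draws(fit, wcols)
  if (nrow(d) == 0L) stop("fit contains no saved draws")
  covs <- sub("^w_", "", wcols)
  keys <- apply(d == 1, 1L, function(r) {
    inc <- covs[r]
    if (!length(inc)) "(intercept only)" else paste(sort(inc), collapse = ", ")
  })
  tab <- table(keys)
  wt <- as.numeric(tab) / nrow(d)
  key <- names(tab)
  o <- order(-wt, key)
  wt <- wt[o]; key <- key[o]
  cum <- cumsum(wt)
  reported <- seq_along(wt) <= which(cum >= head_cutoff)[1L]
  out <- data.frame(model = key, weight = wt, cumulative = cum,
                    reported = reported, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("model_weight_table", "data.frame")
  attr(out, "head_cutoff") <- head_cutoff
  out
}

#' @export
print.model_weight_table <- function(x, ...) {
  cat("model weights (", sum(x$reported), " best model(s) reach cumulative ",
      attr(x, "head_cutoff"), "):\n", sep = "")
  print.data.frame(format(x, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Covariates deemed important by the inclusion-weight rule
#'
#' A covariate is important when its inclusion weight is at or above the
#' threshold (inclusive: a weight of exactly 0.50 qualifies at the default).
#'
#' @param weights Named weight vector from [variable_weights()], or an
#'   `mn_fit` (weights are computed first).
#' @param threshold Importance threshold (default 0.5).
#' @return Character vector of important covariate names (possibly empty).
#' @export
important_variables <- function(weights, threshold = 0.5) {
  if (inherits(weights, "mn_fit")) weights <- variable_weights(weights)
  names(weights)[weights >= threshold]
}

#' Write variable- and model-weight tables to CSV
#'
#' `variables` is a covariates x analyses table of inclusion weights with an
#' `important` flag column per analysis (weight >= threshold); `models` is
#' the best-models table per analysis, one block per analysis with
#' cumulative weights.
#'
#' @param fits Named list of `mn_fit` objects (names label the analyses).
#' @param dir Output directory (created if needed).
#' @param threshold Importance threshold for the flag columns.
#' @param head_cutoff Cumulative-weight cutoff for the model table heads.
#' @return Invisibly, list of the two data.frames written
#'   (`variable_weights.csv`, `model_weights.csv`).
#' @export
write_weight_tables <- function(fits, dir, threshold = 0.5,
                                head_cutoff = 0.5) {
  stopifnot(is.list(fits), length(fits) >= 1L, !is.null(names(fits)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vw <- lapply(fits, variable_weights)
  covs <- names(vw[[1L]])
  vtab <- data.frame(variable = covs, stringsAsFactors = FALSE)
  for (an in names(fits)) {
    vtab[[an]] <- as.numeric(vw[[an]][covs])
    vtab[[paste0(an, "_important")]] <- vw[[an]][covs] >= threshold
  }
  utils::write.csv(vtab, file.path(dir, "variable_weights.csv"),
                   row.names = FALSE)
  mtabs <- lapply(names(fits), function(an) {
    mt <- model_weights(fits[[an]], head_cutoff)
    cbind(analysis = an, mt[mt$reported, c("model", "weight", "cumulative")])
  })
  mtab <- do.call(rbind, mtabs)
  utils::write.csv(mtab, file.path(dir, "model_weights.csv"),
                   row.names = FALSE)
  invisible(list(variables = vtab, models = mtab))
}
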