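#' Refit the model with only the important covariates
#'
#' Reruns the full MCMC with the retained covariates always included
#' (indicators fixed to 1) and every other candidate removed from the
#' design. An empty set gives an intercept-only abundance model.
#'
#' @param data A `count_data` object.
#' @param abund_design The full `abundance_design` used for selection.
#' @param det_designs Named list of `detection_design` per method.
#' @param important Character vector of covariate names to retain (from
#'   [important_variables()]).
#' @param config A `sampler_config`.
#' @return An `mn_fit` from the reduced model.
#' @export
refit_reduced <- function(data, abund_design, det_designs, important,
                          config = sampler_config()) {
  red <- subset_design(abund_design, important)
  run_mcmc(data, red, det_designs, config, select = FALSE)
}

#' Posterior summary of local abundance for one analysis
#'
#' Per-site posterior median of the latent abundance draws (the lower median
#' of the pooled integer draws, so the summary is itself an integer) and the
#' relative local abundance obtained by dividing by the maximum median
#' across sites, scaling each analysis to `[0, 1]`.
#'
#' @param fit An `mn_fit` run with `save_N = TRUE`.
#' @param label Analysis label (e.g. `"combined"`).
#' @return A data.frame of class `abundance_summary` with columns `site`,
#'   `median_N`, `relative_abundance`, plus attribute `label`.
#' @export
abundance_summary <- function(fit, label = "analysis") {
  Nd <- pooled_N(fit)
  med <- apply(Nd, 2L, .lower_median)
  mx <- max(med)
  rel <- if (mx > 0) med / mx else rep(0, length(med))
  out <- data.frame(site = fit$site_ids, median_N = as.integer(med),
                    relative_abundance = rel, stringsAsFactors = FALSE)
  class(out) <- c("abundance_summary", "data.frame")
  attr(out, "label") <- label
  out
}

# lower median of an integer sample: reproducible without interpolation
.lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]

#' Pearson correlation between two analyses' abundance predictions
#'
#' @param a,b `abundance_summary` objects over the same sites in the same
#'   order.
#' @return Pearson correlation of the per-site posterior medians. Errors if
#'   either vector has zero variance (correlation undefined).
#' @export
prediction_correlation <- function(a, b) {
  if (nrow(a) != nrow(b) || !all(a$site == b$site))
    stop("summaries must cover the same sites in the same order")
  if (stats::sd(a$median_N) == 0 || stats::sd(b$median_N) == 0)
    stop("zero variance in a prediction vector: correlation undefined")
  stats::cor(a$median_N, b$median_N)
}

#' Classify per-site impact of adding the second detection method
#'
#' For each site, `d1 = combined - method-1-only` is the impact on relative
#' predicted abundance of adding method 2 to the method-1-only analysis, and
#' `d2 = combined - method-2-only` the impact of adding method 1. Sites
#' where the two additions moved the prediction in opposite directions get
#' the `opposite_*` categories; `no_change` when both moves are within
#' `tol`; everything else is `concordant`.
#'
#' @param rel_m1_only,rel_m2_only,rel_combined Aligned numeric vectors of
#'   relative abundance in `[0, 1]` (or `abundance_summary` objects).
#' @param tol No-change tolerance on the relative scale.
#' @return A data.frame with columns `d_add_method2`, `d_add_method1`,
#'   `category` (factor with levels `opposite_up_down`, `opposite_down_up`,
#'   `concordant`, `no_change`).
#' @export
classify_change <- function(rel_m1_only, rel_m2_only, rel_combined,
                            tol = 1e-6) {
  gv <- function(x) if (inherits(x, "abundance_summary"))
    x$relative_abundance else as.numeric(x)
  r1 <- gv(rel_m1_only); r2 <- gv(rel_m2_only); rc <- gv(rel_combined)
  if (length(r1) != length(r2) || length(r1) != length(rc))
    stop("inputs must have equal length")
  d1 <- rc - r1  # impact of adding method 2
  d2 <- rc - r2  # impact of adding method 1
  cat_ <- ifelse(abs(d1) < tol & abs(d2) < tol, "no_change",
          ifelse(d1 > 0 & d2 < 0, "opposite_up_down",
          ifelse(d1 < 0 & d2 > 0, "opposite_down_up", "concordant")))
  data.frame(d_add_method2 = d1, d_add_method1 = d2,
             category = factor(cat_, levels = c("opposite_up_down",
                                                "opposite_down_up",
                                                "concordant", "no_change")),
             stringsAsFactors = FALSE)
}

#' Run the three-analysis comparison workflow
#'
#' Repeats the full analysis three times on the same data: method 1 only
#' (all method-2 occasions masked), method 2 only, and both methods
#' combined. Each analysis runs indicator selection, extracts the important
#' covariates, refits with only those, and summarizes local abundance.
#' Only sites with sampling effort in both methods are retained; sites with
#' no effort in either method are dropped with a warning.
#'
#' @param data A `count_data` with both methods.
#' @param abund_design An `abundance_design` over the same sites.
#' @param det_designs Named list of `detection_design` per method.
#' @param config A `sampler_config`; each analysis stage derives its own
#'   seed offset from `config$seed` so stages are independent but the whole
#'   workflow is reproducible.
#' @param threshold Importance threshold for variable selection.
#' @return A list of class `three_analyses`: per analysis (named
#'   `method1_only`, `method2_only`, `combined`) the selection fit
#'   (`selection`), important set (`important`), reduced refit (`refit`) and
#'   `summary`; plus `sites_kept` and the pairwise prediction correlations
#'   (`correlations`).
#' @export
fit_three_analyses <- function(data, abund_design, det_designs,
                               config = sampler_config(), threshold = 0.5) {
  if (length(data$method_names) != 2L)
    stop("the three-analysis comparison needs exactly 2 methods")
  m1 <- data$method_names[1L]; m2 <- data$method_names[2L]
  effort <- lapply(data$counts, function(y) rowSums(!is.na(y)) > 0L)
  keep <- effort[[m1]] & effort[[m2]]
  none <- !(effort[[m1]] | effort[[m2]])
  if (any(none))
    warning(sum(none), " site(s) with no effort in either method dropped")
  if (!all(keep)) {
    message("retaining ", sum(keep), " of ", length(keep),
            " sites sampled with both methods")
    data <- subset_sites(data, keep)
    abund_design$x <- abund_design$x[keep, , drop = FALSE]
    det_designs <- lapply(det_designs, function(dd) {
      dd$v <- lapply(dd$v, function(z) z[keep, , drop = FALSE])
      dd$n_sites <- sum(keep)
      dd
    })
  }
  datasets <- list(
    method1_only = mask_method(data, m2),
    method2_only = mask_method(data, m1),
    combined = data)
  out <- vector("list", 3L)
  names(out) <- names(datasets)
  for (k in seq_along(datasets)) {
    cfg_sel <- config; cfg_sel$seed <- config$seed + 1000L * (k - 1L)
    cfg_ref <- config; cfg_ref$seed <- config$seed + 1000L * (k - 1L) + 500L
    sel <- run_mcmc(datasets[[k]], abund_design, det_designs, cfg_sel,
                    select = TRUE)
    imp <- important_variables(sel, threshold)
    ref <- refit_reduced(datasets[[k]], abund_design, det_designs, imp,
                         cfg_ref)
    out[[k]] <- list(selection = sel, important = imp, refit = ref,
                     summary = abundance_summary(ref, names(datasets)[k]))
  }
  cors <- c(
    m1_vs_m2 = prediction_correlation(out$method1_only$summary,
                                      out$method2_only$summary),
    m1_vs_combined = prediction_correlation(out$method1_only$summary,
                                            out$combined$summary),
    m2_vs_combined = prediction_correlation(out$method2_only$summary,
                                            out$combined$summary))
  structure(c(out, list(sites_kept = data$site_ids, correlations = cors,
                        method_names = c(m1, m2))),
            class = "three_analyses")
}

#' @export
print.three_analyses <- function(x, ...) {
  cat("three-analysis comparison over", length(x$sites_kept), "sites\n")
  for (an in c("method1_only", "method2_only", "combined"))
    cat(sprintf("  %-13s important: %s\n", an,
                if (length(x[[an]]$important))
                  paste(x[[an]]$important, collapse = ", ")
                else "(none)"))
  cat("  prediction correlations:",
      paste(sprintf("%s=%.2f", names(x$correlations), x$correlations),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write per-analysis predictions and the change-classification CSVs
#'
#' @param three A `three_analyses` object.
#' @param dir Output directory.
#' @param tol No-change tolerance for [classify_change()].
#' @return Invisibly, the comparison data.frame.
#' @export
write_comparison <- function(three, dir, tol = 1e-6) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (an in c("method1_only", "method2_only", "combined")) {
    s <- three[[an]]$summary
    utils::write.csv(s, file.path(dir, paste0("abundance_", an, ".csv")),
                     row.names = FALSE)
  }
  cls <- classify_change(three$method1_only$summary,
                         three$method2_only$summary,
                         three$combined$summary, tol = tol)
  cmp <- cbind(grid_cell = three$sites_kept, cls)
  utils::write.csv(cmp, file.path(dir, "prediction_changes.csv"),
                   row.names = FALSE)
  invisible(cmp)
}
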