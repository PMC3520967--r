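#' Read a multi-method count table
#'
#' Expects the capture-history layout: a `grid_cell` column followed by one
#' block of session columns per method, named `<method>_s1 .. <method>_sT`
#' (e.g. `hair_trap_s1..s4, bear_rub_s1..s5`). A blank cell means no
#' sampling effort for that site-session.
#'
#' @param path CSV file path.
#' @return A `count_data` object.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  if (!"grid_cell" %in% names(df))
    stop("count file must have a `grid_cell` column")
  if (nrow(df) == 0L) stop("no sites: count file has only headers")
  sess <- setdiff(names(df), "grid_cell")
  mm <- regmatches(sess, regexec("^(.*)_s([0-9]+)$", sess))
  bad <- vapply(mm, length, 1L) != 3L
  if (any(bad))
    stop("column(s) not in `<method>_s<t>` form: ",
         paste(sess[bad], collapse = ", "))
  meth <- vapply(mm, `[`, "", 2L)
  occ <- as.integer(vapply(mm, `[`, "", 3L))
  counts <- list()
  for (m in unique(meth)) {
    cols <- sess[meth == m]
    t_idx <- occ[meth == m]
    if (!setequal(t_idx, seq_len(max(t_idx))))
      stop("method '", m, "' sessions are not 1..T: ",
           paste(sort(t_idx), collapse = ","))
    y <- matrix(NA_integer_, nrow(df), max(t_idx))
    for (k in seq_along(cols)) {
      v <- trimws(df[[cols[k]]])
      v[v == ""] <- NA
      num <- suppressWarnings(as.numeric(v))
      bad_val <- which(!is.na(v) & (is.na(num) | num < 0 | num != round(num)))
      if (length(bad_val))
        stop("invalid count '", v[bad_val[1L]], "' at row ", bad_val[1L],
             ", column ", cols[k], " (need nonnegative integer or blank)")
      y[, t_idx[k]] <- as.integer(num)
    }
    counts[[m]] <- y
  }
  count_data(counts, site_ids = df$grid_cell)
}

#' Write a multi-method count table
#'
#' Inverse of [read_counts()]; masked (no-effort) cells are written blank.
#'
#' @param data A `count_data` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(data, path) {
  out <- data.frame(grid_cell = data$site_ids, stringsAsFactors = FALSE)
  for (m in data$method_names) {
    y <- data$counts[[m]]
    for (t in seq_len(ncol(y)))
      out[[paste0(m, "_s", t)]] <- y[, t]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a site-covariate table
#'
#' `grid_cell` column plus named covariate columns. Detection covariates
#' that vary by occasion use the `name_s<t>` column convention and are
#' returned as matrices.
#'
#' @param path CSV file path.
#' @return List with `site_ids` and `covariates` (named list: numeric
#'   vectors for session-constant covariates, sites x occasions matrices
#'   for `name_s<t>` blocks).
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"grid_cell" %in% names(df))
    stop("covariate file must have a `grid_cell` column")
  other <- setdiff(names(df), "grid_cell")
  mm <- regmatches(other, regexec("^(.*)_s([0-9]+)$", other))
  is_sess <- vapply(mm, length, 1L) == 3L
  covariates <- list()
  for (nm in other[!is_sess]) covariates[[nm]] <- as.numeric(df[[nm]])
  if (any(is_sess)) {
    base <- vapply(mm[is_sess], `[`, "", 2L)
    tt <- as.integer(vapply(mm[is_sess], `[`, "", 3L))
    cols <- other[is_sess]
    for (b in unique(base)) {
      sel <- base == b
      z <- matrix(NA_real_, nrow(df), max(tt[sel]))
      for (k in which(sel)) z[, tt[k]] <- as.numeric(df[[cols[k]]])
      covariates[[b]] <- z
    }
  }
  list(site_ids = df$grid_cell, covariates = covariates)
}

#' Write a site-covariate table
#'
#' @param site_ids Site labels.
#' @param covariates Named list of vectors (session-constant) and/or
#'   matrices (written as `name_s<t>` blocks).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(site_ids, covariates, path) {
  out <- data.frame(grid_cell = site_ids, stringsAsFactors = FALSE)
  for (nm in names(covariates)) {
    z <- covariates[[nm]]
    if (is.matrix(z)) {
      for (t in seq_len(ncol(z))) out[[paste0(nm, "_s", t)]] <- z[, t]
    } else out[[nm]] <- z
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export posterior draws to a rectangular samples file
#'
#' One row per saved draw: a `chain` column, a `draw` index, then one column
#' per parameter (coefficients and indicators), suitable for any
#' posterior-analysis tool.
#'
#' @param fit An `mn_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  rows <- lapply(seq_along(fit$chains), function(ch)
    data.frame(chain = ch, draw = seq_len(nrow(fit$chains[[ch]])),
               fit$chains[[ch]], check.names = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read exported posterior draws back into chain matrices
#' @param path CSV written by [write_draws()].
#' @return List of chain matrices (draws x parameters).
#' @export
read_draws <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  lapply(split(df, df$chain), function(d)
    as.matrix(d[, setdiff(names(d), c("chain", "draw")), drop = FALSE]))
}
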