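#' Read a run configuration file
#'
#' A single YAML file drives a whole analysis run: input paths, the sampler
#' block, an optional scenario block (for simulated runs), the analysis mode
#' and the selection thresholds. Missing fields fall back to the package
#' defaults.
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with elements `paths`, `sampler`
#'   (a `sampler_config`), `scenario` (a `scenario_config` or `NULL`),
#'   `mode`, `threshold`, `head_cutoff`, and `hash` (an md5 of the file
#'   contents, recorded in every output).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  modes <- c("method1_only", "method2_only", "combined", "all_three")
  mode <- raw$mode %||% "all_three"
  if (!mode %in% modes)
    stop("invalid mode '", mode, "'; must be one of: ",
         paste(modes, collapse = ", "))
  sampler <- do.call(sampler_config, raw$sampler %||% list())
  scenario <- if (!is.null(raw$scenario))
    do.call(scenario_config, .scenario_from_yaml(raw$scenario))
  structure(list(paths = raw$paths %||% list(),
                 sampler = sampler, scenario = scenario, mode = mode,
                 threshold = raw$threshold %||% 0.5,
                 head_cutoff = raw$head_cutoff %||% 0.5,
                 hash = unname(tools::md5sum(path))),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML represents vectors/matrices loosely; rebuild the typed pieces.
.scenario_from_yaml <- function(s) {
  if (!is.null(s$occasions)) s$occasions <- unlist(s$occasions)
  if (!is.null(s$det_p_target)) s$det_p_target <- unlist(s$det_p_target)
  if (!is.null(s$det_slopes))
    s$det_slopes <- lapply(s$det_slopes, unlist)
  if (!is.null(s$susceptibility))
    s$susceptibility <- do.call(rbind, lapply(s$susceptibility,
                                              function(r) as.numeric(unlist(r))))
  if (!is.null(s$beta)) s$beta <- as.numeric(unlist(s$beta))
  if (!is.null(s$beta_B)) s$beta_B <- as.numeric(unlist(s$beta_B))
  if (!is.null(s$rho) && length(s$rho) > 1L)
    s$rho <- do.call(rbind, s$rho)
  s
}

#' Write a scenario configuration to YAML
#'
#' Round-trips through [read_scenario_config()].
#'
#' @param config A `scenario_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  s <- unclass(config)
  s$method_names <- NULL
  s$occasions <- as.list(stats::setNames(as.integer(s$occasions),
                                         names(s$occasions)))
  s$det_p_target <- as.list(s$det_p_target)
  s$det_slopes <- lapply(s$det_slopes, as.list)
  s$susceptibility <- lapply(seq_len(nrow(s$susceptibility)),
                             function(r) as.list(unname(s$susceptibility[r, ])))
  if (is.matrix(s$rho)) s$rho <- apply(s$rho, 1L, as.list, simplify = FALSE)
  yaml::write_yaml(s, path, precision = 15L)
  invisible(path)
}

#' Read a scenario configuration from YAML
#' @param path YAML path written by [write_scenario_config()].
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  do.call(scenario_config, .scenario_from_yaml(yaml::read_yaml(path)))
}

#' Append a line to a run log
#'
#' Every pipeline stage logs its seed and the config hash so that any two
#' runs with equal hashes and seeds are identical.
#'
#' @param logfile Path to the run log (created if needed); `NULL` logs to
#'   stderr only.
#' @param ... Message parts, pasted together.
#' @return Invisibly, the logged line.
#' @export
log_line <- function(logfile, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ",
                 paste0(..., collapse = ""))
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}
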