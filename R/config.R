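## valid RunConfig keys and their sub-keys
.config_keys <- list(
  top = c("preset", "params", "schedule", "sim", "output", "features"),
  params = c("er", "ra_e", "ra_i", "rates"),
  schedule = c("f_onset", "d_total", "segment_duration", "fd_width"),
  sim = c("t0", "t_end", "dt", "init"),
  features = c("threshold_frac", "prominence"))

#' Construct a validated run configuration
#'
#' A run configuration names a preset (or supplies explicit parameter
#' tuples), optional drive-schedule and integration overrides, an output
#' path, and feature-extraction settings. Unknown keys and out-of-range
#' values are rejected. Configurations round-trip losslessly through YAML
#' (see [write_run_config()] / [read_run_config()]).
#'
#' @param preset pattern name, or `NULL` when `params` gives explicit
#'   tuples.
#' @param params optional list with `er` (length 3), `ra_e`, `ra_i`
#'   (length 5 each) and optionally `rates` (length 2: `r_er`, `r_ra`).
#' @param schedule optional list of [build_drives()] overrides.
#' @param sim optional list of integration overrides (`t0`, `t_end`, `dt`,
#'   `init`).
#' @param output optional output CSV path.
#' @param features optional list (`threshold_frac`, `prominence`).
#' @return an object of class `run_config`.
#' @export
run_config <- function(preset = NULL, params = NULL, schedule = NULL,
                       sim = NULL, output = NULL, features = NULL) {
  cfg <- list(preset = preset, params = params, schedule = schedule,
              sim = sim, output = output, features = features)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Validate a run-configuration list
#'
#' @param cfg a named list (as parsed from YAML).
#' @return the list, invisibly; errors on unknown keys or invalid values.
#' @export
validate_run_config <- function(cfg) {
  bad <- setdiff(names(cfg), .config_keys$top)
  if (length(bad)) stop("unknown config keys: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(cfg$preset) && is.null(cfg$params)) {
    stop("config needs a preset name or explicit params", call. = FALSE)
  }
  if (!is.null(cfg$preset) &&
      !cfg$preset %in% c("P0", "pulsatile", "P2", "P1")) {
    stop("unknown preset: ", cfg$preset, call. = FALSE)
  }
  for (blk in c("params", "schedule", "sim", "features")) {
    if (!is.null(cfg[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), .config_keys[[blk]])
      if (length(bad)) stop("unknown ", blk, " keys: ",
                            paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(cfg$params)) {
    p <- cfg$params
    if (is.null(p$er) || length(p$er) != 3) {
      stop("params$er must have length 3", call. = FALSE)
    }
    for (nm in c("ra_e", "ra_i")) {
      if (is.null(p[[nm]]) || length(p[[nm]]) != 5) {
        stop("params$", nm, " must have length 5", call. = FALSE)
      }
    }
    if (!is.null(p$rates) && (length(p$rates) != 2 || any(p$rates <= 0))) {
      stop("params$rates must be two positive rate constants", call. = FALSE)
    }
  }
  if (!is.null(cfg$sim$dt) && cfg$sim$dt <= 0) {
    stop("sim$dt must be > 0", call. = FALSE)
  }
  if (!is.null(cfg$schedule$d_total) && cfg$schedule$d_total < 0) {
    stop("schedule$d_total must be >= 0", call. = FALSE)
  }
  if (!is.null(cfg$schedule$segment_duration) &&
      cfg$schedule$segment_duration <= 0) {
    stop("schedule$segment_duration must be > 0", call. = FALSE)
  }
  if (!is.null(cfg$schedule$fd_width) && cfg$schedule$fd_width <= 0) {
    stop("schedule$fd_width must be > 0", call. = FALSE)
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Execute a run configuration
#'
#' Resolves the configuration into parameters, drives and integration
#' settings, runs the simulation, optionally writes the trajectory CSV, and
#' returns the trajectory.
#'
#' @param cfg a `run_config` (or a path to a YAML config).
#' @return a `song_trajectory`, invisibly when an output path was written.
#' @export
run_from_config <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$params)) {
    p <- cfg$params
    rates <- if (is.null(p$rates)) rate_constants() else
      rate_constants(r_er = p$rates[[1]], r_ra = p$rates[[2]])
    params <- model_params(
      er_coupling(p$er[[1]], p$er[[2]], p$er[[3]]),
      ra_coupling(p$ra_e[[1]], p$ra_e[[2]], p$ra_e[[3]], p$ra_e[[4]],
                  p$ra_e[[5]],
                  p$ra_i[[1]], p$ra_i[[2]], p$ra_i[[3]], p$ra_i[[4]],
                  p$ra_i[[5]]),
      rates)
    preset <- get_preset(cfg$preset %||% "P0")
    preset$params <- params
  } else {
    preset <- get_preset(cfg$preset)
  }
  ov <- c(cfg$schedule, cfg$sim)
  tr <- do.call(run_pattern, c(list(preset), ov))
  if (!is.null(cfg$output)) {
    write_trajectory(tr, cfg$output)
    return(invisible(tr))
  }
  tr
}
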