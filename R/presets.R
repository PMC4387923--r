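## Published parameter tuples. ER triples are (alpha_eer_F, alpha_eer_ra,
## alpha_ier_ra); RA quintuples are (rho, a_Fd, a_Fd2, a_ra, b_ra) for the
## excitatory and inhibitory population respectively.
.preset_table <- list(
  P0 = list(er = c(1, 10, 0),
            ra_e = c(-3, 5, 0, 6, -3),
            ra_i = c(-6, 0.05, 0, 6, 6),
            t_end = 600),
  pulsatile = list(er = c(0.25, 10, 6),
                   ra_e = c(-5.25, 15, 0, 10, -10),
                   ra_i = c(-12, 0, 25, 10, 2),
                   t_end = 800),
  P2 = list(er = c(1, 10, 0),
            ra_e = c(-7, 2, 0, 3.5, -5),
            ra_i = c(-4.5, 0.05, 0, 16, 6),
            t_end = 600),
  P1 = list(er = c(0.25, 4.65, 4.5),
            ra_e = c(-5.25, 35, 0, 10, -10),
            ra_i = c(-12, 0, 25, 10, 2),
            t_end = 800))

#' Pattern preset registry
#'
#' Returns the published parameter set and default drive schedule and
#' integration settings for one of the four canary pressure patterns.
#'
#' @param name one of `"P0"`, `"pulsatile"`, `"P2"`, `"P1"`.
#' @param rates a [rate_constants()] (the rate parse is not part of the
#'   printed tuples; see the methods vignette).
#' @return an object of class `pattern_preset` with fields `name`, `params`
#'   (a [model_params()]), `schedule` (arguments for [build_drives()]) and
#'   `sim` (`t0`, `t_end`, `dt`, `init`).
#' @export
get_preset <- function(name = c("P0", "pulsatile", "P2", "P1"),
                       rates = rate_constants()) {
  name <- match.arg(name)
  p <- .preset_table[[name]]
  params <- model_params(
    er = er_coupling(p$er[1], p$er[2], p$er[3]),
    ra = ra_coupling(p$ra_e[1], p$ra_e[2], p$ra_e[3], p$ra_e[4], p$ra_e[5],
                     p$ra_i[1], p$ra_i[2], p$ra_i[3], p$ra_i[4], p$ra_i[5]),
    rates = rates)
  structure(list(name = name, params = params,
                 schedule = list(pattern = name, f_onset = 0,
                                 d_total = NULL, segment_duration = 300),
                 sim = list(t0 = 0, t_end = p$t_end, dt = 0.05,
                            init = "rest")),
            class = "pattern_preset")
}

#' @export
print.pattern_preset <- function(x, ...) {
  cat(sprintf("Pattern preset \"%s\" (t = [%g, %g] ms, dt = %g ms, init = %s)\n",
              x$name, x$sim$t0, x$sim$t_end, x$sim$dt,
              if (is.character(x$sim$init)) x$sim$init else "numeric"))
  print(x$params)
  invisible(x)
}

#' Run a pattern preset
#'
#' Builds the drive schedule, resolves the initial condition and integrates.
#' Schedule and integration settings can be overridden through `...`
#' (`f_onset`, `d_total`, `segment_duration`, `fd_width`, `t0`, `t_end`,
#' `dt`, `init`), and the drives can be replaced wholesale via `drives`
#' (used by the cooling experiment).
#'
#' @param preset a [get_preset()] object or a pattern name.
#' @param drives optional [drive_set()] overriding the built schedule.
#' @param ... schedule / integration overrides, see above.
#' @return a `song_trajectory` tagged with the preset name.
#' @export
run_pattern <- function(preset, drives = NULL, ...) {
  if (is.character(preset)) preset <- get_preset(preset)
  stopifnot(inherits(preset, "pattern_preset"))
  ov <- list(...)
  bad <- setdiff(names(ov), c("f_onset", "d_total", "segment_duration",
                              "fd_width", "t0", "t_end", "dt", "init"))
  if (length(bad)) stop("unknown overrides: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  sch <- utils::modifyList(preset$schedule,
                           ov[intersect(names(ov),
                                        c("f_onset", "d_total",
                                          "segment_duration", "fd_width"))])
  sim <- utils::modifyList(preset$sim,
                           ov[intersect(names(ov),
                                        c("t0", "t_end", "dt", "init"))])
  if (is.null(drives)) {
    drives <- do.call(build_drives, c(list(pattern = sch$pattern),
                                      sch[setdiff(names(sch), "pattern")]))
  }
  tr <- integrate_model(preset$params, drives, t0 = sim$t0,
                        t_end = sim$t_end, dt = sim$dt, init = sim$init)
  tr$preset <- preset$name
  tr
}

#' Simulate the HVC-cooling experiment on the P0 pattern
#'
#' Runs the P0 preset twice with the same parameters and initial condition:
#' once with the normal drive schedule and once with the HVC-derived pulses
#' stretched by `stretch` ms and (when `mode = "both"`) delayed by
#' `extra_delay` ms. The initiating-area pulse is identical in both runs.
#' With both effects at the published magnitudes (15 ms, 5 ms) the long P0
#' gesture stretches and breaks into two pressure pulses: the decaying
#' directly-driven pulse and the delayed telencephalon-driven pulse separate
#' as the interior minimum drops through the phonation threshold. Burst
#' stretching alone stretches the pattern without breaking it.
#'
#' @param stretch burst-width increase, ms. Default 15.
#' @param extra_delay burst-onset delay, ms. Default 5.
#' @param mode `"both"` or `"stretch_only"`.
#' @param preset preset to perturb (default P0, as in the cooling study).
#' @param ... overrides passed to [run_pattern()] for both runs.
#' @return a list of class `cooling_experiment` with elements `normal` and
#'   `cooled` (two `song_trajectory` objects) and the perturbation settings.
#' @export
run_cooling_experiment <- function(stretch = 15, extra_delay = 5,
                                   mode = c("both", "stretch_only"),
                                   preset = "P0", ...) {
  mode <- match.arg(mode)
  if (stretch < 0 || extra_delay < 0) {
    stop("stretch and extra_delay must be >= 0", call. = FALSE)
  }
  if (is.character(preset)) preset <- get_preset(preset)
  ov <- list(...)
  sch <- utils::modifyList(preset$schedule,
                           ov[intersect(names(ov),
                                        c("f_onset", "d_total",
                                          "segment_duration", "fd_width"))])
  drv <- do.call(build_drives, c(list(pattern = sch$pattern),
                                 sch[setdiff(names(sch), "pattern")]))
  normal <- do.call(run_pattern, c(list(preset, drives = drv), ov))
  cooled <- do.call(run_pattern,
                    c(list(preset,
                           drives = apply_cooling(drv, stretch, extra_delay,
                                                  mode)), ov))
  structure(list(normal = normal, cooled = cooled, stretch = stretch,
                 extra_delay = extra_delay, mode = mode),
            class = "cooling_experiment")
}

#' @export
print.cooling_experiment <- function(x, ...) {
  cat(sprintf("HVC cooling experiment (stretch %g ms, delay %g ms, mode %s)\n",
              x$stretch, x$extra_delay, x$mode))
  for (nm in c("normal", "cooled")) {
    tr <- x[[nm]]
    y <- tr$states[, "e_er"]
    thr <- 0.1 * max(y)
    seg <- segment_pulses(y, tr$times, thr)
    cat(sprintf("  %-7s %d pressure pulse(s) above 10%% of max, total %.1f ms\n",
                paste0(nm, ":"), nrow(seg), sum(seg$end - seg$start)))
  }
  invisible(x)
}
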