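#' Square-pulse drive element
#'
#' Bursts of spikes in the initiating area and in HVC are represented as
#' square functions: value `amplitude` on the half-open interval
#' `[onset, onset + width)` and 0 elsewhere. The half-open convention avoids
#' double counting where two pulses share a boundary.
#'
#' @param onset pulse onset, ms.
#' @param width pulse duration, ms; must be > 0.
#' @param amplitude pulse height (arbitrary drive units, default 10).
#' @return an object of class `square_pulse`.
#' @export
square_pulse <- function(onset, width, amplitude = 10) {
  stopifnot(is.numeric(onset), is.numeric(width), is.numeric(amplitude),
            length(onset) == 1, length(width) == 1, length(amplitude) == 1,
            is.finite(onset), is.finite(width), is.finite(amplitude))
  if (width <= 0) stop("pulse width must be > 0", call. = FALSE)
  if (amplitude < 0) stop("pulse amplitude must be >= 0", call. = FALSE)
  structure(list(onset = onset, width = width, amplitude = amplitude),
            class = "square_pulse")
}

## normalize one signal: accept a square_pulse, a list of square_pulses, or
## NULL/empty; sort by onset; reject overlap.
.as_signal <- function(x, name = "signal") {
  if (is.null(x)) return(list())
  if (inherits(x, "square_pulse")) x <- list(x)
  if (!is.list(x) || !all(vapply(x, inherits, logical(1), "square_pulse"))) {
    stop(name, " must be a square_pulse or a list of square_pulse objects",
         call. = FALSE)
  }
  if (length(x) == 0) return(x)
  x <- x[order(vapply(x, `[[`, numeric(1), "onset"))]
  if (length(x) > 1) {
    on <- vapply(x, `[[`, numeric(1), "onset")
    off <- on + vapply(x, `[[`, numeric(1), "width")
    if (any(on[-1] < off[-length(off)])) {
      stop("overlapping pulses in ", name, call. = FALSE)
    }
  }
  x
}

#' The three drive signals of the model
#'
#' `F` is the initiating-area burst (direct input to `e_er`); `Fd` and `Fd2`
#' are the HVC bursts reaching RA after thalamic/telencephalic processing.
#' Pulses within one signal must not overlap.
#'
#' @param F,Fd,Fd2 each a [square_pulse()], a list of them, or `NULL`.
#' @return an object of class `drive_set`.
#' @export
drive_set <- function(F = NULL, Fd = NULL, Fd2 = NULL) {
  structure(list(F = .as_signal(F, "F"), Fd = .as_signal(Fd, "Fd"),
                 Fd2 = .as_signal(Fd2, "Fd2")), class = "drive_set")
}

#' Evaluate a drive signal at given times
#'
#' Returns the sum of amplitudes of pulses whose half-open support
#' `[onset, onset + width)` contains `t` (at most one, since pulses do not
#' overlap). With `side = "left"` the support is treated as
#' `(onset, onset + width]`, i.e. the left limit of the signal; the
#' integrator uses this for the final Runge-Kutta stage so that a
#' piecewise-constant drive is constant within a step whenever its edges lie
#' on the time grid.
#'
#' @param signal a list of [square_pulse()] objects (one component of a
#'   [drive_set()]), or a `drive_set` from which all three signals are
#'   evaluated (returning a matrix).
#' @param t numeric vector of times, ms.
#' @param side `"right"` (default, right-continuous) or `"left"`.
#' @return numeric vector of drive values (or an `length(t) x 3` matrix when
#'   `signal` is a `drive_set`).
#' @export
evaluate_drive <- function(signal, t, side = c("right", "left")) {
  side <- match.arg(side)
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("t must be finite numeric", call. = FALSE)
  }
  if (inherits(signal, "drive_set")) {
    return(cbind(F = evaluate_drive(signal$F, t, side),
                 Fd = evaluate_drive(signal$Fd, t, side),
                 Fd2 = evaluate_drive(signal$Fd2, t, side)))
  }
  signal <- .as_signal(signal)
  v <- numeric(length(t))
  for (p in signal) {
    inside <- if (side == "right") {
      t >= p$onset & t < p$onset + p$width
    } else {
      t > p$onset & t <= p$onset + p$width
    }
    v[inside] <- v[inside] + p$amplitude
  }
  v
}

#' Build the drive schedule of a named pressure pattern
#'
#' Constructs the `F`, `Fd`, `Fd2` pulse trains for one of the four pattern
#' presets. Published widths: F lasts 20 ms (P0, P2), 50 ms (pulsatile),
#' 40 ms (P1); Fd lasts 10 ms (P0), 140 ms (P1); Fd2 lasts 100 ms (P1); the
#' P2 telencephalic input arrives 22 ms after the IA pulse. Unstated widths
#' default to 20 ms (pulsatile Fd and Fd2) and 10 ms (P2 Fd). All amplitudes
#' are 10.
#'
#' `d_total` is the lumped delay from IA burst onset to the arrival of the
#' processed copy at RA (thalamic leg plus the 10 ms HVC-to-RA leg). It
#' defaults to 26 ms except for P2, whose published total is 22 ms.
#' `segment_duration` separates the onsets of `Fd` and `Fd2` (pulsatile and
#' P1); it is the duration of the pulsating segment.
#'
#' @param pattern one of `"P0"`, `"pulsatile"`, `"P2"`, `"P1"`.
#' @param f_onset onset of the IA pulse, ms (everything translates with it).
#' @param d_total lumped IA-to-RA-input delay, ms; `NULL` for the
#'   per-pattern default.
#' @param segment_duration pulsating-segment duration, ms.
#' @param amplitude pulse height.
#' @param fd_width override for the Fd width, ms; `NULL` for the default.
#' @return a [drive_set()].
#' @export
build_drives <- function(pattern = c("P0", "pulsatile", "P2", "P1"),
                         f_onset = 0, d_total = NULL,
                         segment_duration = 300, amplitude = 10,
                         fd_width = NULL) {
  pattern <- match.arg(pattern)
  if (is.null(d_total)) d_total <- if (pattern == "P2") 22 else 26
  if (!is.numeric(d_total) || d_total < 0) {
    stop("d_total must be a non-negative delay in ms", call. = FALSE)
  }
  if (segment_duration <= 0) {
    stop("segment_duration must be > 0", call. = FALSE)
  }
  sp <- function(on, w) square_pulse(on, w, amplitude)
  fd_on <- f_onset + d_total
  switch(pattern,
    P0 = drive_set(F = sp(f_onset, 20),
                   Fd = sp(fd_on, fd_width %||% 10)),
    P2 = drive_set(F = sp(f_onset, 20),
                   Fd = sp(fd_on, fd_width %||% 10)),
    pulsatile = drive_set(F = sp(f_onset, 50),
                          Fd = sp(fd_on, fd_width %||% 20),
                          Fd2 = sp(fd_on + segment_duration, 20)),
    P1 = drive_set(F = sp(f_onset, 40),
                   Fd = sp(fd_on, fd_width %||% 140),
                   Fd2 = sp(fd_on + segment_duration, 100)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the HVC-cooling transformation to a drive schedule
#'
#' Cooling HVC slows its internal dynamics (stretching its bursts) and slows
#' the recurrent Uva-to-HVC input (delaying burst onset). Both effects act on
#' the HVC-derived signals `Fd` and `Fd2` only; the initiating-area signal
#' `F` is returned unchanged. With `mode = "stretch_only"` only the widths
#' grow; with `mode = "both"` onsets are additionally delayed.
#'
#' @param drives a [drive_set()].
#' @param stretch burst-width increase, ms (>= 0). Default 15.
#' @param extra_delay burst-onset delay, ms (>= 0). Default 5.
#' @param mode `"both"` or `"stretch_only"`.
#' @return a new [drive_set()].
#' @export
apply_cooling <- function(drives, stretch = 15, extra_delay = 5,
                          mode = c("both", "stretch_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(drives, "drive_set"))
  if (stretch < 0 || extra_delay < 0) {
    stop("stretch and extra_delay must be >= 0", call. = FALSE)
  }
  shift <- if (mode == "both") extra_delay else 0
  cool1 <- function(p) square_pulse(p$onset + shift, p$width + stretch,
                                    p$amplitude)
  drive_set(F = drives$F,
            Fd = lapply(drives$Fd, cool1),
            Fd2 = lapply(drives$Fd2, cool1))
}

#' @export
print.drive_set <- function(x, ...) {
  show <- function(sig, nm) {
    if (length(sig) == 0) {
      cat(sprintf("  %-4s (none)\n", paste0(nm, ":")))
    } else {
      cat(sprintf("  %-4s %s\n", paste0(nm, ":"),
                  paste(vapply(sig, function(p)
                    sprintf("[%g, %g) x %g", p$onset, p$onset + p$width,
                            p$amplitude), character(1)), collapse = ", ")))
    }
  }
  cat("Drive set (square pulses, ms):\n")
  show(x$F, "F"); show(x$Fd, "Fd"); show(x$Fd2, "Fd2")
  invisible(x)
}
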