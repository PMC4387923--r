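#' Integrate the model with classical fixed-step RK4
#'
#' Deterministic 4th-order Runge-Kutta on a uniform grid. The square-pulse
#' drives are sampled at the stage times; the final stage (at `t + dt`)
#' samples the left limit of the drives, so that a piecewise-constant drive
#' is constant within each step whenever its edges lie on the grid, and the
#' scheme keeps its full order there (see the methods vignette). Identical
#' inputs produce bit-identical trajectories: there is no randomness
#' anywhere in the simulator.
#'
#' @param params a [model_params()].
#' @param drives a [drive_set()].
#' @param t0,t_end integration window, ms (`t_end > t0`).
#' @param dt step, ms, in (0, 1].
#' @param init initial state: `"rest"` (default; the resting state obtained
#'   by integrating `rest_duration` ms with zero drives from the origin),
#'   `"origin"` (all four activities 0), or a numeric vector of length 4.
#' @param rest_duration length of the zero-drive settling run used by
#'   `init = "rest"`, ms.
#' @return an object of class `song_trajectory`: a list with `times` (length
#'   n), `states` (n x 4 matrix), `drives` (n x 3 matrix of drive values at
#'   the grid times), and metadata (`params`, `drive_set`, `dt`, `preset`).
#' @export
integrate_model <- function(params, drives, t0 = 0, t_end, dt = 0.05,
                            init = "rest", rest_duration = 500) {
  stopifnot(inherits(params, "model_params"), inherits(drives, "drive_set"))
  if (!is.numeric(dt) || dt <= 0 || dt > 1) stop("dt must be in (0, 1] ms",
                                                 call. = FALSE)
  if (t_end <= t0) stop("t_end must exceed t0", call. = FALSE)
  x0 <- .resolve_init(init, params, dt, rest_duration)
  m <- .param_matrices(params)
  n <- as.integer(round((t_end - t0) / dt))
  times <- t0 + (0:n) * dt
  ## pre-sample drives at stage times; last stage uses the left limit
  D1 <- evaluate_drive(drives, times[1:n])
  Dm <- evaluate_drive(drives, times[1:n] + dt / 2)
  D4 <- evaluate_drive(drives, times[2:(n + 1)], side = "left")
  U1 <- D1 %*% t(m$B); Um <- Dm %*% t(m$B); U4 <- D4 %*% t(m$B)
  W <- m$W; rho <- m$rho; r <- m$r
  X <- matrix(NA_real_, n + 1, 4)
  X[1, ] <- x0
  x <- x0
  h <- dt
  for (k in seq_len(n)) {
    u1 <- U1[k, ]; um <- Um[k, ]; u4 <- U4[k, ]
    k1 <- r * (-x + .sig(as.numeric(W %*% x) + rho + u1))
    x2 <- x + (h / 2) * k1
    k2 <- r * (-x2 + .sig(as.numeric(W %*% x2) + rho + um))
    x3 <- x + (h / 2) * k2
    k3 <- r * (-x3 + .sig(as.numeric(W %*% x3) + rho + um))
    x4 <- x + h * k3
    k4 <- r * (-x4 + .sig(as.numeric(W %*% x4) + rho + u4))
    x <- x + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(x))) {
      stop(sprintf("integration produced a non-finite state at t = %g ms",
                   times[k + 1]), call. = FALSE)
    }
    X[k + 1, ] <- x
  }
  colnames(X) <- c("e_er", "i_er", "e_ra", "i_ra")
  structure(list(times = times, states = X,
                 drives = evaluate_drive(drives, times),
                 params = params, drive_set = drives, dt = dt,
                 init = x0, preset = NA_character_),
            class = "song_trajectory")
}

.resolve_init <- function(init, params, dt, rest_duration) {
  if (is.numeric(init)) {
    if (length(init) != 4 || any(!is.finite(init))) {
      stop("numeric init must be 4 finite values", call. = FALSE)
    }
    return(as.numeric(init))
  }
  if (identical(init, "origin")) return(c(0, 0, 0, 0))
  if (identical(init, "rest")) {
    tr <- integrate_model(params, drive_set(), 0, rest_duration, dt = 0.1,
                          init = "origin")
    return(as.numeric(tr$states[nrow(tr$states), ]))
  }
  stop("init must be \"rest\", \"origin\", or a numeric vector of length 4",
       call. = FALSE)
}

#' @export
print.song_trajectory <- function(x, ...) {
  cat(sprintf("song_trajectory%s: %d points, t = [%g, %g] ms, dt = %g ms\n",
              if (is.na(x$preset)) "" else sprintf(" (preset %s)", x$preset),
              length(x$times), x$times[1], x$times[length(x$times)], x$dt))
  rng <- apply(x$states, 2, range)
  for (j in colnames(x$states)) {
    cat(sprintf("  %-5s in [%.4f, %.4f]\n", j, rng[1, j], rng[2, j]))
  }
  invisible(x)
}

#' @export
as.data.frame.song_trajectory <- function(x, ...) {
  data.frame(t_ms = x$times, x$states, x$drives, check.names = FALSE)
}

#' Plot a simulated trajectory
#'
#' Stacked traces of the four activities with the three drive signals
#' (scaled to unit height) in the top panel, in the spirit of the published
#' figure layout: drives, RA activity, ER activity (the pressure pattern).
#'
#' @param x a `song_trajectory`.
#' @param ... passed to [graphics::matplot()] for the state panel.
#' @export
plot.song_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  amp <- max(x$drives, 1)
  graphics::matplot(x$times, x$drives / amp, type = "l", lty = 1,
                    col = c("blue", "darkgreen", "purple"),
                    ylab = "drives", xlab = "")
  graphics::legend("topright", c("F (IA)", "Fd (HVC)", "Fd2 (HVC)"),
                   col = c("blue", "darkgreen", "purple"), lty = 1, bty = "n")
  graphics::matplot(x$times, x$states[, c("e_ra", "i_ra")], type = "l",
                    lty = 1, col = c("red", "orange"), ylab = "RA", xlab = "")
  graphics::matplot(x$times, x$states[, c("e_er", "i_er")], type = "l",
                    lty = 1, col = c("black", "grey50"),
                    ylab = "ER (pressure)", xlab = "time (ms)", ...)
  invisible(x)
}

#' @export
summary.song_trajectory <- function(object, ...) {
  extract_features(object, ...)
}
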