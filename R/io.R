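#' Write a trajectory to delimited text
#'
#' CSV with header `t_ms,e_er,i_er,e_ra,i_ra,F,Fd,Fd2`, one row per time
#' point at full double precision, preceded by a commented (`#`) metadata
#' block recording the preset name, the step, and the parameter values.
#'
#' @param trajectory a `song_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "song_trajectory"))
  p <- trajectory$params
  meta <- c(
    sprintf("# songcircuit trajectory"),
    sprintf("# preset: %s", trajectory$preset),
    sprintf("# dt_ms: %.17g", trajectory$dt),
    sprintf("# rates: r_er=%.17g r_ra=%.17g", p$rates$r_er, p$rates$r_ra),
    sprintf("# er: %s", paste(sprintf("%s=%.17g", names(p$er),
                                      unlist(p$er)), collapse = " ")),
    sprintf("# ra: %s", paste(sprintf("%s=%.17g", names(p$ra),
                                      unlist(p$ra)), collapse = " ")))
  m <- cbind(t_ms = trajectory$times, trajectory$states, trajectory$drives)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(colnames(m), collapse = ","), con)
  if (nrow(m) > 0) {
    body <- apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                          collapse = ","))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV file path.
#' @return a data frame with columns `t_ms, e_er, i_er, e_ra, i_ra, F, Fd,
#'   Fd2` (metadata comments are skipped).
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", colClasses = "numeric")
}

#' Read a recorded pressure time series
#'
#' Reads a delimited text file with numeric time and value columns (such as
#' exported air-sac pressure recordings), returning a uniformly sampled
#' trace. A non-uniform time grid is linearly resampled to its median step;
#' the amplitude can be min-max normalised to `[0, 1]` (recorded pressure
#' units are arbitrary, the model's activities are dimensionless).
#'
#' @param path delimited text file.
#' @param time_column,value_column column names.
#' @param normalize min-max normalise the values to `[0, 1]`?
#' @param sep field separator (default `","`).
#' @return a data frame with columns `time` and `value` on a uniform grid.
#' @export
read_pressure_series <- function(path, time_column = "t_ms",
                                 value_column = "value", normalize = FALSE,
                                 sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#")
  for (col in c(time_column, value_column)) {
    if (!col %in% names(d)) {
      stop("column not found in ", path, ": ", col, call. = FALSE)
    }
  }
  tt <- d[[time_column]]; y <- d[[value_column]]
  if (!is.numeric(tt) || !is.numeric(y) || anyNA(tt) || anyNA(y)) {
    stop("non-numeric cells in time or value column", call. = FALSE)
  }
  if (length(tt) < 3) stop("need at least 3 rows", call. = FALSE)
  o <- order(tt); tt <- tt[o]; y <- y[o]
  steps <- diff(tt)
  if (any(steps <= 0)) stop("duplicated time points", call. = FALSE)
  h <- stats::median(steps)
  if (max(abs(steps - h)) > 1e-9 * max(h, 1)) {
    grid <- seq(tt[1], tt[length(tt)], by = h)
    y <- stats::approx(tt, y, xout = grid)$y
    tt <- grid
  }
  if (normalize) {
    rng <- range(y)
    y <- if (diff(rng) > 0) (y - rng[1]) / diff(rng) else y * 0
  }
  data.frame(time = tt, value = y)
}

#' Deterministic analytic test traces
#'
#' Generates traces with exactly known extrema and periods, for exercising
#' the feature operators:
#'
#' * `"sine"`: `offset + amplitude * sin(2 pi t / period)`.
#' * `"bump_pair"`: two identical raised-cosine arches of height `peak`
#'   standing on a floor at `valley`; exactly two maxima (`peak`) with one
#'   interior minimum (`valley`) between them.
#' * `"decaying_train"`: raised-cosine arches of period `period` under an
#'   exponential envelope `exp(-t / tau)`; successive maxima decay.
#'
#' Optional Gaussian jitter takes an explicit seed (restored afterwards via
#' a local RNG state), so fixtures stay reproducible.
#'
#' @param kind one of `"sine"`, `"bump_pair"`, `"decaying_train"`.
#' @param n number of samples (>= 3).
#' @param dt sample step, ms.
#' @param period oscillation period, ms (sine, decaying_train).
#' @param amplitude,offset sine parameters.
#' @param peak,valley bump-pair levels.
#' @param tau envelope time constant, ms (decaying_train).
#' @param jitter_sd standard deviation of additive noise (default 0: none).
#' @param seed RNG seed, required when `jitter_sd > 0`.
#' @return a data frame with columns `time` and `value`.
#' @export
generate_fixture <- function(kind = c("sine", "bump_pair", "decaying_train"),
                             n = 1000, dt = 0.1, period = 20,
                             amplitude = 1, offset = 0,
                             peak = 1, valley = 0.3, tau = 50,
                             jitter_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  tt <- (seq_len(n) - 1) * dt
  y <- switch(kind,
    sine = offset + amplitude * sin(2 * pi * tt / period),
    ## y = valley + (peak - valley) sin(pi t / L)^2 with L = span / 2:
    ## maxima exactly `peak` at t = L/2 and 3L/2, one interior minimum
    ## exactly `valley` at t = L
    bump_pair = valley + (peak - valley) * sin(pi * tt / (tt[n] / 2))^2,
    decaying_train = exp(-tt / tau) * 0.5 * (1 - cos(2 * pi * tt / period)))
  if (jitter_sd > 0) {
    if (is.null(seed)) stop("jitter requires an explicit seed",
                            call. = FALSE)
    y <- y + withr_local_rnorm(n, jitter_sd, seed)
  }
  data.frame(time = tt, value = y)
}

## deterministic noise without touching the global RNG stream
withr_local_rnorm <- function(n, sd, seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::rnorm(n, 0, sd)
}
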