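## ---- extrema ---------------------------------------------------------------

## indices of strict local maxima, with flat plateaus collapsed to their
## (rounded) midpoint; endpoints excluded.
.raw_maxima <- function(y) {
  n <- length(y)
  d <- diff(y)
  s <- sign(d)
  ## carry the last non-zero slope through flat runs
  for (k in seq_along(s)) if (s[k] == 0 && k > 1) s[k] <- s[k - 1]
  idx <- which(diff(s) < 0) + 1
  idx[idx > 1 & idx < n]
}

## topographic prominence of maxima at indices idx: height above the higher
## of the two key saddles (the minima separating the peak from the nearest
## higher terrain on each side, or from the series end).
.prominence <- function(y, idx) {
  vapply(idx, function(i) {
    hi_l <- which(y[seq_len(i - 1)] > y[i])
    lo <- if (length(hi_l)) max(hi_l) else 1
    left_base <- min(y[lo:i])
    hi_r <- which(y[(i + 1):length(y)] > y[i])
    hi <- if (length(hi_r)) i + min(hi_r) else length(y)
    right_base <- min(y[i:hi])
    y[i] - max(left_base, right_base)
  }, numeric(1))
}

#' Local extrema by topographic prominence
#'
#' Finds local maxima and minima of a uniformly sampled trace whose
#' prominence (height above the higher of the two flanking key saddles, or
#' the mirror-image quantity for minima) exceeds a threshold. Endpoints are
#' excluded. The returned extrema alternate in kind along time: where
#' prominence filtering leaves two maxima (minima) adjacent, the deepest
#' minimum (highest maximum) between them is restored.
#'
#' @param values numeric trace, at least 3 samples.
#' @param times optional sample times (defaults to the sample index).
#' @param prominence prominence threshold, activity units, > 0.
#' @return data frame with columns `time`, `value`, `kind`
#'   (`"max"`/`"min"`), and `index`.
#' @export
find_local_extrema <- function(values, times = NULL, prominence = 0.02) {
  if (!is.numeric(values) || length(values) < 3) {
    stop("series must have at least 3 samples", call. = FALSE)
  }
  if (!is.numeric(prominence) || prominence <= 0) {
    stop("prominence must be > 0", call. = FALSE)
  }
  if (is.null(times)) times <- seq_along(values)
  stopifnot(length(times) == length(values))
  mx <- .raw_maxima(values)
  mx <- mx[.prominence(values, mx) >= prominence]
  mn <- .raw_maxima(-values)
  mn <- mn[.prominence(-values, mn) >= prominence]
  idx <- c(mx, mn)
  kind <- rep(c("max", "min"), c(length(mx), length(mn)))
  o <- order(idx)
  idx <- idx[o]; kind <- kind[o]
  ## enforce alternation: between two same-kind extrema restore the opposite
  ## turning point (always exists)
  k <- 1
  while (k < length(idx)) {
    if (kind[k] == kind[k + 1]) {
      seg <- (idx[k] + 1):(idx[k + 1] - 1)
      j <- if (kind[k] == "max") seg[which.min(values[seg])] else
        seg[which.max(values[seg])]
      idx <- append(idx, j, after = k)
      kind <- append(kind, if (kind[k] == "max") "min" else "max", after = k)
    }
    k <- k + 1
  }
  data.frame(time = times[idx], value = values[idx], kind = kind,
             index = idx)
}

## ---- pulse segmentation ----------------------------------------------------

#' Segment a trace into supra-threshold pressure pulses
#'
#' Maximal contiguous runs with `values >= threshold`, reported as half-open
#' time intervals; runs shorter than `min_duration` (integration-grid ripple)
#' are discarded. Crossing of the phonation threshold at a pattern's
#' interior minimum is what defines the "breaking" of a syllable into two
#' pulses.
#'
#' @param values numeric trace.
#' @param times sample times (uniform grid).
#' @param threshold activity threshold, >= 0.
#' @param min_duration minimum pulse duration, ms.
#' @return data frame with columns `start`, `end` (ms), one row per pulse.
#' @export
segment_pulses <- function(values, times, threshold, min_duration = 2) {
  stopifnot(is.numeric(values), is.numeric(times),
            length(values) == length(times))
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  above <- values >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (length(keep) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  out <- data.frame(start = times[starts[keep]],
                    end = times[ends[keep]] + dt)
  out[out$end - out$start >= min_duration, , drop = FALSE]
}

## ---- periodicity and amplitude trend ---------------------------------------

#' Dominant oscillation period of a trace
#'
#' Median inter-maximum interval within a time window, using
#' [find_local_extrema()]. Returns `NA` when fewer than two prominent maxima
#' fall inside the window.
#'
#' @param values,times the trace.
#' @param window `c(t_start, t_end)`; default the whole trace.
#' @param prominence prominence threshold for maxima.
#' @return period in ms, or `NA_real_`.
#' @export
dominant_period <- function(values, times, window = NULL,
                            prominence = 0.02) {
  if (is.null(window)) window <- range(times)
  if (length(window) != 2 || window[1] >= window[2] ||
      window[1] < min(times) - 1e-9 || window[2] > max(times) + 1e-9) {
    stop("invalid window", call. = FALSE)
  }
  w <- times >= window[1] & times <= window[2]
  if (sum(w) < 3) stop("window contains fewer than 3 samples", call. = FALSE)
  ex <- find_local_extrema(values[w], times[w], prominence)
  tm <- ex$time[ex$kind == "max"]
  if (length(tm) < 2) return(NA_real_)
  stats::median(diff(tm))
}

#' Amplitude trend of the RA excitatory activity
#'
#' Classifies the envelope of `e_ra` inside a window as `"increasing"`,
#' `"constant"` or `"decreasing"`. The envelope heights are, in order of
#' preference: the prominent maxima of `e_ra` itself (at least 3 in the
#' window); the `e_ra` level sampled at the times of the prominent `e_er`
#' maxima, i.e. the RA drive behind successive expiratory pulses (the preset
#' RA transients are monotone, with no interior maxima of their own); or the
#' raw series. A least-squares slope of the heights against time is
#' normalised to a relative change across the window
#' (`slope * window span / mean level`); `|relative change| < tol` counts as
#' constant.
#'
#' @param trajectory a `song_trajectory`, or a numeric activity trace (then
#'   supply `times`).
#' @param window `c(t_start, t_end)`; default: the pulsating segment
#'   `[Fd onset, Fd2 onset]` when both exist, else the whole trace.
#' @param tol relative-change tolerance for `"constant"`.
#' @param prominence prominence threshold for envelope maxima.
#' @param times sample times for a plain numeric trace.
#' @return one of `"increasing"`, `"constant"`, `"decreasing"`.
#' @export
ra_amplitude_trend <- function(trajectory, window = NULL, tol = 0.1,
                               prominence = 0.02, times = NULL) {
  is_tr <- inherits(trajectory, "song_trajectory")
  y <- if (is_tr) trajectory$states[, "e_ra"] else trajectory
  tt <- if (is_tr) trajectory$times else
    (if (is.null(times)) seq_along(y) else times)
  if (is.null(window)) {
    window <- range(tt)
    if (is_tr) {
      ds <- trajectory$drive_set
      if (length(ds$Fd) && length(ds$Fd2)) {
        window <- c(ds$Fd[[1]]$onset, ds$Fd2[[1]]$onset)
      }
    }
  }
  w <- tt >= window[1] & tt <= window[2]
  if (sum(w) < 3) return("constant")
  yw <- y[w]; tw <- tt[w]
  ex <- find_local_extrema(yw, tw, prominence)
  pk <- ex[ex$kind == "max", ]
  if (nrow(pk) < 3 && is_tr) {
    ## monotone RA transient: sample it at the expiratory (e_er) pulses
    er <- trajectory$states[w, "e_er"]
    exe <- find_local_extrema(er, tw, prominence)
    pke <- exe[exe$kind == "max" & exe$value >= 0.5 * max(er), ]
    if (nrow(pke) >= 3) {
      pk <- data.frame(time = pke$time, value = yw[pke$index])
    }
  }
  if (nrow(pk) >= 3) {
    fit <- stats::lsfit(pk$time, pk$value)
    rel <- fit$coefficients[2] * (max(pk$time) - min(pk$time)) /
      max(mean(pk$value), 1e-12)
  } else {
    fit <- stats::lsfit(tw, yw)
    rel <- fit$coefficients[2] * (max(tw) - min(tw)) /
      max(mean(yw), 1e-12)
  }
  if (rel > tol) "increasing" else if (rel < -tol) "decreasing" else
    "constant"
}

## ---- classification --------------------------------------------------------

## fixed classifier constants (committed, not fitted): see methods vignette
.cls <- list(
  silent_max    = 0.05,  # traces never exceeding this are "unknown"
  major_frac    = 0.5,   # a "major" maximum reaches this fraction of max
  min_cycles    = 4,     # major maxima needed for the oscillatory branch
  period_cv     = 0.35,  # max coefficient of variation of cycle intervals
  ride_frac     = 0.2,   # cycle minima above this fraction of max: pulsatile
  lobe_ratio    = 2.5,   # second/first lobe duration ratio separating P0/P2
  threshold_frac = 0.1,  # phonation threshold as fraction of global max
  prominence    = 0.02)

#' Rule-based pressure-pattern classifier
#'
#' Labels a simulated (or recorded, resampled) expiratory trace as one of
#' the four canonical canary patterns, or `"unknown"`. The rules, with fixed
#' committed thresholds, mirror the verbal pattern definitions:
#'
#' * four or more near-constant-period major cycles: oscillatory. Cycle
#'   minima staying above 20% of the global maximum (small fluctuations
#'   mounted on a sustained expiration) give `"pulsatile"`; cycles returning
#'   near baseline give `"P1"`.
#' * a pulse with one interior minimum: `"P0"` when the lobe after the
#'   minimum lasts more than 2.5 times the leading lobe (brief peak then a
#'   long gesture), `"P2"` when the two lobes are comparable.
#' * anything else (including near-silent traces): `"unknown"`.
#'
#' @param trajectory a `song_trajectory`, or a numeric trace.
#' @param times sample times when `trajectory` is a plain numeric trace.
#' @return a character label.
#' @export
classify_pattern <- function(trajectory, times = NULL) {
  if (inherits(trajectory, "song_trajectory")) {
    y <- trajectory$states[, "e_er"]
    tt <- trajectory$times
  } else {
    y <- trajectory
    tt <- if (is.null(times)) seq_along(y) else times
  }
  ymax <- max(y)
  if (ymax < .cls$silent_max) return("unknown")
  ex <- find_local_extrema(y, tt, .cls$prominence)
  pk <- ex[ex$kind == "max" & ex$value >= .cls$major_frac * ymax, ]
  if (nrow(pk) >= .cls$min_cycles) {
    iv <- diff(pk$time)
    if (stats::sd(iv) / mean(iv) <= .cls$period_cv) {
      cyc_min <- vapply(seq_len(nrow(pk) - 1), function(j) {
        min(y[pk$index[j]:pk$index[j + 1]])
      }, numeric(1))
      return(if (stats::median(cyc_min) >= .cls$ride_frac * ymax)
        "pulsatile" else "P1")
    }
  }
  if (nrow(pk) >= 2) {
    ## two-lobe pulse: split the supra-threshold trace at the interior min
    seg <- (pk$index[1] + 1):(pk$index[nrow(pk)] - 1)
    imin <- seg[which.min(y[seg])]
    thr <- .cls$threshold_frac * ymax
    dt <- tt[2] - tt[1]
    lobe1 <- sum(y[seq_len(imin)] >= thr) * dt
    lobe2 <- sum(y[imin:length(y)] >= thr) * dt
    if (lobe1 > 0 && lobe2 > 0) {
      return(if (lobe2 / lobe1 >= .cls$lobe_ratio) "P0" else "P2")
    }
  }
  "unknown"
}

## ---- feature report --------------------------------------------------------

#' Extract the pattern-defining features of a trace
#'
#' Bundles the feature operators into one report: prominent extrema, count
#' of supra-threshold pressure pulses (against a phonation threshold given
#' as a fraction of the global maximum), dominant oscillation period, RA
#' amplitude trend (when a full trajectory is supplied), and the rule-based
#' pattern label.
#'
#' @param trajectory a `song_trajectory`, or a numeric trace with `times`.
#' @param times sample times for a plain numeric trace.
#' @param threshold_frac phonation threshold as a fraction of the global
#'   maximum (default 0.1).
#' @param prominence extrema prominence threshold (default 0.02).
#' @return an object of class `feature_report`.
#' @export
extract_features <- function(trajectory, times = NULL, threshold_frac = 0.1,
                             prominence = 0.02) {
  is_tr <- inherits(trajectory, "song_trajectory")
  y <- if (is_tr) trajectory$states[, "e_er"] else trajectory
  tt <- if (is_tr) trajectory$times else
    (if (is.null(times)) seq_along(y) else times)
  ex <- find_local_extrema(y, tt, prominence)
  thr <- threshold_frac * max(y)
  pulses <- segment_pulses(y, tt, thr)
  per <- dominant_period(y, tt, prominence = prominence)
  structure(list(extrema = ex, n_pulses = nrow(pulses), pulses = pulses,
                 dominant_period = per,
                 ra_amplitude_trend = if (is_tr)
                   ra_amplitude_trend(trajectory) else NA_character_,
                 label = classify_pattern(if (is_tr) trajectory else y,
                                          times = tt),
                 threshold = thr),
            class = "feature_report")
}

#' @export
print.feature_report <- function(x, ...) {
  cat("Trace features\n")
  cat(sprintf("  label:           %s\n", x$label))
  cat(sprintf("  pulses >= %.3g:  %d\n", x$threshold, x$n_pulses))
  cat(sprintf("  dominant period: %s\n",
              if (is.na(x$dominant_period)) "none" else
                sprintf("%.1f ms", x$dominant_period)))
  if (!is.na(x$ra_amplitude_trend)) {
    cat(sprintf("  RA trend:        %s\n", x$ra_amplitude_trend))
  }
  cat(sprintf("  extrema:         %d (%d max, %d min)\n", nrow(x$extrema),
              sum(x$extrema$kind == "max"), sum(x$extrema$kind == "min")))
  invisible(x)
}

#' Flat key-value serialization of a feature report
#'
#' @param x a `feature_report`.
#' @return named character vector of scalar features.
#' @export
format_feature_report <- function(x) {
  stopifnot(inherits(x, "feature_report"))
  c(label = x$label,
    n_pulses = as.character(x$n_pulses),
    dominant_period_ms = as.character(x$dominant_period),
    ra_amplitude_trend = as.character(x$ra_amplitude_trend),
    threshold = as.character(x$threshold),
    n_extrema = as.character(nrow(x$extrema)))
}
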