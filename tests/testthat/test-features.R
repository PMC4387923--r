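test_that("extrema of a sine are found once per cycle and alternate", {
  d <- generate_fixture("sine", n = 1001, dt = 0.1, period = 20)
  ex <- find_local_extrema(d$value, d$time, prominence = 0.1)
  ## 100 ms of a 20 ms sine: 5 cycles, endpoints excluded
  expect_equal(sum(ex$kind == "max"), 5)
  expect_equal(sum(ex$kind == "min"), 5)
  expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]))
  expect_equal(ex$value[ex$kind == "max"], rep(1, 5), tolerance = 1e-3)
  ## constant series has no extrema
  expect_equal(nrow(find_local_extrema(rep(2, 100), prominence = 0.1)), 0)
  expect_error(find_local_extrema(c(1, 2), prominence = 0.1), "3 samples")
  expect_error(find_local_extrema(1:10, prominence = 0), "prominence")
})

test_that("the two-bump fixture yields exactly 2 maxima and 1 minimum", {
  d <- generate_fixture("bump_pair", n = 2001, dt = 0.1, peak = 1,
                        valley = 0.3)
  ex <- find_local_extrema(d$value, d$time, prominence = 0.1)
  expect_equal(sum(ex$kind == "max"), 2)
  expect_equal(sum(ex$kind == "min"), 1)
  expect_equal(ex$value[ex$kind == "max"], c(1, 1), tolerance = 1e-6)
  expect_equal(ex$value[ex$kind == "min"], 0.3, tolerance = 1e-6)
  ## prominence of each bump is peak - valley = 0.7: a 0.8 threshold
  ## rejects them
  expect_equal(nrow(find_local_extrema(d$value, d$time, prominence = 0.8)),
               0)
})

test_that("extrema are invariant under adding a constant", {
  d <- generate_fixture("decaying_train", n = 1500, dt = 0.2, period = 40,
                        tau = 120)
  a <- find_local_extrema(d$value, d$time, prominence = 0.05)
  b <- find_local_extrema(d$value + 17.3, d$time, prominence = 0.05)
  expect_equal(a$index, b$index)
  expect_equal(b$value - a$value, rep(17.3, nrow(a)))
})

test_that("pulse segmentation counts supra-threshold runs", {
  d <- generate_fixture("bump_pair", n = 2001, dt = 0.1, valley = 0.05)
  seg <- segment_pulses(d$value, d$time, threshold = 0.1)
  expect_equal(nrow(seg), 2)
  ## threshold below the valley keeps one joint pulse
  seg1 <- segment_pulses(d$value, d$time, threshold = 0.02)
  expect_equal(nrow(seg1), 1)
  expect_equal(nrow(segment_pulses(rep(0, 100), 1:100, 0.5)), 0)
})

test_that("raising the threshold shrinks pulses and splits them at the minimum", {
  tr <- preset_run("P0")
  y <- tr$states[, "e_er"]
  thr <- seq(0.02, 0.9, by = 0.04) * max(y)
  dur <- vapply(thr, function(th) {
    s <- segment_pulses(y, tr$times, th)
    sum(s$end - s$start)
  }, numeric(1))
  ## total supra-threshold duration is non-increasing in the threshold
  expect_true(all(diff(dur) <= 1e-9))
  ## a threshold above the interior minimum splits the P0 pulse in two
  ex <- find_local_extrema(y, tr$times, prominence = 0.02)
  vmin <- min(ex$value[ex$kind == "min"])
  expect_equal(nrow(segment_pulses(y, tr$times, 0.5 * vmin)), 1)
  expect_equal(nrow(segment_pulses(y, tr$times, 1.1 * vmin)), 2)
})

test_that("dominant period recovers a constructed periodicity", {
  d <- generate_fixture("sine", n = 2000, dt = 0.1, period = 20)
  expect_equal(dominant_period(d$value, d$time), 20, tolerance = 0.1 / 20)
  ## single bump: no period
  half <- generate_fixture("sine", n = 101, dt = 0.1, period = 20)
  expect_true(is.na(dominant_period(half$value, half$time,
                                    window = c(0, 10))))
  expect_error(dominant_period(d$value, d$time, window = c(50, 10)),
               "window")
})

test_that("amplitude trend labels constructed envelopes", {
  d <- generate_fixture("decaying_train", n = 3000, dt = 0.2, period = 40,
                        tau = 150)
  expect_equal(ra_amplitude_trend(d$value, times = d$time), "decreasing")
  up <- data.frame(time = d$time, value = rev(d$value))
  expect_equal(ra_amplitude_trend(up$value, times = up$time), "increasing")
  flat <- generate_fixture("sine", n = 2000, dt = 0.1, period = 20,
                           offset = 2)
  expect_equal(ra_amplitude_trend(flat$value, times = flat$time),
               "constant")
})

test_that("each preset classifies as itself", {
  for (nm in c("P0", "pulsatile", "P2", "P1")) {
    expect_equal(classify_pattern(preset_run(nm)), nm, info = nm)
  }
  expect_equal(classify_pattern(rep(0, 500), times = 1:500), "unknown")
})

test_that("feature reports bundle the operators coherently", {
  tr <- preset_run("pulsatile")
  fr <- extract_features(tr)
  expect_s3_class(fr, "feature_report")
  expect_equal(fr$label, "pulsatile")
  expect_equal(fr$n_pulses, 1)   # ripple rides a sustained expiration
  expect_gt(fr$dominant_period, 10)
  expect_equal(fr$ra_amplitude_trend, "increasing")
  expect_true(all(fr$extrema$kind[-1] != fr$extrema$kind[-nrow(fr$extrema)]))
  kv <- format_feature_report(fr)
  expect_equal(unname(kv["label"]), "pulsatile")
})
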