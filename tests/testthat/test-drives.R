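test_that("square pulses evaluate on a half-open support", {
  p <- square_pulse(0, 20, 10)
  expect_equal(evaluate_drive(list(p), 5), 10)
  expect_equal(evaluate_drive(list(p), 0), 10)    # onset included
  expect_equal(evaluate_drive(list(p), 20), 0)    # offset excluded
  expect_equal(evaluate_drive(list(p), -1e-9), 0)
  expect_equal(evaluate_drive(list(), c(-5, 0, 100)), c(0, 0, 0))
  ## left limit flips the convention
  expect_equal(evaluate_drive(list(p), 0, side = "left"), 0)
  expect_equal(evaluate_drive(list(p), 20, side = "left"), 10)
  expect_error(square_pulse(0, 0), "width")
  expect_error(square_pulse(0, 10, -1), "amplitude")
  expect_error(drive_set(F = list(square_pulse(0, 20), square_pulse(10, 5))),
               "overlap")
  ## shared boundary is fine (half-open)
  expect_silent(drive_set(F = list(square_pulse(0, 10), square_pulse(10, 5))))
})

test_that("drive signals integrate to amplitude times total width", {
  set.seed(11)
  for (k in 1:10) {
    d <- random_drives(400)
    for (sig in d[c("F", "Fd", "Fd2")]) {
      tt <- seq(-10, 600, by = 0.01)
      num <- sum(evaluate_drive(sig, tt)) * 0.01
      exact <- sum(vapply(sig, function(p) p$amplitude * p$width,
                          numeric(1)))
      expect_equal(num, exact, tolerance = 0.02 * max(exact, 1))
    }
  }
})

test_that("build_drives reproduces the published schedules", {
  d <- build_drives("P2")
  expect_equal(d$Fd[[1]]$onset, 22)
  expect_equal(d$F[[1]]$width, 20)
  d <- build_drives("P1")
  expect_equal(d$F[[1]]$width, 40)
  expect_equal(d$Fd[[1]]$width, 140)
  expect_equal(d$Fd2[[1]]$width, 100)
  d <- build_drives("P0")
  expect_equal(d$F[[1]]$width, 20)
  expect_equal(d$Fd[[1]]$width, 10)
  expect_length(d$Fd2, 0)
  ## all amplitudes 10
  for (pat in c("P0", "pulsatile", "P2", "P1")) {
    d <- build_drives(pat)
    for (sig in d[c("F", "Fd", "Fd2")]) {
      for (p in sig) expect_equal(p$amplitude, 10)
    }
  }
  expect_error(build_drives("P3"), "arg")
  expect_error(build_drives("P0", d_total = -5), "d_total")
})

test_that("build_drives translates with the IA pulse onset", {
  a <- build_drives("pulsatile", f_onset = 0)
  b <- build_drives("pulsatile", f_onset = 100)
  for (sig in c("F", "Fd", "Fd2")) {
    for (k in seq_along(a[[sig]])) {
      expect_equal(b[[sig]][[k]]$onset, a[[sig]][[k]]$onset + 100)
      expect_equal(b[[sig]][[k]]$width, a[[sig]][[k]]$width)
    }
  }
})

test_that("apply_cooling stretches and delays HVC pulses only", {
  d <- build_drives("P0")
  cb <- apply_cooling(d, 15, 5, "both")
  expect_equal(cb$Fd[[1]]$width, 25)
  expect_equal(cb$Fd[[1]]$onset, d$Fd[[1]]$onset + 5)
  expect_identical(cb$F, d$F)
  cs <- apply_cooling(d, 15, 5, "stretch_only")
  expect_equal(cs$Fd[[1]]$width, 25)
  expect_equal(cs$Fd[[1]]$onset, d$Fd[[1]]$onset)
  ## null perturbation is the identity
  expect_identical(apply_cooling(d, 0, 0, "both"), d)
  expect_error(apply_cooling(d, 15, 5, "warm"), "arg")
  expect_error(apply_cooling(d, -1, 0), ">= 0")
})

test_that("cooling commutes with time translation of the schedule", {
  d0 <- build_drives("P0", f_onset = 0)
  d1 <- build_drives("P0", f_onset = 37)
  shift <- function(ds, by) drive_set(
    F = lapply(ds$F, function(p) square_pulse(p$onset + by, p$width,
                                              p$amplitude)),
    Fd = lapply(ds$Fd, function(p) square_pulse(p$onset + by, p$width,
                                                p$amplitude)),
    Fd2 = lapply(ds$Fd2, function(p) square_pulse(p$onset + by, p$width,
                                                  p$amplitude)))
  expect_equal(apply_cooling(d1, 15, 5, "both"),
               shift(apply_cooling(d0, 15, 5, "both"), 37))
})
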