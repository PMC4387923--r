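test_that("sigmoid matches the logistic function and is numerically stable", {
  expect_identical(sigmoid(0), 0.5)
  ## frozen from a 30-digit mpmath evaluation of 1/(1 + e^7.5)
  expect_equal(sigmoid(-7.5), 5.5277863692359952e-4, tolerance = 1e-12)
  expect_gt(sigmoid(2), sigmoid(1))
  x <- seq(-30, 30, by = 0.37)
  expect_true(all(diff(sigmoid(x)) > 0))
  expect_lt(sigmoid(-800), 1e-300)   # clamped, no overflow
  expect_identical(sigmoid(800), 1)
  expect_true(all(is.finite(sigmoid(c(-700, 700)))))
  expect_error(sigmoid(NA_real_), "finite")
  expect_error(sigmoid(Inf), "finite")
})

test_that("rhs implements the four coupled equations", {
  p <- get_preset("P0")$params
  ## all derivatives strictly positive at the origin with zero drives
  dx <- rhs(c(0, 0, 0, 0), 0, p, c(0, 0, 0))
  expect_true(all(dx > 0))
  ## each equals rate * S(bias) there
  expect_equal(unname(dx[1]), p$rates$r_er * sigmoid(p$er$bias_e))
  expect_equal(unname(dx[2]), p$rates$r_er * sigmoid(p$er$bias_i))
  expect_equal(unname(dx[3]), p$rates$r_ra * sigmoid(p$ra$rho_e))
  expect_equal(unname(dx[4]), p$rates$r_ra * sigmoid(p$ra$rho_i))
  ## raising F with the state frozen strictly increases d(e_er)/dt
  st <- c(0.3, 0.1, 0.2, 0.05)
  expect_gt(rhs(st, 0, p, c(10, 0, 0))[1], rhs(st, 0, p, c(0, 0, 0))[1])
  ## full formula check against an independent scalar transcription
  set.seed(42)
  for (k in 1:20) {
    st <- stats::runif(4)
    d <- stats::runif(3, 0, 10)
    S <- function(x) 1 / (1 + exp(-x))
    er <- p$er; ra <- p$ra
    expect_equal(unname(rhs(st, 0, p, d)), c(
      p$rates$r_er * (-st[1] + S(er$bias_e + er$alpha_eer_ra * st[3] +
        er$alpha_eer_F * d[1] + er$w_ee * st[1] + er$w_ei * st[2])),
      p$rates$r_er * (-st[2] + S(er$bias_i + er$alpha_ier_ra * st[3] +
        er$w_ie * st[1] + er$w_ii * st[2])),
      p$rates$r_ra * (-st[3] + S(ra$rho_e + ra$a_e_Fd * d[2] +
        ra$a_e_Fd2 * d[3] + ra$a_e_ra * st[3] + ra$b_e_ra * st[4])),
      p$rates$r_ra * (-st[4] + S(ra$rho_i + ra$a_i_Fd * d[2] +
        ra$a_i_Fd2 * d[3] + ra$a_i_ra * st[3] + ra$b_i_ra * st[4]))),
      tolerance = 1e-14)
  }
  expect_error(rhs(c(0, 0, 0, NA), 0, p, c(0, 0, 0)), "finite")
  expect_error(rhs(c(0, 0, 0, 0), Inf, p, c(0, 0, 0)), "finite")
})

test_that("each derivative is monotone in each input with the printed sign", {
  p <- get_preset("pulsatile")$params
  set.seed(7)
  sgn <- function(a, b) if (a > b) 1 else -1
  for (k in 1:25) {
    st <- stats::runif(4)
    base <- rhs(st, 0, p, c(2, 2, 2))
    ## e_ra raises e_er (alpha_eer_ra > 0) and i_er (alpha_ier_ra > 0)
    up <- st; up[3] <- up[3] + 0.1
    pert <- rhs(up, 0, p, c(2, 2, 2))
    expect_gt(pert[1], base[1])
    expect_gt(pert[2], base[2])
    ## i_ra lowers d(e_ra)/dt (b_e_ra = -10)
    up <- st; up[4] <- up[4] + 0.1
    pert <- rhs(up, 0, p, c(2, 2, 2))
    expect_lt(pert[3], base[3])
    ## Fd2 never lowers d(i_ra)/dt (a_i_Fd2 = 25; the sigmoid may saturate)
    pert <- rhs(st, 0, p, c(2, 2, 4))
    expect_gte(pert[4], base[4])
  }
  ## strict monotonicity in Fd2 where the sigmoid is far from saturation
  d0 <- rhs(c(0, 0, 0, 0), 0, p, c(0, 0, 0))
  d1 <- rhs(c(0, 0, 0, 0), 0, p, c(0, 0, 0.2))
  expect_gt(d1[4], d0[4])
})

test_that("a decoupled unit has equilibrium exactly S(bias)", {
  er <- er_coupling(0, 0, 0, bias_e = -1.3, bias_i = -2,
                    w_ee = 0, w_ei = 0, w_ie = 0, w_ii = 0)
  ra <- ra_coupling(0.7, 0, 0, 0, 0, -3, 0, 0, 0, 0)
  p <- model_params(er, ra)
  eq <- find_equilibria(p, n_starts = 2)
  expect_equal(nrow(eq), 1)
  expect_equal(unname(eq[1, ]),
               sigmoid(c(-1.3, -2, 0.7, -3)), tolerance = 1e-9)
})

test_that("equilibria do not depend on the rate constants", {
  pre <- get_preset("P0")
  p_slow <- model_params(pre$params$er, pre$params$ra,
                         rate_constants(r_er = 0.004, r_ra = 0.33))
  eq1 <- find_equilibria(pre$params, n_starts = 3)
  eq2 <- find_equilibria(p_slow, n_starts = 3)
  expect_equal(eq1, eq2, tolerance = 1e-8)
})

test_that("returned equilibria have tiny residuals and include the ER off state", {
  p <- get_preset("P0")$params
  eq <- find_equilibria(p, c(0, 0, 0), n_starts = 4)
  expect_gt(nrow(eq), 0)
  for (k in seq_len(nrow(eq))) {
    res <- rhs(eq[k, ], 0, p, c(0, 0, 0))
    expect_lt(sqrt(sum(res^2)), 1e-10)
  }
  expect_true(any(eq[, "e_er"] < 0.5))
  expect_true(all(diff(eq[, "e_er"]) >= 0))  # sorted by e_er
})
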