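# Independent oracles and shared fixtures for the test suite.

## cache of preset runs shared across test files (same process under
## test_dir); every entry is produced by the public API.
.runs <- new.env(parent = emptyenv())
preset_run <- function(name) {
  if (is.null(.runs[[name]])) .runs[[name]] <- run_pattern(name)
  .runs[[name]]
}

## closed-form solution of a single additive unit with constant total
## sigmoid argument c: x(t) = S(c) + (x0 - S(c)) exp(-r t)
unit_closed_form <- function(t, x0, cc, r) {
  s <- 1 / (1 + exp(-cc))
  s + (x0 - s) * exp(-r * t)
}

## Brute-force residual scan of [0,1]^4 at a given resolution: enumerates
## every grid point where all four (rate-free) residuals are below `tol`,
## then clusters them and returns one representative (the lowest residual
## norm) per cluster. Written directly from the coupling lists,
## independently of the package's rhs/Jacobian machinery. The e_er/i_er
## residuals depend on (e, i, re) and the RA residuals on (re, ri) only, so
## the scan enumerates the RA plane first and the ER plane per admissible
## (re, ri) cell; this visits exactly the same grid points as a flat
## four-dimensional loop.
brute_scan_equilibria <- function(params, res = 0.01, tol = 0.05) {
  sig <- function(x) 1 / (1 + exp(-x))
  er <- params$er; ra <- params$ra
  g <- seq(0, 1, by = res)
  RE <- rep(g, times = length(g)); RI <- rep(g, each = length(g))
  f3 <- -RE + sig(ra$rho_e + ra$a_e_ra * RE + ra$b_e_ra * RI)
  f4 <- -RI + sig(ra$rho_i + ra$a_i_ra * RE + ra$b_i_ra * RI)
  okra <- which(abs(f3) < tol & abs(f4) < tol)
  E <- rep(g, times = length(g)); I <- rep(g, each = length(g))
  cand <- matrix(numeric(0), 0, 5)
  for (k in okra) {
    re <- RE[k]; ri <- RI[k]
    f1 <- -E + sig(er$bias_e + er$alpha_eer_ra * re + er$w_ee * E +
                     er$w_ei * I)
    f2 <- -I + sig(er$bias_i + er$alpha_ier_ra * re + er$w_ie * E +
                     er$w_ii * I)
    ok <- which(abs(f1) < tol & abs(f2) < tol)
    if (length(ok)) {
      nrm <- sqrt(f1[ok]^2 + f2[ok]^2 + f3[k]^2 + f4[k]^2)
      cand <- rbind(cand, cbind(E[ok], I[ok], re, ri, nrm))
    }
  }
  if (nrow(cand) == 0) return(matrix(numeric(0), 0, 4))
  ## greedy clustering by residual norm
  cand <- cand[order(cand[, 5]), , drop = FALSE]
  reps <- matrix(numeric(0), 0, 4)
  while (nrow(cand) > 0) {
    r0 <- cand[1, 1:4]
    reps <- rbind(reps, r0)
    d <- sqrt(rowSums((cand[, 1:4, drop = FALSE] -
                         matrix(r0, nrow(cand), 4, byrow = TRUE))^2))
    cand <- cand[d > 5 * res, , drop = FALSE]
  }
  unname(reps)
}

## random-but-reproducible model parameters and drive schedules for
## property tests (boundedness holds for any finite values)
random_params <- function() {
  er <- er_coupling(stats::runif(1, 0, 5), stats::runif(1, -10, 15),
                    stats::runif(1, -5, 10),
                    bias_e = stats::runif(1, -12, 2),
                    bias_i = stats::runif(1, -12, 2),
                    w_ee = stats::runif(1, -5, 12),
                    w_ei = stats::runif(1, -12, 5),
                    w_ie = stats::runif(1, -5, 12),
                    w_ii = stats::runif(1, -5, 8))
  ra <- ra_coupling(stats::runif(1, -12, 2), stats::runif(1, 0, 35),
                    stats::runif(1, 0, 25), stats::runif(1, -5, 16),
                    stats::runif(1, -12, 8),
                    stats::runif(1, -12, 2), stats::runif(1, 0, 25),
                    stats::runif(1, 0, 25), stats::runif(1, -5, 16),
                    stats::runif(1, -12, 8))
  rates <- rate_constants(r_er = stats::runif(1, 0.02, 0.3),
                          r_ra = stats::runif(1, 0.02, 0.3))
  model_params(er, ra, rates)
}

random_drives <- function(t_max = 1000) {
  one <- function() {
    n <- sample(0:3, 1)
    if (n == 0) return(NULL)
    on <- sort(stats::runif(n, 0, t_max))
    w <- stats::runif(n, 2, 50)
    ## shrink widths to avoid overlap
    if (n > 1) w[-n] <- pmin(w[-n], diff(on) * 0.9)
    lapply(seq_len(n), function(k) square_pulse(on[k], w[k], 10))
  }
  drive_set(F = one(), Fd = one(), Fd2 = one())
}
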