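#' Couplings of the expiratory-related (ER) area
#'
#' The ER area is an excitatory/inhibitory pair (`e_er`, `i_er`). Its
#' internal wiring is fixed by the model definition; the three gains that
#' differ between pressure patterns are the drive gain `alpha_eer_F` (IA
#' pulse onto `e_er`) and the two gains of the RA excitatory output onto the
#' ER pair (`alpha_eer_ra`, `alpha_ier_ra`).
#'
#' @param alpha_eer_F gain of the initiating-area pulse F on `e_er`.
#' @param alpha_eer_ra gain of RA excitatory activity on `e_er`.
#' @param alpha_ier_ra gain of RA excitatory activity on `i_er`.
#' @param bias_e,bias_i fixed biases of the two populations.
#' @param w_ee,w_ei,w_ie,w_ii fixed internal weights (`e_er` self-excitation,
#'   `i_er -> e_er` inhibition, `e_er -> i_er` excitation, `i_er` self term).
#' @return an object of class `er_coupling`.
#' @export
er_coupling <- function(alpha_eer_F, alpha_eer_ra, alpha_ier_ra,
                        bias_e = -7.5, bias_i = -11.5,
                        w_ee = 10, w_ei = -10, w_ie = 10, w_ii = 2) {
  out <- list(alpha_eer_F = alpha_eer_F, alpha_eer_ra = alpha_eer_ra,
              alpha_ier_ra = alpha_ier_ra, bias_e = bias_e, bias_i = bias_i,
              w_ee = w_ee, w_ei = w_ei, w_ie = w_ie, w_ii = w_ii)
  stopifnot(all(vapply(out, function(v) is.numeric(v) && length(v) == 1 &&
                         is.finite(v), logical(1))))
  structure(out, class = "er_coupling")
}

#' Couplings of nucleus RA
#'
#' RA is an excitatory/inhibitory pair (`e_ra`, `i_ra`) that processes the
#' HVC bursts (`Fd`, `Fd2`) into the second, telencephalon-processed drive to
#' the ER area. Each population has a bias, gains for the two HVC-derived
#' pulses, and gains for the two RA activities. Note that in the inhibitory
#' equation the `a_i_ra` term multiplies the excitatory activity `e_ra`, as
#' in the model definition.
#'
#' @param rho_e,a_e_Fd,a_e_Fd2,a_e_ra,b_e_ra excitatory population: bias,
#'   gains of Fd, Fd2, `e_ra`, and `i_ra`.
#' @param rho_i,a_i_Fd,a_i_Fd2,a_i_ra,b_i_ra inhibitory population: bias,
#'   gains of Fd, Fd2, `e_ra`, and `i_ra`.
#' @return an object of class `ra_coupling`.
#' @export
ra_coupling <- function(rho_e, a_e_Fd, a_e_Fd2, a_e_ra, b_e_ra,
                        rho_i, a_i_Fd, a_i_Fd2, a_i_ra, b_i_ra) {
  out <- list(rho_e = rho_e, a_e_Fd = a_e_Fd, a_e_Fd2 = a_e_Fd2,
              a_e_ra = a_e_ra, b_e_ra = b_e_ra,
              rho_i = rho_i, a_i_Fd = a_i_Fd, a_i_Fd2 = a_i_Fd2,
              a_i_ra = a_i_ra, b_i_ra = b_i_ra)
  stopifnot(all(vapply(out, function(v) is.numeric(v) && length(v) == 1 &&
                         is.finite(v), logical(1))))
  structure(out, class = "ra_coupling")
}

#' Rate constants (inverse time constants) of the two areas
#'
#' Both ER populations share the rate constant `r_er` and both RA populations
#' share `r_ra`, in 1/ms. Three parses of the model's printed prefactors are
#' selectable:
#'
#' * `"fast"` (default): `r_er = 1/4.95`, `r_ra = 1/20` per ms
#'   (tau_ER ~ 5 ms, tau_RA = 20 ms). This is the only reading under which
#'   the four pressure patterns and the cooling experiment reproduce at the
#'   published pulse widths and delays; see the methods vignette.
#' * `"reciprocal"`: `r_er = 1/49.5`, `r_ra = 1/20` per ms.
#' * `"literal"`: `r_er = 149.5`, `r_ra = 20` per ms.
#'
#' Explicit `r_er` / `r_ra` values override the parse.
#'
#' @param parse one of `"fast"`, `"reciprocal"`, `"literal"`.
#' @param r_er,r_ra optional explicit rate constants (1/ms), both > 0.
#' @return an object of class `rate_constants` with fields `r_er`, `r_ra`.
#' @export
rate_constants <- function(parse = c("fast", "reciprocal", "literal"),
                           r_er = NULL, r_ra = NULL) {
  parse <- match.arg(parse)
  def <- switch(parse,
    fast       = c(1 / 4.95, 1 / 20),
    reciprocal = c(1 / 49.5, 1 / 20),
    literal    = c(149.5, 20))
  r_er <- if (is.null(r_er)) def[1] else r_er
  r_ra <- if (is.null(r_ra)) def[2] else r_ra
  stopifnot(is.numeric(r_er), is.numeric(r_ra), length(r_er) == 1,
            length(r_ra) == 1, is.finite(r_er), is.finite(r_ra),
            r_er > 0, r_ra > 0)
  structure(list(r_er = r_er, r_ra = r_ra, parse = parse),
            class = "rate_constants")
}

#' Full parameter set of the four-population model
#'
#' Aggregates the ER couplings, RA couplings and rate constants. The state
#' ordering used throughout the package is `(e_er, i_er, e_ra, i_ra)`.
#'
#' @param er an [er_coupling()].
#' @param ra an [ra_coupling()].
#' @param rates a [rate_constants()].
#' @return an object of class `model_params`.
#' @export
model_params <- function(er, ra, rates = rate_constants()) {
  stopifnot(inherits(er, "er_coupling"), inherits(ra, "ra_coupling"),
            inherits(rates, "rate_constants"))
  structure(list(er = er, ra = ra, rates = rates), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (state order: e_er, i_er, e_ra, i_ra)\n")
  cat(sprintf("  ER:  (alpha_eer_F, alpha_eer_ra, alpha_ier_ra) = (%g, %g, %g)\n",
              x$er$alpha_eer_F, x$er$alpha_eer_ra, x$er$alpha_ier_ra))
  cat(sprintf("       biases (%g, %g), weights (%g, %g, %g, %g)\n",
              x$er$bias_e, x$er$bias_i, x$er$w_ee, x$er$w_ei, x$er$w_ie,
              x$er$w_ii))
  cat(sprintf("  RA_e: (rho, a_Fd, a_Fd2, a_ra, b_ra) = (%g, %g, %g, %g, %g)\n",
              x$ra$rho_e, x$ra$a_e_Fd, x$ra$a_e_Fd2, x$ra$a_e_ra, x$ra$b_e_ra))
  cat(sprintf("  RA_i: (rho, a_Fd, a_Fd2, a_ra, b_ra) = (%g, %g, %g, %g, %g)\n",
              x$ra$rho_i, x$ra$a_i_Fd, x$ra$a_i_Fd2, x$ra$a_i_ra, x$ra$b_i_ra))
  cat(sprintf("  rates: r_er = %g/ms, r_ra = %g/ms (parse: %s)\n",
              x$rates$r_er, x$rates$r_ra, x$rates$parse))
  invisible(x)
}

#' Network state constructor
#'
#' The state of the model: the four dimensionless average activities. All
#' dynamics keep a state started in `[0, 1]^4` inside `[0, 1]^4` (the
#' sigmoid output lies in (0, 1) and the leak pulls each activity toward it).
#'
#' @param e_er,i_er,e_ra,i_ra activities.
#' @return a named numeric vector of length 4.
#' @export
network_state <- function(e_er = 0, i_er = 0, e_ra = 0, i_ra = 0) {
  x <- c(e_er = e_er, i_er = i_er, e_ra = e_ra, i_ra = i_ra)
  if (!is.numeric(x) || length(x) != 4 || any(!is.finite(x))) {
    stop("network_state components must be finite numbers", call. = FALSE)
  }
  x
}

## Linear-algebra view of the model used by rhs() and the integrator:
##   dx/dt = r * (-x + S(W x + B d(t) + rho))
## with x = (e_er, i_er, e_ra, i_ra), d = (F, Fd, Fd2).
.param_matrices <- function(params) {
  er <- params$er; ra <- params$ra
  W <- matrix(c(
    er$w_ee, er$w_ei, er$alpha_eer_ra, 0,
    er$w_ie, er$w_ii, er$alpha_ier_ra, 0,
    0,       0,       ra$a_e_ra,       ra$b_e_ra,
    0,       0,       ra$a_i_ra,       ra$b_i_ra), 4, 4, byrow = TRUE)
  B <- matrix(c(
    er$alpha_eer_F, 0,        0,
    0,              0,        0,
    0,              ra$a_e_Fd, ra$a_e_Fd2,
    0,              ra$a_i_Fd, ra$a_i_Fd2), 4, 3, byrow = TRUE)
  rho <- c(er$bias_e, er$bias_i, ra$rho_e, ra$rho_i)
  r <- c(params$rates$r_er, params$rates$r_er,
         params$rates$r_ra, params$rates$r_ra)
  list(W = W, B = B, rho = rho, r = r)
}
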