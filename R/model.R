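#' Right-hand side of the four-population model
#'
#' Time derivatives of the state `(e_er, i_er, e_ra, i_ra)`:
#' \deqn{de_{er}/dt = r_{er}(-e_{er} + S(b_e + \alpha_{eer,ra} e_{ra} +
#'   \alpha_{eer,F} F(t) + w_{ee} e_{er} + w_{ei} i_{er}))}
#' \deqn{di_{er}/dt = r_{er}(-i_{er} + S(b_i + \alpha_{ier,ra} e_{ra} +
#'   w_{ie} e_{er} + w_{ii} i_{er}))}
#' \deqn{de_{ra}/dt = r_{ra}(-e_{ra} + S(\rho_e + a_{Fd} Fd(t) +
#'   a_{Fd2} Fd2(t) + a_{ra} e_{ra} + b_{ra} i_{ra}))}
#' \deqn{di_{ra}/dt = r_{ra}(-i_{ra} + S(\rho_i + a_{Fd} Fd(t) +
#'   a_{Fd2} Fd2(t) + a_{ra} e_{ra} + b_{ra} i_{ra}))}
#' where `S` is [sigmoid()] and, in the `i_ra` equation, the `a_i_ra` term
#' multiplies the excitatory activity `e_ra`.
#'
#' @param state numeric vector of length 4 (order `e_er, i_er, e_ra, i_ra`).
#' @param t time, ms.
#' @param params a [model_params()].
#' @param drives a [drive_set()], or a numeric vector of length 3 giving
#'   constant values of `(F, Fd, Fd2)`.
#' @return named numeric vector of the four derivatives, 1/ms.
#' @export
rhs <- function(state, t, params, drives) {
  if (!is.numeric(state) || length(state) != 4 || any(!is.finite(state))) {
    stop("state must be 4 finite numbers", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t)) {
    stop("t must be a finite time", call. = FALSE)
  }
  stopifnot(inherits(params, "model_params"))
  d <- if (inherits(drives, "drive_set")) {
    as.numeric(evaluate_drive(drives, t))
  } else if (is.numeric(drives) && length(drives) == 3) {
    drives
  } else {
    stop("drives must be a drive_set or numeric of length 3", call. = FALSE)
  }
  m <- .param_matrices(params)
  dx <- m$r * (-state + .sig(as.numeric(m$W %*% state) + m$rho +
                               as.numeric(m$B %*% d)))
  names(dx) <- c("e_er", "i_er", "e_ra", "i_ra")
  dx
}

#' Find equilibria of the model under constant drives
#'
#' Searches for all roots of the right-hand side with the drives frozen at
#' constant values, via damped Newton refinement (numerical Jacobian) from a
#' regular grid of starting points in `[0, 1]^4`. Roots with residual norm
#' below `tol` are kept; roots closer than `merge_tol` are merged; the
#' result is sorted by `e_er` ascending. Equilibria are independent of the
#' rate constants (positive factors do not move the zeros).
#'
#' The pattern mechanisms live on this equilibrium structure: at rest the ER
#' pair sits on its "off" fixed point, and a sufficiently strong RA input
#' (P0, but not P2) removes it, forcing the system to the "on" fixed point.
#'
#' @param params a [model_params()].
#' @param constant_drives numeric length 3, constant `(F, Fd, Fd2)`.
#' @param n_starts starting points per dimension (total `n_starts^4`).
#' @param tol residual-norm tolerance for an accepted root.
#' @param merge_tol distance below which two roots are considered identical.
#' @return a matrix with columns `e_er, i_er, e_ra, i_ra`, one row per
#'   equilibrium (possibly zero rows).
#' @export
find_equilibria <- function(params, constant_drives = c(0, 0, 0),
                            n_starts = 4, tol = 1e-10, merge_tol = 1e-6) {
  stopifnot(inherits(params, "model_params"), n_starts >= 1,
            is.numeric(constant_drives), length(constant_drives) == 3)
  m <- .param_matrices(params)
  u <- as.numeric(m$B %*% constant_drives)
  ## rates cancel in the root condition; solve -x + S(Wx + rho + u) = 0
  f <- function(x) -x + .sig(as.numeric(m$W %*% x) + m$rho + u)
  grid1 <- if (n_starts == 1) 0.5 else seq(0, 1, length.out = n_starts)
  starts <- as.matrix(expand.grid(grid1, grid1, grid1, grid1))
  roots <- list()
  for (k in seq_len(nrow(starts))) {
    x <- starts[k, ]
    ok <- FALSE
    for (it in 1:100) {
      fx <- f(x)
      if (sqrt(sum(fx^2)) < tol) { ok <- TRUE; break }
      J <- matrix(0, 4, 4)
      h <- 1e-7
      for (j in 1:4) {
        xp <- x; xp[j] <- xp[j] + h
        J[, j] <- (f(xp) - fx) / h
      }
      dxn <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(dxn)) break
      ## damping: halve the step until the residual decreases
      lam <- 1
      repeat {
        xn <- x + lam * dxn
        if (sqrt(sum(f(xn)^2)) < sqrt(sum(fx^2)) || lam < 1e-4) break
        lam <- lam / 2
      }
      if (lam < 1e-4) break
      x <- xn
    }
    if (ok && all(is.finite(x))) {
      dup <- any(vapply(roots, function(r) sqrt(sum((r - x)^2)) < merge_tol,
                        logical(1)))
      if (!dup) roots[[length(roots) + 1]] <- x
    }
  }
  out <- if (length(roots) == 0) {
    matrix(numeric(0), 0, 4)
  } else {
    do.call(rbind, roots[order(vapply(roots, `[[`, numeric(1), 1))])
  }
  colnames(out) <- c("e_er", "i_er", "e_ra", "i_ra")
  out
}
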