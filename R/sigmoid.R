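#' Logistic sigmoid nonlinearity
#'
#' The saturating input-output function of every population in the additive
#' model, `S(x) = 1 / (1 + exp(-x))`. The argument is clamped to +/- 700
#' before exponentiation so that extreme synaptic inputs saturate cleanly to
#' 0 or 1 instead of overflowing; at the model's operating scales (|x| < 400)
#' the clamp never engages.
#'
#' @param x numeric vector of synaptic inputs; must be finite.
#' @return numeric vector of activities in (0, 1).
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(-7.5)   # ~5.53e-4, the resting drive of the ER excitatory unit
#' @export
sigmoid <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("sigmoid() requires finite numeric input", call. = FALSE)
  }
  1 / (1 + exp(-pmin(pmax(x, -700), 700)))
}

## internal, no validation: used in integration inner loops
.sig <- function(x) 1 / (1 + exp(-pmin(pmax(x, -700), 700)))
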