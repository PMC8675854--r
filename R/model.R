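## Vector field and Jacobian --------------------------------------------------

#' Hill response function
#'
#' Saturating response nonlinearity `x^n / (s^n + x^n)` mapping presynaptic
#' population activity to synaptic drive.  For `x >= 0` the value lies in
#' `[0, 1)`; with an even index `n` the function is defined (and even) for
#' negative activity as well.
#'
#' @param x activity value(s); must be finite.
#' @param s Hill coefficient (half-saturation point), `s > 0`.
#' @param n Hill index, integer `>= 1`.
#' @return numeric vector of the same length as `x`.
#' @examples
#' hill_response(2, s = 2, n = 2)   # 0.5 at the half-saturation point
#' @export
hill_response <- function(x, s = 2, n = 2) {
  if (any(!is.finite(x))) stop("activity x must be finite")
  if (!is.numeric(s) || length(s) != 1 || s <= 0)
    stop("Hill coefficient s must be a single positive number")
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("Hill index n must be an integer >= 1")
  x^n / (s^n + x^n)
}

# derivative of the Hill response, d/dx [x^n/(s^n+x^n)]
hill_deriv <- function(x, s = 2, n = 2) {
  n * s^n * x^(n - 1) / (s^n + x^n)^2
}

check_state <- function(x) {
  if (!is.numeric(x) || length(x) != 7)
    stop("state must be a numeric vector of length 7")
  if (any(!is.finite(x))) stop("state must be finite")
  as.numeric(x)
}

#' Right-hand side of the seven-population firing-rate model
#'
#' Evaluates the time derivative (activity per ms) of the state
#' `x = (x1..x7)` for populations cortex, striatum-D1, striatum-D2, GPi,
#' GPe, thalamus and STN.  Each equation has the form
#' `dx_i/dt = (I_i - x_i/R_i + sum of weighted Hill responses) / C_i`,
#' with the dopamine level entering the two striatal equations with
#' opposite sign (`+Dinput` for D1, `-Dinput` for D2).
#'
#' @param x state vector of length 7.
#' @param params a [bgct_params()] object.
#' @return numeric vector of length 7, the time derivative in 1/ms units.
#' @export
bgct_drift <- function(x, params) {
  x <- check_state(x)
  bgct_drift_c(x, bgct_parms_vector(params))
}

#' Exact Jacobian of the model vector field
#'
#' Analytic 7 x 7 matrix of partial derivatives of [bgct_drift()].  The
#' diagonal carries the leak terms `-1/(C_i R_i)`; off-diagonal entries are
#' connection weights times the derivative of the Hill response of the
#' source population.
#'
#' @inheritParams bgct_drift
#' @return a 7 x 7 numeric matrix (units 1/ms).
#' @export
bgct_jacobian <- function(x, params) {
  x <- check_state(x)
  bgct_jac_c(x, bgct_parms_vector(params))
}

# analytic derivative of the drift with respect to one connection weight:
# d f_eq / d T = sign * H(x_source) / C_eq, zero elsewhere.
drift_weight_deriv <- function(x, params, name) {
  i <- match(name, .bgct_weight_map$name)
  if (is.na(i)) stop("not a connection weight: ", name)
  v <- bgct_parms_vector(params)
  out <- numeric(7)
  eq <- .bgct_weight_map$eq[i]
  out[eq] <- .bgct_weight_map$sign[i] *
    hill_response(x[.bgct_weight_map$source[i]], v["s"], v["n"]) /
    v[paste0("C", eq)]
  out
}
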