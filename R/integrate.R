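## Deterministic integration (deSolve, compiled right-hand side) --------------

#' Integrate the deterministic model
#'
#' Adaptive, stiff-capable integration (`deSolve::lsoda` by default) of the
#' firing-rate equations with the compiled right-hand side and analytic
#' Jacobian, with dense output at a fixed reporting step for downstream
#' attractor and period detection.
#'
#' @param params a [bgct_params()] object.
#' @param x0 initial state, length 7.
#' @param t_end end time in ms (> 0).
#' @param dt_report reporting step in ms (default 0.1).
#' @param rtol,atol relative / absolute integration tolerances.
#' @param method a `deSolve` method name, default `"lsoda"`.
#' @return a `data.frame` of class `bgct_trajectory` with columns `time`
#'   and `x1..x7`.
#' @export
integrate_bgct <- function(params, x0, t_end, dt_report = 0.1,
                           rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  x0 <- check_state(x0)
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be positive")
  times <- seq(0, t_end, by = dt_report)
  pv <- bgct_parms_vector(params)
  out <- deSolve::ode(
    y = stats::setNames(x0, paste0("x", 1:7)),
    times = times, parms = pv,
    func = "bgct_derivs", initfunc = "bgct_initmod",
    jacfunc = "bgct_jac", jactype = "fullusr",
    dllname = "bgctdyn", method = method, rtol = rtol, atol = atol
  )
  out <- as.data.frame(out)
  names(out)[1] <- "time"
  if (nrow(out) < length(times) || any(!is.finite(as.matrix(out))))
    stop("integration failed (blow-up or solver error) from x0 = (",
         paste(signif(x0, 6), collapse = ", "), ") at T42 = ",
         unclass(params)["T42"], ", T53 = ", unclass(params)["T53"])
  class(out) <- c("bgct_trajectory", "data.frame")
  attr(out, "params") <- params
  out
}
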