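## Model parameters -----------------------------------------------------------

# canonical parameter names, in the order expected by the compiled core
.bgct_par_names <- c(
  paste0("C", 1:7), paste0("R", 1:7),
  "T16", "T21", "T26", "T31", "T36", "T42", "T45", "T47", "T53", "T57",
  "T64", "T71", "T75",
  paste0("I", 1:7), "s", "n", "Dinput"
)

.bgct_weight_names <- c("T16", "T21", "T26", "T31", "T36", "T42", "T45",
                        "T47", "T53", "T57", "T64", "T71", "T75")

# connection-weight bookkeeping: target equation, sign in that equation and
# presynaptic (source) population of every weight.  +1 entries are
# excitatory, -1 inhibitory; T64 enters the thalamic equation with a minus
# sign because GPi inhibits the thalamus.
.bgct_weight_map <- data.frame(
  name = .bgct_weight_names,
  eq     = c(1, 2, 2, 3, 3, 4, 4, 4, 5, 5, 6, 7, 7),
  sign   = c(1, 1, 1, 1, 1, -1, -1, 1, -1, 1, -1, 1, -1),
  source = c(6, 1, 6, 1, 6, 2, 5, 7, 3, 7, 4, 1, 5),
  stringsAsFactors = FALSE
)

#' Default model parameters of the basal ganglia-thalamocortical loop
#'
#' Builds the full parameter set of the seven-population firing-rate model:
#' membrane capacitances `C1..C7` and resistances `R1..R7`, the thirteen
#' connection weights `Tij` (from population `j` to population `i`),
#' external inputs `I1..I7`, the Hill coefficient `s` and index `n` of the
#' response nonlinearity, and the dopamine level `Dinput`.  Populations are
#' numbered 1 = cortex, 2 = striatum (D1), 3 = striatum (D2), 4 = GPi,
#' 5 = GPe, 6 = thalamus, 7 = STN.
#'
#' Defaults are the published typical values (`C = 3.60`, `R = 1.67`,
#' `s = 2`, `n = 2`, `Dinput = 0.6`, and the fixed weights and inputs).
#' The striatal output weights `T42` (striatum D1 -> GPi, direct pathway)
#' and `T53` (striatum D2 -> GPe, indirect pathway) are the free parameters
#' of most analyses; they default to 1 (a monostable operating point) and
#' are normally set explicitly.  Time is in milliseconds throughout;
#' the nominal membrane time constant is `R*C` (about 6 ms).
#'
#' @param ... named overrides, e.g. `bgct_params(T42 = 3, T53 = 4)`.
#'   Names must be canonical parameter names (`C1..C7`, `R1..R7`, `Tij`,
#'   `I1..I7`, `s`, `n`, `Dinput`).
#' @return a named numeric vector of class `bgct_params` with 37 entries.
#' @examples
#' p <- bgct_params(T42 = 5, T53 = 4)
#' bgct_drift(rep(0, 7), p)
#' @export
bgct_params <- function(...) {
  p <- c(
    rep(3.60, 7), rep(1.67, 7),
    ## T16  T21  T26  T31  T36  T42 T45 T47 T53 T57 T64  T71  T75
         2, 1.4, 1.4, 1.4, 1.4,   1,  3,  2,  1,  1, 3.2, 1.8, 1.8,
    0.1, 0.05, 1.2, 4.4, 2.8, 2, 1.2,
    2, 2, 0.6
  )
  names(p) <- .bgct_par_names
  class(p) <- "bgct_params"
  update_params(p, ...)
}

#' Update model parameters
#'
#' @param params a `bgct_params` object.
#' @param ... named numeric overrides (canonical names only).
#' @param warn_range warn when a connection weight is set outside the
#'   explored range \[0, 7\].  The range is not a hard bound.
#' @return the updated `bgct_params` object.
#' @export
update_params <- function(params, ..., warn_range = TRUE) {
  ov <- list(...)
  if (length(ov) == 0) {
    validate_params(params)
    return(params)
  }
  if (is.null(names(ov)) || any(names(ov) == ""))
    stop("parameter overrides must be named")
  unknown <- setdiff(names(ov), .bgct_par_names)
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  for (nm in names(ov)) {
    v <- ov[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
    params[nm] <- v
  }
  validate_params(params)
  if (warn_range) {
    w <- unlist(params[.bgct_weight_names])
    out <- names(w)[w < 0 | w > 7]
    out <- intersect(out, names(ov))
    if (length(out))
      warning("connection weight(s) outside the explored range [0, 7]: ",
              paste(out, collapse = ", "))
  }
  params
}

validate_params <- function(params) {
  if (!inherits(params, "bgct_params"))
    stop("expected a 'bgct_params' object; see bgct_params()")
  if (length(params) != 37 || !identical(names(unclass(params)),
                                         .bgct_par_names))
    stop("corrupt parameter vector")
  v <- unclass(params)
  if (any(!is.finite(v))) stop("all parameters must be finite")
  if (any(v[paste0("C", 1:7)] <= 0)) stop("capacitances C must be positive")
  if (any(v[paste0("R", 1:7)] <= 0)) stop("resistances R must be positive")
  if (v["s"] <= 0) stop("Hill coefficient s must be positive")
  n <- v["n"]
  if (n < 1 || n != round(n)) stop("Hill index n must be an integer >= 1")
  invisible(params)
}

# flat numeric vector in the order the compiled core expects
bgct_parms_vector <- function(params) {
  validate_params(params)
  unclass(params)
}

#' @export
print.bgct_params <- function(x, ...) {
  v <- unclass(x)
  cat("BGCT loop model parameters (time in ms)\n")
  cat(sprintf("  C = %.3g, R = %.3g (tau = RC = %.4g ms)\n",
              v["C1"], v["R1"], v["C1"] * v["R1"]))
  cat("  direct/indirect striatal weights: T42 =", v["T42"],
      ", T53 =", v["T53"], "\n")
  w <- v[.bgct_weight_names][-c(6, 9)]
  cat("  other weights:",
      paste(sprintf("%s=%.3g", names(w), w), collapse = " "), "\n")
  cat("  inputs I =", paste(signif(v[paste0("I", 1:7)], 3), collapse = ", "),
      "\n")
  cat(sprintf("  Hill: s = %g, n = %g;  dopamine Dinput = %g\n",
              v["s"], v["n"], v["Dinput"]))
  invisible(x)
}

#' Read or write a parameter set as a flat YAML file
#'
#' The file is a flat key-value mapping whose keys are the canonical
#' parameter names (`C1..C7`, `R1..R7`, `T16`, ..., `I1..I7`, `s`, `n`,
#' `Dinput`).  Missing keys keep their default value; unknown keys are an
#' error.
#'
#' @param path file path.
#' @return `read_params()` returns a `bgct_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  kv <- yaml::read_yaml(path)
  if (!is.list(kv) || (length(kv) && is.null(names(kv))))
    stop("malformed parameter file (expected a flat key-value mapping): ",
         path)
  ## YAML 1.1 reads a bare `n` key as the boolean FALSE
  names(kv)[names(kv) %in% c("FALSE", "no")] <- "n"
  do.call(bgct_params, kv)
}

#' @rdname read_params
#' @param params a `bgct_params` object to write.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  v <- as.list(unclass(params))
  yaml::write_yaml(v, path)
  invisible(path)
}
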