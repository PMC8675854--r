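## Attractor census: stable steady states and limit cycles --------------------

# local maxima of a series with quadratic (three-point) refinement of the
# peak time; resolution is finer than the reporting step.
peak_times <- function(t, y) {
  n <- length(y)
  if (n < 3) return(numeric(0))
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  i <- i[i > 1 & i < n]
  if (!length(i)) return(numeric(0))
  h <- t[2] - t[1]
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  delta <- ifelse(abs(den) > 0, 0.5 * (y[i - 1] - y[i + 1]) / den, 0)
  t[i] + pmax(pmin(delta, 1), -1) * h
}

# mean of the last k inter-peak intervals provided their coefficient of
# variation is below cv_max; tries period-doubled grouping when single
# intervals alternate (two unequal maxima per period).
estimate_period <- function(pt, k = 10, k_min = 5, cv_max = 0.02) {
  iv <- diff(pt)
  if (length(iv) < k_min) return(NULL)
  iv <- utils::tail(iv, k)
  cv <- stats::sd(iv) / mean(iv)
  if (is.finite(cv) && cv < cv_max) return(mean(iv))
  if (length(iv) >= 2 * k_min) {
    m <- length(iv) %/% 2
    iv2 <- iv[seq_len(2 * m) %% 2 == 1] + iv[seq_len(2 * m) %% 2 == 0]
    cv2 <- stats::sd(iv2) / mean(iv2)
    if (is.finite(cv2) && cv2 < cv_max) return(mean(iv2))
  }
  NULL
}

#' Classify the attractor reached by a trajectory
#'
#' Discards the leading `transient_fraction` of the trajectory.  If the
#' post-transient peak-to-peak amplitude of every variable is below
#' `osc_threshold` the endpoint is Newton-polished into an equilibrium;
#' otherwise the period is estimated from successive maxima of the
#' cortical activity `x1` (quadratic peak interpolation, mean of the last
#' inter-peak intervals with coefficient of variation below 2%).  When
#' neither succeeds the verdict is `"undecided"`, and the caller is
#' expected to retry once with a longer integration before giving up.
#'
#' @param traj a `bgct_trajectory` from [integrate_bgct()].
#' @param params a [bgct_params()] object.
#' @param transient_fraction fraction of the trajectory discarded as
#'   transient (default 0.5).
#' @param osc_threshold peak-to-peak amplitude (activity units) separating
#'   numerical ripple from genuine oscillation (default 1e-3).
#' @return an object of class `bgct_equilibrium` (list with `state`,
#'   `eigenvalues`, `stability`, `residual`), a `bgct_cycle` (list with
#'   `period` ms, `frequency` Hz, `beta_band`, `envelope` 2 x 7 matrix,
#'   `mean_state`, `sample_orbit`), or the string `"undecided"`.
#' @export
detect_attractor <- function(traj, params, transient_fraction = 0.5,
                             osc_threshold = 1e-3) {
  if (!inherits(traj, "bgct_trajectory")) stop("expected a bgct_trajectory")
  t_end <- max(traj$time)
  post <- traj[traj$time >= transient_fraction * t_end, , drop = FALSE]
  if (nrow(post) < 10) stop("trajectory shorter than the transient")
  X <- as.matrix(post[, paste0("x", 1:7)])
  amp <- apply(X, 2, function(v) diff(range(v)))
  if (all(amp < osc_threshold)) {
    root <- bgct_newton_polish_c(X[nrow(X), ], bgct_parms_vector(params),
                                 1e-9, 80L)
    if (is.null(root)) return("undecided")
    cl <- classify_stability(root, params)
    return(structure(list(state = as.numeric(root),
                          eigenvalues = cl$eigenvalues,
                          stability = cl$stability,
                          residual = max(abs(bgct_drift(root, params)))),
                     class = "bgct_equilibrium"))
  }
  pt <- peak_times(post$time, post$x1)
  period <- estimate_period(pt)
  if (is.null(period)) return("undecided")
  ## envelope, mean and sample orbit over the final full period
  win <- post$time >= max(post$time) - period
  W <- as.matrix(post[win, paste0("x", 1:7)])
  env <- rbind(min = apply(W, 2, min), max = apply(W, 2, max))
  freq <- 1000 / period
  structure(list(period = period, frequency = freq,
                 beta_band = freq >= 13 && freq <= 30,
                 envelope = env,
                 mean_state = colMeans(W),
                 sample_orbit = post[win, , drop = FALSE]),
            class = "bgct_cycle")
}

#' Oscillation frequency of a limit cycle
#'
#' @param cycle a `bgct_cycle` from [detect_attractor()] or
#'   [attractor_census()].
#' @return a list with `frequency_hz` (`1000 / period`) and `beta_band`,
#'   whether the frequency lies in the 13-30 Hz beta band.
#' @export
oscillation_frequency <- function(cycle) {
  if (!inherits(cycle, "bgct_cycle")) stop("expected a bgct_cycle")
  f <- 1000 / cycle$period
  list(frequency_hz = f, beta_band = f >= 13 && f <= 30)
}

# two cycles are the same attractor if their periods differ by <= 2%
# (relative) AND their mean states are within 0.05; the two coexisting
# cycles found at strong indirect coupling must not be merged.
same_cycle <- function(a, b, period_rtol = 0.02, mean_dist = 0.05) {
  abs(a$period - b$period) / max(a$period, b$period) <= period_rtol &&
    sqrt(sum((a$mean_state - b$mean_state)^2)) <= mean_dist
}

# default deterministic initial conditions: Halton points spanning the box
# plus small paired perturbations of every equilibrium along the real part
# of its leading eigenvector
census_ic_grid <- function(eq, n_box = 64, search_box = c(-1, 10),
                           eps = 0.01) {
  ics <- list()
  if (n_box > 0) {
    H <- halton_points(n_box, 7) * diff(search_box) + search_box[1]
    ics <- lapply(seq_len(n_box), function(i) H[i, ])
  }
  for (i in seq_len(nrow(eq))) {
    x <- as.numeric(eq[i, paste0("x", 1:7)])
    J <- bgct_jacobian(x, attr(eq, "params"))
    es <- eigen(J)
    v <- Re(es$vectors[, which.max(Re(es$values))])
    nv <- sqrt(sum(v^2))
    v <- if (nv > 0) v / nv else rep(1 / sqrt(7), 7)
    ics <- c(ics, list(x + eps * v, x - eps * v))
  }
  ics
}

#' Census of all stable attractors at fixed parameters
#'
#' Integrates the model from many initial conditions, classifies each
#' outcome with [detect_attractor()], deduplicates the resulting stable
#' equilibria and limit cycles, and merges the equilibrium side with the
#' root-search enumeration of [find_equilibria()].  The canonical regime
#' tag is `"kSS+mLC"`: k stable steady states, m stable limit cycles.
#'
#' `ic_strategy = "grid"` (default) uses a deterministic 64-point Halton
#' grid over `search_box` plus paired perturbations of every equilibrium.
#' `"targeted"` integrates only from perturbations of unstable equilibria
#' (stable equilibria are already known exactly from the root search);
#' all limit cycles of this model arise through Hopf bifurcations and
#' coexist with an unstable equilibrium, so this much cheaper strategy is
#' used for large parameter sweeps and is cross-checked against the full
#' grid in the test suite.
#'
#' @param params a [bgct_params()] object.
#' @param ic_grid optional list of initial state vectors; overrides
#'   `ic_strategy`.
#' @param t_end integration time per initial condition, ms (default 3000;
#'   undecided outcomes are retried once at twice this horizon).
#' @param ic_strategy `"grid"` or `"targeted"`, see above.
#' @param n_box number of Halton box points in the grid strategy.
#' @param search_box interval for box initial conditions and the root
#'   search.
#' @param n_starts Newton multistart count for [find_equilibria()].
#' @param equilibria optional precomputed `bgct_equilibria` table.
#' @param dt_report,transient_fraction,osc_threshold passed to
#'   [integrate_bgct()] and [detect_attractor()].
#' @return an object of class `bgct_attractor_set`: list with `equilibria`
#'   (stable rows), `all_equilibria`, `cycles` (list of `bgct_cycle`),
#'   `regime_tag`, `n_undecided`, and `exhaustive` (FALSE when some
#'   initial condition stayed undecided after the retry).
#' @export
attractor_census <- function(params, ic_grid = NULL, t_end = 3000,
                             ic_strategy = c("grid", "targeted"),
                             n_box = 64, search_box = c(-1, 10),
                             n_starts = 2000, equilibria = NULL,
                             dt_report = 0.1, transient_fraction = 0.5,
                             osc_threshold = 1e-3) {
  ic_strategy <- match.arg(ic_strategy)
  eq <- if (is.null(equilibria))
    find_equilibria(params, search_box, n_starts) else equilibria
  if (is.null(ic_grid)) {
    ic_grid <- if (ic_strategy == "grid") {
      census_ic_grid(eq, n_box, search_box)
    } else {
      unst <- eq[eq$stability != "stable", , drop = FALSE]
      attr(unst, "params") <- params
      census_ic_grid(unst, n_box = 0)
    }
  }
  cycles <- list()
  sim_eq <- list()
  n_undecided <- 0L
  ## a detection that lands on an *unstable* equilibrium means the
  ## trajectory had not escaped its neighbourhood yet (slow growth close
  ## to a Hopf curve) — treated like "undecided" and retried longer
  unresolved <- function(det)
    identical(det, "undecided") ||
      (inherits(det, "bgct_equilibrium") && det$stability != "stable")
  for (x0 in ic_grid) {
    det <- detect_attractor(
      integrate_bgct(params, x0, t_end, dt_report),
      params, transient_fraction, osc_threshold)
    if (unresolved(det)) {   # retry once, longer horizon
      det <- detect_attractor(
        integrate_bgct(params, x0, 2 * t_end, dt_report),
        params, transient_fraction, osc_threshold)
    }
    if (unresolved(det)) {
      n_undecided <- n_undecided + 1L
    } else if (inherits(det, "bgct_cycle")) {
      if (!any(vapply(cycles, same_cycle, logical(1), b = det)))
        cycles[[length(cycles) + 1]] <- det
    } else if (det$stability == "stable") {
      dup <- any(vapply(sim_eq, function(e)
        max(abs(e$state - det$state)) < 1e-5, logical(1)))
      if (!dup) sim_eq[[length(sim_eq) + 1]] <- det
    }
  }
  ## merge simulation-found stable equilibria into the root-search table
  known <- stable_states(eq)
  for (e in sim_eq) {
    if (nrow(known) == 0 ||
        !any(apply(known, 1, function(r) max(abs(r - e$state)) < 1e-5))) {
      cl <- classify_stability(e$state, params)
      row <- data.frame(
        t(stats::setNames(e$state, paste0("x", 1:7))),
        t(stats::setNames(Re(cl$eigenvalues), paste0("re_lambda", 1:7))),
        t(stats::setNames(Im(cl$eigenvalues), paste0("im_lambda", 1:7))),
        stability = cl$stability, residual = e$residual,
        singular = FALSE, marginal = cl$marginal)
      eq <- rbind(as.data.frame(eq), row)
      eq <- eq[order(eq$x1), ]
      rownames(eq) <- NULL
      class(eq) <- c("bgct_equilibria", "data.frame")
      attr(eq, "params") <- params
      known <- stable_states(eq)
    }
  }
  stab <- eq[eq$stability == "stable", , drop = FALSE]
  ## order cycles by mean cortical activity for reproducible output
  if (length(cycles) > 1)
    cycles <- cycles[order(vapply(cycles, function(cc)
      cc$mean_state[1], numeric(1)))]
  structure(list(
    equilibria = stab,
    all_equilibria = eq,
    cycles = cycles,
    regime_tag = sprintf("%dSS+%dLC", nrow(stab), length(cycles)),
    n_undecided = n_undecided,
    exhaustive = n_undecided == 0L,
    params = params
  ), class = "bgct_attractor_set")
}

#' @export
print.bgct_attractor_set <- function(x, ...) {
  cat("Attractor census:", x$regime_tag,
      if (!x$exhaustive) "(non-exhaustive)" else "", "\n")
  if (nrow(x$equilibria))
    cat("  stable equilibria at x1 =",
        paste(signif(x$equilibria$x1, 5), collapse = ", "), "\n")
  for (cc in x$cycles)
    cat(sprintf(
      "  limit cycle: period %.2f ms (%.1f Hz%s), x1 in [%.4g, %.4g]\n",
      cc$period, cc$frequency, if (cc$beta_band) ", beta band" else "",
      cc$envelope["min", 1], cc$envelope["max", 1]))
  invisible(x)
}

#' Export an attractor census as JSON
#'
#' @param x a `bgct_attractor_set`.
#' @param path output file.
#' @export
write_census_json <- function(x, path) {
  cyc <- lapply(x$cycles, function(cc) list(
    period_ms = cc$period, frequency_hz = cc$frequency,
    beta_band = cc$beta_band,
    envelope_min = as.numeric(cc$envelope["min", ]),
    envelope_max = as.numeric(cc$envelope["max", ]),
    mean_state = as.numeric(cc$mean_state)))
  jsonlite::write_json(list(
    regime_tag = x$regime_tag,
    equilibria = as.data.frame(x$all_equilibria),
    cycles = cyc,
    exhaustive = x$exhaustive
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
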