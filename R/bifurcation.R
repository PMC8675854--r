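## Codimension-1 and -2 bifurcation analysis ----------------------------------

# null vector of a k x (k+1) matrix A (tangent of the continuation curve)
null_tangent <- function(A) {
  q <- qr(t(A))
  Q <- qr.Q(q, complete = TRUE)
  v <- Q[, ncol(A)]
  v / sqrt(sum(v^2))
}

# fold test function: det of the Jacobian, scaled by the nominal time
# constant so typical magnitudes are O(1)
g_fold <- function(x, params) {
  v <- bgct_parms_vector(params)
  det(v["C1"] * v["R1"] * bgct_jacobian(x, params))
}

# Hopf test function: real part of the leading complex eigenvalue pair
# (|Im| > 1e-4; smaller imaginary parts are classified fold-adjacent).
# Returns NA when no complex pair exists.
g_hopf <- function(x, params, im_min = 1e-4) {
  ev <- eigen(bgct_jacobian(x, params), only.values = TRUE)$values
  cplx <- ev[abs(Im(ev)) > im_min]
  if (!length(cplx)) return(c(re = NA_real_, im = NA_real_))
  i <- which.max(Re(cplx))
  c(re = Re(cplx[i]), im = abs(Im(cplx[i])))
}

set_scan <- function(params, name, value) {
  params[name] <- value
  params
}

# Newton refinement of a codim-1 bifurcation point: solves
# {drift = 0, g = 0} in the 8 unknowns (x, p).  The test-function row is
# differenced numerically; the drift rows are analytic.
refine_codim1_point <- function(x, pval, params, scan_param, type,
                                tol = 1e-10, maxit = 30) {
  u <- c(x, pval)
  gfun <- function(u) {
    pp <- set_scan(params, scan_param, u[8])
    if (type == "fold") g_fold(u[1:7], pp) else g_hopf(u[1:7], pp)["re"]
  }
  for (it in seq_len(maxit)) {
    pp <- set_scan(params, scan_param, u[8])
    f <- bgct_drift(u[1:7], pp)
    g <- gfun(u)
    if (is.na(g)) return(NULL)
    if (max(abs(f)) < tol && abs(g) < tol) break
    J <- cbind(bgct_jacobian(u[1:7], pp),
               drift_weight_deriv(u[1:7], pp, scan_param))
    grad <- numeric(8)
    for (j in 1:8) {
      h <- 1e-6 * max(1, abs(u[j]))
      up <- u; up[j] <- u[j] + h
      um <- u; um[j] <- u[j] - h
      grad[j] <- (gfun(up) - gfun(um)) / (2 * h)
    }
    M <- rbind(J, grad)
    du <- tryCatch(solve(M, c(f, g)), error = function(e) NULL)
    if (is.null(du)) return(NULL)
    u <- u - du
    if (any(!is.finite(u))) return(NULL)
  }
  pp <- set_scan(params, scan_param, u[8])
  if (max(abs(bgct_drift(u[1:7], pp))) > 1e-8) return(NULL)
  omega <- if (type == "hopf") unname(g_hopf(u[1:7], pp)["im"]) else NA_real_
  if (type == "hopf" && (!is.finite(omega) || omega < 1e-4)) return(NULL)
  list(x = u[1:7], param = u[8], omega = omega)
}

# one-directional pseudo-arclength continuation of an equilibrium branch
trace_direction <- function(x0, p0, params, scan_param, range, dir,
                            step0 = 0.01, h_min = 1e-5, h_max = 0.1,
                            corr_tol = 1e-10, max_steps = 30000,
                            state_bound = 50) {
  u <- c(x0, p0)
  pp <- set_scan(params, scan_param, p0)
  A <- cbind(bgct_jacobian(x0, pp), drift_weight_deriv(x0, pp, scan_param))
  tang <- null_tangent(A)
  if (tang[8] * dir < 0) tang <- -tang
  h <- step0
  pts <- list()
  escaped <- FALSE
  for (step in seq_len(max_steps)) {
    pred <- u + h * tang
    uc <- pred
    ok <- FALSE
    for (it in 1:10) {
      pc <- set_scan(params, scan_param, uc[8])
      f <- bgct_drift(uc[1:7], pc)
      r <- c(f, sum(tang * (uc - pred)))
      if (max(abs(r)) < corr_tol) { ok <- TRUE; break }
      M <- rbind(cbind(bgct_jacobian(uc[1:7], pc),
                       drift_weight_deriv(uc[1:7], pc, scan_param)),
                 tang)
      du <- tryCatch(solve(M, r), error = function(e) NULL)
      if (is.null(du) || any(!is.finite(du))) break
      uc <- uc - du
      if (max(abs(uc[1:7])) > state_bound) break
    }
    if (!ok) {
      h <- h / 2
      if (h < h_min) break
      next
    }
    ## new tangent, oriented by continuity
    pc <- set_scan(params, scan_param, uc[8])
    A <- cbind(bgct_jacobian(uc[1:7], pc),
               drift_weight_deriv(uc[1:7], pc, scan_param))
    tnew <- null_tangent(A)
    if (sum(tnew * tang) < 0) tnew <- -tnew
    u <- uc
    tang <- tnew
    pts[[length(pts) + 1]] <- u
    if (max(abs(u[1:7])) > state_bound) { escaped <- TRUE; break }
    if (u[8] < range[1] - 1e-9 || u[8] > range[2] + 1e-9) break
    h <- min(h * 1.3, h_max)
  }
  list(points = pts, escaped = escaped)
}

branch_covers <- function(branch_pts, x, pval, tol = 1e-4) {
  if (!length(branch_pts)) return(FALSE)
  d <- vapply(branch_pts, function(u) max(abs(u - c(x, pval))), numeric(1))
  min(d) < tol
}

#' Codimension-one bifurcation diagram along one connection weight
#'
#' Traces all equilibrium branches over `range` by pseudo-arclength
#' continuation (seeded from [find_equilibria()] at five values spanning
#' the range), locates fold points (turning points of the branch in the
#' scan parameter) and Hopf points (sign change of the real part of the
#' leading complex eigenvalue pair), refines each by Newton iteration on
#' the corresponding extended system, and optionally measures stable
#' limit-cycle envelopes by simulation on a uniform sub-grid of scanned
#' values.
#'
#' @param params a [bgct_params()] object giving the fixed parameters.
#' @param scan_param name of the scanned connection weight (e.g. `"T42"`).
#' @param range scan interval, default `c(0, 7)`.
#' @param step0,h_min,h_max initial / minimum / maximum arclength step.
#' @param corr_tol Newton corrector tolerance.
#' @param envelope measure stable-cycle envelopes (default TRUE).
#' @param n_env number of sub-grid values for the envelope.
#' @param t_end integration horizon for the envelope censuses.
#' @param n_starts multistart count for the seeding root searches.
#' @return an object of class `bgct_branch_diagram`: list with `branches`
#'   (each a data.frame `param`, `x1..x7`, `max_re`, `leading_im`,
#'   `stability`), `folds` (`param`, `x1..x7`), `hopfs` (`param`,
#'   `x1..x7`, `omega` in rad/ms), `envelope` (per scanned value and
#'   cycle: `x1_min`, `x1_max`, `period`, `frequency`), `scan_param`,
#'   `range`, and `escaped` (branch left the state bound and was
#'   truncated).
#' @export
trace_branch <- function(params, scan_param, range = c(0, 7),
                         step0 = 0.01, h_min = 1e-5, h_max = 0.1,
                         corr_tol = 1e-10, envelope = TRUE, n_env = 60,
                         t_end = 3000, n_starts = 800) {
  validate_params(params)
  if (!scan_param %in% .bgct_weight_names)
    stop("scan_param must be a declared connection weight")
  seeds <- list()
  for (pv in seq(range[1], range[2], length.out = 5)) {
    eqs <- find_equilibria(set_scan(params, scan_param, pv),
                           n_starts = n_starts)
    for (i in seq_len(nrow(eqs)))
      seeds[[length(seeds) + 1]] <-
        list(x = as.numeric(eqs[i, paste0("x", 1:7)]), p = pv)
  }
  branches <- list()
  all_pts <- list()
  escaped <- FALSE
  for (sd in seeds) {
    if (branch_covers(all_pts, sd$x, sd$p)) next
    up <- trace_direction(sd$x, sd$p, params, scan_param, range, +1,
                          step0, h_min, h_max, corr_tol)
    dn <- trace_direction(sd$x, sd$p, params, scan_param, range, -1,
                          step0, h_min, h_max, corr_tol)
    pts <- c(rev(dn$points), list(c(sd$x, sd$p)), up$points)
    escaped <- escaped || up$escaped || dn$escaped
    if (length(pts) < 2) next
    branches[[length(branches) + 1]] <- pts
    all_pts <- c(all_pts, pts)
  }
  ## per-point eigen classification + bifurcation detection
  br_out <- list()
  folds <- list()
  hopfs <- list()
  for (pts in branches) {
    n <- length(pts)
    P <- vapply(pts, `[`, numeric(1), 8)
    X <- t(vapply(pts, function(u) u[1:7], numeric(7)))
    max_re <- numeric(n)
    lead_re <- numeric(n)
    lead_im <- numeric(n)
    for (i in seq_len(n)) {
      pp <- set_scan(params, scan_param, P[i])
      ev <- eigen(bgct_jac_c(X[i, ], bgct_parms_vector(pp)),
                  only.values = TRUE)$values
      max_re[i] <- max(Re(ev))
      gh <- {
        cp <- ev[abs(Im(ev)) > 1e-4]
        if (length(cp)) {
          k <- which.max(Re(cp)); c(Re(cp[k]), abs(Im(cp[k])))
        } else c(NA_real_, NA_real_)
      }
      lead_re[i] <- gh[1]
      lead_im[i] <- gh[2]
    }
    df <- data.frame(param = P, X, max_re = max_re, leading_im = lead_im,
                     stability = ifelse(max_re < -1e-8, "stable",
                                        "unstable"))
    names(df)[2:8] <- paste0("x", 1:7)
    br_out[[length(br_out) + 1]] <- df
    ## folds: sign change of the parameter increment along the branch
    dp <- diff(P)
    turn <- which(dp[-length(dp)] * dp[-1] < 0) + 1
    for (i in turn) {
      r <- refine_codim1_point(X[i, ], P[i], params, scan_param, "fold")
      if (!is.null(r)) folds[[length(folds) + 1]] <- c(r$param, r$x)
    }
    ## Hopf: sign change of the leading complex pair's real part
    cross <- which(!is.na(lead_re[-n]) & !is.na(lead_re[-1]) &
                     lead_re[-n] * lead_re[-1] < 0)
    for (i in cross) {
      r <- refine_codim1_point(X[i, ], P[i], params, scan_param, "hopf")
      if (!is.null(r))
        hopfs[[length(hopfs) + 1]] <- c(r$param, r$x, r$omega)
    }
  }
  dedup_rows <- function(lst, tol = 1e-4) {
    out <- list()
    for (v in lst) {
      if (!any(vapply(out, function(w)
        max(abs(w[1:8] - v[1:8])) < tol, logical(1))))
        out[[length(out) + 1]] <- v
    }
    out
  }
  folds <- dedup_rows(folds)
  hopfs <- dedup_rows(hopfs)
  fold_df <- as.data.frame(do.call(rbind, folds))
  hopf_df <- as.data.frame(do.call(rbind, hopfs))
  if (nrow(fold_df <- if (length(folds)) fold_df else
           as.data.frame(matrix(numeric(0), 0, 8))) >= 0)
    names(fold_df) <- c("param", paste0("x", 1:7))
  if (nrow(hopf_df <- if (length(hopfs)) hopf_df else
           as.data.frame(matrix(numeric(0), 0, 9))) >= 0)
    names(hopf_df) <- c("param", paste0("x", 1:7), "omega")
  fold_df <- fold_df[order(fold_df$param), , drop = FALSE]
  hopf_df <- hopf_df[order(hopf_df$param), , drop = FALSE]
  out <- list(scan_param = scan_param, range = range, params = params,
              branches = br_out, folds = fold_df, hopfs = hopf_df,
              envelope = NULL, escaped = escaped)
  if (envelope)
    out$envelope <- cycle_envelope(out, n_env = n_env, t_end = t_end)
  class(out) <- "bgct_branch_diagram"
  out
}

# stable-cycle envelopes on a uniform sub-grid of the scanned range,
# seeded from the traced branches (equilibria at each sub-grid value are
# polished from the nearest branch points rather than re-enumerated)
cycle_envelope <- function(bd, n_env = 60, t_end = 3000) {
  vals <- seq(bd$range[1], bd$range[2], length.out = n_env)
  rows <- list()
  for (pv in vals) {
    pp <- set_scan(bd$params, bd$scan_param, pv)
    states <- list()
    for (df in bd$branches) {
      near <- which(abs(df$param - pv) < 0.15)
      if (!length(near)) next
      ## one representative per crossing of this param value
      for (i in near[c(TRUE, diff(near) > 1)]) {
        r <- bgct_newton_polish_c(as.numeric(df[i, paste0("x", 1:7)]),
                                  bgct_parms_vector(pp), 1e-9, 60L)
        if (is.null(r)) next
        if (!any(vapply(states, function(s) max(abs(s - r)) < 1e-5,
                        logical(1))))
          states[[length(states) + 1]] <- as.numeric(r)
      }
    }
    if (!length(states)) next
    ics <- list()
    for (s in states) {
      cl <- classify_stability(s, pp)
      if (cl$stability == "unstable") {
        es <- eigen(bgct_jacobian(s, pp))
        v <- Re(es$vectors[, which.max(Re(es$values))])
        v <- v / max(sqrt(sum(v^2)), 1e-12)
        ics <- c(ics, list(s + 0.01 * v, s - 0.01 * v))
      }
    }
    if (!length(ics)) next
    cycles <- list()
    for (x0 in ics) {
      det <- detect_attractor(integrate_bgct(pp, x0, t_end), pp)
      if (identical(det, "undecided"))
        det <- detect_attractor(integrate_bgct(pp, x0, 2 * t_end), pp)
      if (inherits(det, "bgct_cycle") &&
          !any(vapply(cycles, same_cycle, logical(1), b = det)))
        cycles[[length(cycles) + 1]] <- det
    }
    for (k in seq_along(cycles)) {
      cc <- cycles[[k]]
      rows[[length(rows) + 1]] <- data.frame(
        param = pv, cycle = k, x1_min = cc$envelope["min", 1],
        x1_max = cc$envelope["max", 1], period = cc$period,
        frequency = cc$frequency)
    }
  }
  if (!length(rows))
    return(data.frame(param = numeric(0), cycle = integer(0),
                      x1_min = numeric(0), x1_max = numeric(0),
                      period = numeric(0), frequency = numeric(0)))
  do.call(rbind, rows)
}

#' @export
print.bgct_branch_diagram <- function(x, ...) {
  cat("Codim-1 bifurcation diagram:", x$scan_param, "in [",
      x$range[1], ",", x$range[2], "]\n")
  cat("  branches:", length(x$branches),
      " folds:", nrow(x$folds), " Hopf points:", nrow(x$hopfs), "\n")
  if (nrow(x$folds))
    cat("  folds at", x$scan_param, "=",
        paste(signif(x$folds$param, 6), collapse = ", "), "\n")
  if (nrow(x$hopfs))
    cat("  Hopf at", x$scan_param, "=",
        paste(signif(x$hopfs$param, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Export a branch diagram as CSV plus JSON sidecar
#'
#' The CSV holds the sampled branches (scan value, state, stability,
#' branch id); the JSON sidecar stores fold and Hopf points (with the
#' crossing frequency omega, rad/ms) and the stable-cycle envelopes.
#'
#' @param bd a `bgct_branch_diagram`.
#' @param csv_path,json_path output paths.
#' @export
write_branch_csv <- function(bd, csv_path, json_path = NULL) {
  rows <- do.call(rbind, lapply(seq_along(bd$branches), function(i)
    cbind(branch = i, bd$branches[[i]])))
  con <- file(csv_path, "w")
  writeLines(paste0("# codim-1 branches: scan parameter ", bd$scan_param,
                    " (dimensionless weight), activity in model units"),
             con)
  utils::write.csv(rows, con, row.names = FALSE)
  close(con)
  if (!is.null(json_path))
    jsonlite::write_json(list(scan_param = bd$scan_param,
                              folds = bd$folds, hopfs = bd$hopfs,
                              envelope = bd$envelope),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

## --------------------------------------------------------------------------
## codimension-2 curves

# pseudo-arclength continuation of a fold or Hopf curve in two parameters
trace_codim2_direction <- function(x0, a0, b0, params, p1, p2, window,
                                   type, dir, step0 = 0.01, h_min = 1e-5,
                                   h_max = 0.05, corr_tol = 1e-9,
                                   max_steps = 20000, state_bound = 50) {
  gfun <- function(u) {
    pp <- set_scan(set_scan(params, p1, u[8]), p2, u[9])
    if (type == "fold") g_fold(u[1:7], pp) else g_hopf(u[1:7], pp)["re"]
  }
  ext_jac <- function(u, g0) {
    pp <- set_scan(set_scan(params, p1, u[8]), p2, u[9])
    J <- cbind(bgct_jacobian(u[1:7], pp),
               drift_weight_deriv(u[1:7], pp, p1),
               drift_weight_deriv(u[1:7], pp, p2))
    grad <- numeric(9)
    for (j in 1:9) {
      h <- 1e-6 * max(1, abs(u[j]))
      up <- u; up[j] <- u[j] + h
      um <- u; um[j] <- u[j] - h
      grad[j] <- (gfun(up) - gfun(um)) / (2 * h)
    }
    rbind(J, grad)
  }
  u <- c(x0, a0, b0)
  A <- ext_jac(u, gfun(u))
  if (any(!is.finite(A))) return(list(points = list(), stalled = TRUE))
  tang <- null_tangent(A)
  pl <- sqrt(tang[8]^2 + tang[9]^2)
  if (pl > 1e-12 && (tang[8] * dir[1] + tang[9] * dir[2]) < 0)
    tang <- -tang
  h <- step0
  pts <- list()
  stalled <- FALSE
  for (step in seq_len(max_steps)) {
    pred <- u + h * tang
    uc <- pred
    ok <- FALSE
    for (it in 1:10) {
      pp <- set_scan(set_scan(params, p1, uc[8]), p2, uc[9])
      g <- gfun(uc)
      if (is.na(g)) break
      r <- c(bgct_drift(uc[1:7], pp), g, sum(tang * (uc - pred)))
      if (max(abs(r[1:8])) < corr_tol) { ok <- TRUE; break }
      M <- rbind(ext_jac(uc, g), tang)
      du <- tryCatch(solve(M, r), error = function(e) NULL)
      if (is.null(du) || any(!is.finite(du))) break
      uc <- uc - du
      if (max(abs(uc[1:7])) > state_bound) break
    }
    if (!ok) {
      h <- h / 2
      if (h < h_min) { stalled <- length(pts) > 0; break }
      next
    }
    pp <- set_scan(set_scan(params, p1, uc[8]), p2, uc[9])
    if (type == "hopf") {
      im <- g_hopf(uc[1:7], pp)["im"]
      if (!is.finite(im) || im < 1e-4) break  # fold-adjacent: stop curve
      ## keep only the *active* part of the Hopf locus: if the crossing
      ## equilibrium has further eigenvalues in the right half plane the
      ## Hopf happens on a saddle and changes no attractor, so the curve
      ## is not a regime boundary there
      ev <- eigen(bgct_jacobian(uc[1:7], pp), only.values = TRUE)$values
      crit <- which(abs(Im(ev)) > 1e-4 & abs(Re(ev)) < 1e-6)
      if (sum(Re(ev) > 1e-6 & !seq_along(ev) %in% crit) > 0) break
    }
    A <- ext_jac(uc, 0)
    tnew <- null_tangent(A)
    if (sum(tnew * tang) < 0) tnew <- -tnew
    u <- uc
    tang <- tnew
    pts[[length(pts) + 1]] <- u
    ## outside the window (with a small margin): clip and stop
    if (u[8] < window[1] - 0.02 || u[8] > window[2] + 0.02 ||
        u[9] < window[3] - 0.02 || u[9] > window[4] + 0.02) break
    if (max(abs(u[1:7])) > state_bound) break
    ## closed loop
    if (length(pts) > 25 &&
        max(abs(u - pts[[1]])) < 1.5 * h) break
    h <- min(h * 1.3, h_max)
  }
  list(points = pts, stalled = stalled)
}

# full curve through one seed point (both directions)
trace_codim2_curve <- function(seed, params, p1, p2, window, type, ...) {
  up <- trace_codim2_direction(seed$x, seed$a, seed$b, params, p1, p2,
                               window, type, dir = c(1, 0), ...)
  dn <- trace_codim2_direction(seed$x, seed$a, seed$b, params, p1, p2,
                               window, type, dir = c(-1, 0), ...)
  pts <- c(rev(dn$points), list(c(seed$x, seed$a, seed$b)), up$points)
  P <- t(vapply(pts, function(u) u[c(8, 9)], numeric(2)))
  X <- t(vapply(pts, function(u) u[1:7], numeric(7)))
  list(type = type, p1 = P[, 1], p2 = P[, 2], x = X,
       partial = up$stalled || dn$stalled)
}

# cusp points: turning points of a fold curve in the parameter plane,
# detected as a reversal of the in-plane direction of travel
detect_cusps <- function(curve, tol_dot = -0.25, dedup = 0.05) {
  P <- cbind(curve$p1, curve$p2)
  n <- nrow(P)
  if (n < 5) return(NULL)
  d <- diff(P)
  len <- sqrt(rowSums(d^2))
  keep <- len > 1e-12
  d <- d / pmax(len, 1e-300)
  dots <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
  idx <- which(dots < tol_dot & keep[-length(keep)] & keep[-1]) + 1
  if (!length(idx)) return(NULL)
  out <- P[idx, , drop = FALSE]
  ## dedup nearby detections
  sel <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1])
    if (any(sqrt(rowSums((out[seq_len(i - 1), , drop = FALSE] -
                            matrix(out[i, ], i - 1, 2,
                                   byrow = TRUE))^2)) < dedup))
      sel[i] <- FALSE
  out[sel, , drop = FALSE]
}

#' Trace fold and Hopf curves in a two-parameter plane
#'
#' Seeds codimension-1 scans along several slices of the window (both in
#' `p1` at fixed `p2` values and in `p2` at fixed `p1` values), then
#' continues every detected fold point through the extended system
#' `{drift = 0, det J = 0}` and every Hopf point through
#' `{drift = 0, Re lambda_pair = 0}` by pseudo-arclength continuation in
#' `(x, p1, p2)`.  Curves are clipped to the window; a Hopf curve stops
#' where the imaginary part of the crossing pair falls below `1e-4`
#' (fold-adjacent degeneracy).  Cusp points are emitted where a fold
#' curve's in-plane direction of travel reverses (turning point of the
#' curve in the plane).
#'
#' @param params fixed model parameters.
#' @param p1,p2 names of the two scanned connection weights.
#' @param window numeric length 4: `c(p1_min, p1_max, p2_min, p2_max)`.
#' @param n_slices number of seeding slices per axis (default 5).
#' @param n_starts multistart count for the seeding scans.
#' @return list with `curves` (each: `type`, `p1`, `p2`, `x`, `partial`)
#'   and `cusps` (matrix of plane coordinates, one row per cusp).
#' @export
trace_codim2_curves <- function(params, p1, p2, window = c(0, 7, 0, 7),
                                n_slices = 5, n_starts = 600) {
  validate_params(params)
  if (p1 == p2) stop("p1 and p2 must be different weights")
  stopifnot(p1 %in% .bgct_weight_names, p2 %in% .bgct_weight_names)
  seeds <- list()
  add_seed <- function(x, a, b, type)
    seeds[[length(seeds) + 1]] <<- list(x = x, a = a, b = b, type = type)
  slice_scan <- function(scan_name, fix_name, fix_vals, rng) {
    for (fv in fix_vals) {
      bd <- trace_branch(set_scan(params, fix_name, fv), scan_name,
                         range = rng, envelope = FALSE,
                         n_starts = n_starts)
      for (i in seq_len(nrow(bd$folds))) {
        v <- as.numeric(bd$folds[i, paste0("x", 1:7)])
        if (scan_name == p1) add_seed(v, bd$folds$param[i], fv, "fold")
        else add_seed(v, fv, bd$folds$param[i], "fold")
      }
      for (i in seq_len(nrow(bd$hopfs))) {
        v <- as.numeric(bd$hopfs[i, paste0("x", 1:7)])
        if (scan_name == p1) add_seed(v, bd$hopfs$param[i], fv, "hopf")
        else add_seed(v, fv, bd$hopfs$param[i], "hopf")
      }
    }
  }
  slice_scan(p1, p2, seq(window[3], window[4], length.out = n_slices),
             window[1:2])
  slice_scan(p2, p1, seq(window[1], window[2], length.out = n_slices),
             window[3:4])
  curves <- list()
  on_existing <- function(sd) {
    for (cv in curves) {
      if (cv$type != sd$type) next
      d <- sqrt((cv$p1 - sd$a)^2 + (cv$p2 - sd$b)^2)
      if (min(d) < 0.03) return(TRUE)
    }
    FALSE
  }
  for (sd in seeds) {
    if (on_existing(sd)) next
    cv <- trace_codim2_curve(sd, params, p1, p2, window, sd$type)
    if (length(cv$p1) >= 3) curves[[length(curves) + 1]] <- cv
  }
  cusps <- do.call(rbind, lapply(curves, function(cv)
    if (cv$type == "fold") detect_cusps(cv) else NULL))
  list(curves = curves, cusps = cusps, p1 = p1, p2 = p2, window = window)
}
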