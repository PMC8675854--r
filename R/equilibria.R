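## Equilibrium enumeration and linear stability -------------------------------

# deterministic low-discrepancy start grid: Halton sequence in [0,1]^dim
# (one prime base per dimension).  No wall-clock randomness anywhere.
halton_points <- function(n, dim = 7, skip = 0) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  if (dim > length(primes)) stop("at most 10 dimensions supported")
  out <- matrix(0, n, dim)
  for (d in seq_len(dim)) {
    b <- primes[d]
    for (i in seq_len(n)) {
      k <- i + skip
      f <- 1; r <- 0
      while (k > 0) {
        f <- f / b
        r <- r + f * (k %% b)
        k <- k %/% b
      }
      out[i, d] <- r
    }
  }
  out
}

#' Enumerate equilibria of the model at fixed parameters
#'
#' Runs a damped-Newton root search of the vector field from a
#' deterministic low-discrepancy (Halton) grid of starting points spanning
#' `search_box`, deduplicates the converged roots, classifies the linear
#' stability of each from the eigenvalues of the exact Jacobian, and
#' returns the roots sorted by cortical activity `x1`.  The search box
#' only seeds the starts; converged roots outside it are kept, because at
#' strong striatal inhibition the GPi coordinate of an equilibrium can be
#' driven well below zero.
#'
#' Repeated calls with identical arguments return identical tables.
#'
#' @param params a [bgct_params()] object.
#' @param search_box numeric length 2, per-variable interval from which
#'   starts are drawn (default `c(-1, 10)`).
#' @param n_starts number of Newton starts (default 2000).
#' @param tol residual bound: a root must satisfy `max |drift| < tol`.
#' @param dedup_tol two roots closer than this (max-abs state distance)
#'   are considered the same root.
#' @param margin stability margin for the eigenvalue real parts; see
#'   [classify_stability()].
#' @return a `data.frame` of class `bgct_equilibria` with columns
#'   `x1..x7`, `re_lambda1..re_lambda7`, `im_lambda1..im_lambda7`
#'   (eigenvalues sorted by decreasing real part), `stability`
#'   (`"stable"` or `"unstable"`), `residual`, `singular` (near-singular
#'   Jacobian at the root) and `marginal` (an eigenvalue real part within
#'   `margin` of zero, i.e. bifurcation-adjacent).  Empty (zero-row) when
#'   no start converges.
#' @export
find_equilibria <- function(params, search_box = c(-1, 10), n_starts = 2000,
                            tol = 1e-9, dedup_tol = 1e-5, margin = 1e-8) {
  validate_params(params)
  if (length(search_box) != 2 || diff(search_box) <= 0)
    stop("search_box must be an increasing interval of length 2")
  if (n_starts < 1) stop("n_starts must be >= 1")
  starts <- halton_points(n_starts, 7) * diff(search_box) + search_box[1]
  res <- bgct_newton_multistart_c(starts, bgct_parms_vector(params),
                                  tol, 80L, dedup_tol)
  roots <- res$roots
  k <- nrow(roots)
  out <- as.data.frame(matrix(numeric(0), 0, 7 + 14))
  names(out) <- c(paste0("x", 1:7), paste0("re_lambda", 1:7),
                  paste0("im_lambda", 1:7))
  out$stability <- character(0)
  out$residual <- numeric(0)
  out$singular <- logical(0)
  out$marginal <- logical(0)
  if (k > 0) {
    rows <- vector("list", k)
    for (i in seq_len(k)) {
      cl <- classify_stability(roots[i, ], params, margin = margin)
      rows[[i]] <- data.frame(
        t(stats::setNames(roots[i, ], paste0("x", 1:7))),
        t(stats::setNames(Re(cl$eigenvalues), paste0("re_lambda", 1:7))),
        t(stats::setNames(Im(cl$eigenvalues), paste0("im_lambda", 1:7))),
        stability = cl$stability,
        residual = res$residual[i],
        singular = res$singular[i],
        marginal = cl$marginal
      )
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$x1), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("bgct_equilibria", "data.frame")
  attr(out, "params") <- params
  attr(out, "tol") <- tol
  out
}

#' Linear stability of a state
#'
#' Computes the eigenvalues of the exact Jacobian at `x` (sorted by
#' decreasing real part) and labels the state `"stable"` when every real
#' part is below `-margin`, otherwise `"unstable"`.  States with an
#' eigenvalue real part within `margin` of zero are flagged as
#' bifurcation-adjacent via `marginal`.
#'
#' @param x state vector of length 7 (normally an equilibrium).
#' @param params a [bgct_params()] object.
#' @param margin real-part threshold (1/ms), default `1e-8`.
#' @return a list with `eigenvalues` (complex, length 7), `stability`,
#'   `marginal`, and `leading_complex` (the eigenvalue with largest real
#'   part among those with nonzero imaginary part, or `NA`).
#' @export
classify_stability <- function(x, params, margin = 1e-8) {
  x <- check_state(x)
  J <- bgct_jacobian(x, params)
  ev <- tryCatch(eigen(J, only.values = TRUE)$values,
                 error = function(e)
                   stop("eigenvalue computation failed at state (",
                        paste(signif(x, 6), collapse = ", "), "): ",
                        conditionMessage(e)))
  ev <- ev[order(-Re(ev))]
  cplx <- ev[abs(Im(ev)) > 1e-4]
  list(
    eigenvalues = ev,
    stability = if (max(Re(ev)) < -margin) "stable" else "unstable",
    marginal = any(abs(Re(ev)) < margin),
    leading_complex = if (length(cplx)) cplx[1] else NA_complex_
  )
}

# states (rows) of the stable / unstable equilibria in a census table
stable_states <- function(eq) {
  as.matrix(eq[eq$stability == "stable", paste0("x", 1:7), drop = FALSE])
}

#' Write an equilibrium table to CSV
#'
#' Columns: `x1..x7`, `re_lambda1..7`, `im_lambda1..7`, `stability`,
#' `residual`.  A comment header records the units.
#'
#' @param eq a `bgct_equilibria` table from [find_equilibria()].
#' @param path output file path.
#' @export
write_equilibria_csv <- function(eq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# equilibria: activity in model units, eigenvalues in 1/ms",
             con)
  cols <- c(paste0("x", 1:7), paste0("re_lambda", 1:7),
            paste0("im_lambda", 1:7), "stability", "residual")
  utils::write.csv(as.data.frame(eq)[, cols], con, row.names = FALSE)
  invisible(path)
}

#' @export
print.bgct_equilibria <- function(x, ...) {
  if (!all(c("x1", "re_lambda1", "stability", "residual") %in% names(x)))
    return(NextMethod())   # column subset: plain data.frame printing
  cat("Equilibria:", nrow(x), "found (",
      sum(x$stability == "stable"), "stable )\n")
  if (nrow(x))
    print(data.frame(x1 = signif(x$x1, 6),
                     max_re = signif(x$re_lambda1, 4),
                     stability = x$stability,
                     residual = format(x$residual, digits = 2)))
  invisible(x)
}
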