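## Potential landscape U = -ln(Pss) from Langevin ensembles -------------------

#' Noise specification for the stochastic integrator
#'
#' Additive Gaussian white noise of strength `D` applied to the selected
#' equations: the Euler-Maruyama update is
#' `x <- x + drift(x) dt + sqrt(2 D dt) eta` with independent standard
#' normal `eta` per applied equation and step (noise correlation
#' `<zeta(t) zeta(t')> = 2 D delta(t - t')`, isotropic and diagonal).
#'
#' @param D noise strength (default `1e-6`); `D = 0` gives a
#'   deterministic Euler integrator.
#' @param dt Euler-Maruyama step in ms (default 0.01).
#' @param seed integer seed; all stochastic runs are fully reproducible.
#' @param applied equations receiving noise (default all seven).
#' @param reflect optional reflecting floor at zero activity for the
#'   stochastic integrator only (off by default; the deterministic field
#'   is never clamped).
#' @return a list of class `bgct_noise`.
#' @export
noise_spec <- function(D = 1e-6, dt = 0.01, seed = 1L, applied = 1:7,
                       reflect = FALSE) {
  if (!is.numeric(D) || D < 0) stop("noise strength D must be >= 0")
  if (dt <= 0) stop("dt must be positive")
  applied <- as.integer(applied)
  if (length(applied) < 1 || any(applied < 1 | applied > 7))
    stop("applied must index equations 1..7")
  structure(list(D = D, dt = dt, seed = as.integer(seed),
                 applied = applied, reflect = isTRUE(reflect)),
            class = "bgct_noise")
}

#' Simulate one noise-driven (Langevin) trajectory
#'
#' Seeded Euler-Maruyama integration of the model with additive Gaussian
#' white noise (see [noise_spec()]).  With `D = 0` the scheme reduces to
#' deterministic Euler and matches [integrate_bgct()] to the order of the
#' step size.
#'
#' @param params a [bgct_params()] object.
#' @param x0 initial state.
#' @param t_end horizon in ms.
#' @param noise a [noise_spec()].
#' @param record_dt recording interval in ms (default 0.1).
#' @param burn_in time discarded before recording starts (default 0).
#' @return a `data.frame` of class `bgct_trajectory` (columns `time`,
#'   `x1..x7`).
#' @export
langevin_simulate <- function(params, x0, t_end, noise = noise_spec(),
                              record_dt = 0.1, burn_in = 0) {
  x0 <- check_state(x0)
  if (!inherits(noise, "bgct_noise")) stop("expected a noise_spec()")
  nsteps <- round(t_end / noise$dt)
  burn <- round(burn_in / noise$dt)
  every <- max(1L, round(record_dt / noise$dt))
  set.seed(noise$seed)
  out <- tryCatch(
    bgct_em_c(x0, bgct_parms_vector(params), noise$dt, as.integer(nsteps),
              noise$D, noise$applied, as.integer(burn), as.integer(every),
              noise$reflect),
    error = function(e)
      stop("Langevin simulation failed (seed ", noise$seed, "): ",
           conditionMessage(e)))
  out <- as.data.frame(out)
  names(out) <- c("time", paste0("x", 1:7))
  class(out) <- c("bgct_trajectory", "data.frame")
  attr(out, "params") <- params
  out
}

#' Estimate the stationary occupancy Pss on the (x1, x2) plane
#'
#' Runs an ensemble of seeded Langevin replicates started from the
#' deterministic census initial-condition grid, accumulates post-burn-in
#' samples of cortical (`x1`) and striatal-D1 (`x2`) activity into a 2-D
#' histogram, and normalizes.  At the default noise strength `D = 1e-6`
#' basin hopping is essentially impossible, so the stationary
#' distribution is assembled from the multi-start ensemble (each replicate
#' settles into the attractor of its own basin); relative weights of the
#' basins therefore reflect the uniform initial-condition grid.
#'
#' @param params a [bgct_params()] object.
#' @param noise a [noise_spec()]; per-replicate seeds are derived from
#'   `noise$seed`.
#' @param ensemble number of replicates (default 200).
#' @param t_end,burn_in per-replicate horizon and discarded transient, ms.
#' @param grid_n histogram bins per axis (default 100), spanning the
#'   occupied bounding box padded by `pad` on each side.
#' @param sample_mode `"occupancy"` accumulates all post-burn-in samples;
#'   `"endpoint"` keeps only each replicate's final state.
#' @param record_dt sampling interval within a replicate, ms.
#' @param pad relative padding of the histogram bounding box.
#' @return an object of class `bgct_landscape` with `pss` (normalized
#'   occupancy, `grid_n x grid_n`), `x1_edges`, `x2_edges`, `n_samples`
#'   and the generating settings.  Pass to [potential_landscape()].
#' @export
estimate_pss <- function(params, noise = noise_spec(), ensemble = 200,
                         t_end = 3000, burn_in = 1500, grid_n = 100,
                         sample_mode = c("occupancy", "endpoint"),
                         record_dt = 1, pad = 0.1) {
  sample_mode <- match.arg(sample_mode)
  if (ensemble < 1) stop("ensemble must be >= 1")
  eq <- find_equilibria(params)
  ics <- census_ic_grid(eq, n_box = 64)
  samples <- vector("list", ensemble)
  for (i in seq_len(ensemble)) {
    ni <- noise
    ni$seed <- as.integer((noise$seed + 104729 * i) %% 2147483647L)
    x0 <- ics[[(i - 1L) %% length(ics) + 1L]]
    tr <- langevin_simulate(params, x0, t_end, ni,
                            record_dt = record_dt, burn_in = burn_in)
    samples[[i]] <- if (sample_mode == "endpoint")
      as.matrix(tr[nrow(tr), c("x1", "x2")])
    else as.matrix(tr[, c("x1", "x2")])
  }
  S <- do.call(rbind, samples)
  if (nrow(S) == 0) stop("no samples collected")
  r1 <- range(S[, 1]); r2 <- range(S[, 2])
  e1 <- diff(r1); e2 <- diff(r2)
  ## degenerate extent (a single point attractor): give the box a width
  if (e1 < 1e-8) e1 <- max(abs(r1[1]), 1) * 1e-3
  if (e2 < 1e-8) e2 <- max(abs(r2[1]), 1) * 1e-3
  x1_edges <- seq(r1[1] - pad * e1, r1[2] + pad * e1,
                  length.out = grid_n + 1)
  x2_edges <- seq(r2[1] - pad * e2, r2[2] + pad * e2,
                  length.out = grid_n + 1)
  i <- pmin(pmax(findInterval(S[, 1], x1_edges, all.inside = TRUE), 1),
            grid_n)
  j <- pmin(pmax(findInterval(S[, 2], x2_edges, all.inside = TRUE), 1),
            grid_n)
  counts <- matrix(0, grid_n, grid_n)
  tab <- table(factor(i, levels = 1:grid_n), factor(j, levels = 1:grid_n))
  counts <- matrix(as.numeric(tab), grid_n, grid_n)
  pss <- counts / sum(counts)
  structure(list(pss = pss, x1_edges = x1_edges, x2_edges = x2_edges,
                 n_samples = nrow(S), sample_mode = sample_mode,
                 noise = noise, ensemble = ensemble, params = params),
            class = "bgct_landscape")
}

#' Potential landscape U = -ln(Pss) with minima and ring detection
#'
#' Computes `U = -ln(pss)` on occupied bins (empty bins are masked and
#' excluded from the minima search), reports every strict local minimum
#' (U below all occupied 8-neighbors; empty neighbors count as infinitely
#' high), and tests whether the low-U set forms a closed ring (flood-fill
#' hole count), the landscape signature of a stable limit cycle.
#'
#' By default the ring test uses the whole occupied support of `Pss`
#' (`ring_drop = Inf`): at the tiny default noise strength the support
#' converges to the attractor itself, and the occupancy contrast along a
#' relaxation-like cycle — slow segments dwell 10-20 times longer than
#' fast ones — routinely exceeds any fixed potential depth, so a
#' finite-depth cut (available via `ring_drop`) can break a genuine ring
#' into its slow segments at fine bin resolutions.
#'
#' @param ls a `bgct_landscape` from [estimate_pss()].
#' @param ring_drop optional depth (natural-log units above the global
#'   minimum) restricting the low-U set; `Inf` (default) means all
#'   occupied bins.
#' @return the landscape with `U` (matrix, `NA` on empty bins), `minima`
#'   (data.frame `x1`, `x2`, `U`), `ring_detected` and `n_holes` filled.
#' @export
potential_landscape <- function(ls, ring_drop = Inf) {
  if (!inherits(ls, "bgct_landscape")) stop("expected a bgct_landscape")
  U <- -log(ls$pss)
  U[!is.finite(U)] <- NA
  n <- nrow(U)
  ## strict 8-neighbor minima among occupied bins
  Upad <- matrix(Inf, n + 2, n + 2)
  Upad[2:(n + 1), 2:(n + 1)] <- ifelse(is.na(U), Inf, U)
  is_min <- matrix(TRUE, n, n)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- Upad[2:(n + 1) + di, 2:(n + 1) + dj]
    is_min <- is_min & (ifelse(is.na(U), Inf, U) < nb)
  }
  is_min <- is_min & !is.na(U)
  cx <- (ls$x1_edges[-1] + ls$x1_edges[-(n + 1)]) / 2
  cy <- (ls$x2_edges[-1] + ls$x2_edges[-(n + 1)]) / 2
  idx <- which(is_min, arr.ind = TRUE)
  minima <- data.frame(x1 = cx[idx[, 1]], x2 = cy[idx[, 2]],
                       U = U[idx])
  minima <- minima[order(minima$U), , drop = FALSE]
  rownames(minima) <- NULL
  ## ring detection: holes of the low-U set
  low <- !is.na(U) & U <= min(U, na.rm = TRUE) + ring_drop
  holes <- count_holes(low)
  ls$U <- U
  ls$minima <- minima
  ls$ring_detected <- holes > 0
  ls$n_holes <- holes
  ls$ring_drop <- ring_drop
  ls
}

# number of holes of a binary mask: connected components (4-connectivity)
# of the complement that do not touch the border
count_holes <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  comp <- matrix(NA_integer_, n, m)
  nextid <- 0L
  for (start in which(!mask)) {
    if (!is.na(comp[start])) next
    nextid <- nextid + 1L
    queue <- start
    comp[start] <- nextid
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% n + 1L
      j <- (cur - 1L) %/% n + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1 || ii > n || jj < 1 || jj > m) next
        k <- (jj - 1L) * n + ii
        if (!mask[k] && is.na(comp[k])) {
          comp[k] <- nextid
          queue <- c(queue, k)
        }
      }
    }
  }
  if (nextid == 0L) return(0L)
  border <- unique(stats::na.omit(c(comp[1, ], comp[n, ], comp[, 1],
                                    comp[, m])))
  length(setdiff(seq_len(nextid), border))
}

#' @export
print.bgct_landscape <- function(x, ...) {
  cat("Potential landscape on (x1, x2):", x$n_samples, "samples,",
      nrow(x$pss), "x", ncol(x$pss), "bins\n")
  if (!is.null(x$minima)) {
    cat("  local minima:", nrow(x$minima),
        if (isTRUE(x$ring_detected)) " (closed low-U ring present)" else "",
        "\n")
    if (nrow(x$minima))
      print(utils::head(transform(x$minima, U = signif(U, 5)), 5))
  }
  invisible(x)
}

#' Export a landscape as a text grid container plus minima CSV
#'
#' Writes a single JSON file holding bin edges, `pss` and `U` (row-major
#' lists), and optionally a CSV of the minima.
#'
#' @param ls a landscape (after [potential_landscape()]).
#' @param json_path,minima_csv output paths (`NULL` to skip).
#' @export
write_landscape <- function(ls, json_path = NULL, minima_csv = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(
      x1_edges = ls$x1_edges, x2_edges = ls$x2_edges,
      pss = apply(ls$pss, 1, identity, simplify = FALSE),
      U = if (is.null(ls$U)) NULL else
        apply(ls$U, 1, identity, simplify = FALSE),
      ring_detected = ls$ring_detected,
      sample_mode = ls$sample_mode, D = ls$noise$D
    ), json_path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(minima_csv) && !is.null(ls$minima)) {
    con <- file(minima_csv, "w")
    writeLines("# landscape minima: activity in model units, U in nats",
               con)
    utils::write.csv(ls$minima, con, row.names = FALSE)
    close(con)
  }
  invisible(ls)
}
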