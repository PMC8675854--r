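## Two-parameter regime map ---------------------------------------------------

# mark raster cells crossed by a polyline (dense sampling along segments)
rasterize_curve <- function(p1, p2, window, M) {
  w1 <- window[2] - window[1]
  w2 <- window[4] - window[3]
  cs <- min(w1, w2) / M
  cells <- matrix(FALSE, M, M)     # [i = p1 cell, j = p2 cell]
  for (k in seq_len(length(p1) - 1)) {
    len <- sqrt((p1[k + 1] - p1[k])^2 + (p2[k + 1] - p2[k])^2)
    ns <- max(2L, ceiling(len / (cs / 2)))
    a <- p1[k] + (p1[k + 1] - p1[k]) * seq(0, 1, length.out = ns)
    b <- p2[k] + (p2[k + 1] - p2[k]) * seq(0, 1, length.out = ns)
    i <- pmin(pmax(floor((a - window[1]) / w1 * M) + 1, 1), M)
    j <- pmin(pmax(floor((b - window[3]) / w2 * M) + 1, 1), M)
    keep <- a >= window[1] & a <= window[2] & b >= window[3] & b <= window[4]
    cells[cbind(i[keep], j[keep])] <- TRUE
  }
  cells
}

# connected components of the non-boundary cells (4-connectivity) by
# iterative min-label propagation
label_components <- function(boundary) {
  M <- nrow(boundary)
  lab <- matrix(seq_len(M * M), M, M)
  lab[boundary] <- NA
  repeat {
    new <- lab
    ## shift in the four directions and take the componentwise min
    up <- rbind(lab[-1, , drop = FALSE], rep(NA, M))
    dn <- rbind(rep(NA, M), lab[-M, , drop = FALSE])
    lf <- cbind(lab[, -1, drop = FALSE], rep(NA, M))
    rt <- cbind(rep(NA, M), lab[, -M, drop = FALSE])
    new <- pmin(new, up, dn, lf, rt, na.rm = TRUE)
    new[boundary] <- NA
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# distance (in cells) to the nearest boundary cell or window edge,
# by iterative relaxation
boundary_distance <- function(boundary) {
  M <- nrow(boundary)
  d <- matrix(Inf, M, M)
  d[boundary] <- 0
  repeat {
    up <- rbind(d[-1, , drop = FALSE], rep(0, M))
    dn <- rbind(rep(0, M), d[-M, , drop = FALSE])
    lf <- cbind(d[, -1, drop = FALSE], rep(0, M))
    rt <- cbind(rep(0, M), d[, -M, drop = FALSE])
    new <- pmin(d, up + 1, dn + 1, lf + 1, rt + 1)
    if (identical(new, d)) break
    d <- new
  }
  d
}

# bridge the endpoint of a Hopf curve to the nearest fold-curve point when
# it terminates inside the window (fold-adjacent degeneracy): prevents
# raster leaks between regions that the degenerate gap would connect
bridge_curve_ends <- function(curves, window, max_gap = 0.15) {
  fold_pts <- do.call(rbind, lapply(curves, function(cv)
    if (cv$type == "fold") cbind(cv$p1, cv$p2) else NULL))
  if (is.null(fold_pts)) return(curves)
  inside <- function(a, b)
    a > window[1] + 0.03 && a < window[2] - 0.03 &&
    b > window[3] + 0.03 && b < window[4] - 0.03
  for (k in seq_along(curves)) {
    cv <- curves[[k]]
    if (cv$type != "hopf") next
    for (end in c(1L, length(cv$p1))) {
      a <- cv$p1[end]; b <- cv$p2[end]
      if (!inside(a, b)) next
      dd <- sqrt((fold_pts[, 1] - a)^2 + (fold_pts[, 2] - b)^2)
      i <- which.min(dd)
      if (dd[i] < max_gap) {
        if (end == 1L) {
          cv$p1 <- c(fold_pts[i, 1], cv$p1)
          cv$p2 <- c(fold_pts[i, 2], cv$p2)
        } else {
          cv$p1 <- c(cv$p1, fold_pts[i, 1])
          cv$p2 <- c(cv$p2, fold_pts[i, 2])
        }
      }
    }
    curves[[k]] <- cv
  }
  curves
}

#' Regime map over a two-parameter plane
#'
#' Combines traced fold/Hopf curves (the region boundaries) with attractor
#' censuses on a regular lattice.  The plane minus the curves is
#' decomposed into connected faces on a fine raster (4-connectivity);
#' every face is a candidate dynamical region and receives the regime tag
#' of the lattice censuses it contains.  Faces too thin to contain a
#' lattice point are censused at an interior representative instead, so
#' narrow regions are not lost.  `region_count` is the number of faces:
#' two faces separated by a bifurcation curve count separately even if
#' they carry the same tag.
#'
#' @param params fixed model parameters.
#' @param p1,p2 names of the two scanned weights.
#' @param window `c(p1_min, p1_max, p2_min, p2_max)`, default `[0,7]^2`.
#' @param resolution lattice points per axis (>= 21, default 71).
#' @param curves optional precomputed result of [trace_codim2_curves()].
#' @param raster_factor fine-raster refinement relative to the lattice.
#' @param n_starts multistart count for the per-point root searches.
#' @param t_end census integration horizon (ms).
#' @param min_cells minimum face size in raster cells; the default is one
#'   lattice cell (`raster_factor^2`), so a face must be resolvable at
#'   the reporting lattice to count as a region.  Smaller faces (e.g. a
#'   cusp wedge clipped to a sub-lattice corner by the window edge) are
#'   excluded from `region_count`.
#' @return an object of class `bgct_regime_map`: list with `grid` (lattice
#'   data.frame `p1`, `p2`, `tag`, `face`, `exhaustive`), `faces`
#'   (per-region representative point, tag, lattice support, mismatch
#'   flag), `curves`, `cusps`, `region_count`, and the call geometry.
#' @export
region_map <- function(params, p1, p2, window = c(0, 7, 0, 7),
                       resolution = 71, curves = NULL, raster_factor = 8,
                       n_starts = 400, t_end = 3000,
                       min_cells = raster_factor^2) {
  validate_params(params)
  if (resolution < 21) stop("resolution must be at least 21 per axis")
  if (is.null(curves))
    curves <- trace_codim2_curves(params, p1, p2, window)
  cv <- bridge_curve_ends(curves$curves, window)
  M <- raster_factor * (resolution - 1)
  boundary <- matrix(FALSE, M, M)
  for (c1 in cv)
    boundary <- boundary | rasterize_curve(c1$p1, c1$p2, window, M)
  lab <- label_components(boundary)
  dist <- boundary_distance(boundary)
  ids <- sort(unique(lab[!is.na(lab)]))
  sizes <- table(lab)
  ids <- ids[sizes[as.character(ids)] >= min_cells]

  w1 <- window[2] - window[1]
  w2 <- window[4] - window[3]
  cell_center <- function(i, j)
    c(window[1] + (i - 0.5) / M * w1, window[3] + (j - 0.5) / M * w2)

  ## lattice censuses
  a_vals <- seq(window[1], window[2], length.out = resolution)
  b_vals <- seq(window[3], window[4], length.out = resolution)
  grid <- expand.grid(p1 = a_vals, p2 = b_vals)
  grid$tag <- NA_character_
  grid$face <- NA_integer_
  grid$exhaustive <- NA
  cache_tag <- function(a, b) {
    pp <- set_scan(set_scan(params, p1, a), p2, b)
    ## a coarser reporting step than the census default: periods here are
    ## tens of ms, so 0.2 ms still resolves every peak
    cs <- attractor_census(pp, ic_strategy = "targeted",
                           n_starts = n_starts, t_end = t_end,
                           dt_report = 0.2)
    list(tag = cs$regime_tag, exhaustive = cs$exhaustive)
  }
  for (r in seq_len(nrow(grid))) {
    i <- pmin(pmax(floor((grid$p1[r] - window[1]) / w1 * M) + 1, 1), M)
    j <- pmin(pmax(floor((grid$p2[r] - window[3]) / w2 * M) + 1, 1), M)
    grid$face[r] <- if (is.na(lab[i, j])) NA_integer_ else lab[i, j]
    cs <- cache_tag(grid$p1[r], grid$p2[r])
    grid$tag[r] <- cs$tag
    grid$exhaustive[r] <- cs$exhaustive
  }

  ## face table: majority lattice tag, or census at an interior
  ## representative for faces without lattice support
  faces <- data.frame(id = ids, rep_p1 = NA_real_, rep_p2 = NA_real_,
                      tag = NA_character_, n_lattice = 0L,
                      mismatch = FALSE)
  for (k in seq_along(ids)) {
    id <- ids[k]
    in_face <- which(grid$face == id & grid$exhaustive)
    ## representative: deepest interior cell of the face
    sel <- which(lab == id, arr.ind = TRUE)
    best <- sel[which.max(dist[sel]), ]
    ctr <- cell_center(best[1], best[2])
    faces$rep_p1[k] <- ctr[1]
    faces$rep_p2[k] <- ctr[2]
    faces$n_lattice[k] <- length(in_face)
    if (length(in_face)) {
      tags <- grid$tag[in_face]
      tt <- sort(table(tags), decreasing = TRUE)
      faces$tag[k] <- names(tt)[1]
      faces$mismatch[k] <- length(tt) > 1
    } else {
      faces$tag[k] <- cache_tag(ctr[1], ctr[2])$tag
    }
  }
  structure(list(p1 = p1, p2 = p2, window = window,
                 resolution = resolution, grid = grid, faces = faces,
                 curves = curves$curves, cusps = curves$cusps,
                 region_count = nrow(faces)),
            class = "bgct_regime_map")
}

#' @export
print.bgct_regime_map <- function(x, ...) {
  cat("Regime map in (", x$p1, ",", x$p2, "):", x$region_count,
      "regions\n")
  cat("  curves:", sum(vapply(x$curves, function(c1) c1$type == "fold",
                              logical(1))), "fold,",
      sum(vapply(x$curves, function(c1) c1$type == "hopf", logical(1))),
      "Hopf;  cusps:", if (is.null(x$cusps)) 0 else nrow(x$cusps), "\n")
  tab <- table(x$faces$tag)
  for (nm in names(tab))
    cat("  ", nm, ":", tab[[nm]], "region(s)\n")
  invisible(x)
}

#' Export a regime map as JSON plus a CSV label lattice
#'
#' @param rm_ a `bgct_regime_map`.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @export
write_regime_map <- function(rm_, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      p1 = rm_$p1, p2 = rm_$p2, window = rm_$window,
      region_count = rm_$region_count,
      faces = rm_$faces,
      curves = lapply(rm_$curves, function(c1)
        list(type = c1$type, p1 = c1$p1, p2 = c1$p2)),
      cusps = if (is.null(rm_$cusps)) list() else
        as.data.frame(rm_$cusps)
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    con <- file(csv_path, "w")
    writeLines("# regime-map lattice: weights dimensionless", con)
    utils::write.csv(rm_$grid, con, row.names = FALSE)
    close(con)
  }
  invisible(rm_)
}
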