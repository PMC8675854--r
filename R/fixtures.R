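## Reproducible synthetic fixtures --------------------------------------------

# pinned states for the drift regression fixture: fixed, hand-chosen
# points spanning the operating range (including a negative coordinate)
.bgct_pinned_states <- list(
  rep(0, 7),
  c(0.5, 1, 1.5, 2, 2.5, 3, 3.5),
  c(2, 2, 2, 2, 2, 2, 2),
  c(0.2235, 1.4135, 2.0518, 6.1041, 4.6253, 1.1525, 3.3391),
  c(1.5, 3, 4, -2, 5, 0.5, 2)
)

#' Generate the package's synthetic fixture bundle
#'
#' Writes, under `out_dir`:
#' \itemize{
#' \item `deterministic/` — time-series CSVs of every attractor at one
#'   representative `(T42, T53)` point per dynamical regime (stable
#'   steady states approached from a perturbation; limit cycles over a
#'   few periods),
#' \item `stochastic/` — seeded Langevin trajectory CSVs at a monostable
#'   and an oscillatory representative,
#' \item `drift_regression.csv` — the seven drift components at five
#'   pinned states under the default parameters, printed to full double
#'   precision,
#' \item `manifest.json` — the seed, representatives and file list.
#' }
#' The bundle is a deterministic function of `seed`: the same seed
#' reproduces it byte for byte.
#'
#' @param out_dir output directory (created if needed).
#' @param seed global seed; stage seeds derive from it via
#'   [stage_seed()].
#' @param representatives a data.frame with columns `tag`, `T42`, `T53`
#'   giving one point per regime.  By default a small built-in set of
#'   regime representatives (one per dynamical configuration of the
#'   direct/indirect-pathway plane) is used; pass the `faces` table of a
#'   [region_map()] run for a map-derived set.
#' @return invisibly, the manifest list.
#' @export
generate_fixtures <- function(out_dir, seed = 1,
                              representatives = NULL) {
  if (is.null(representatives)) representatives <- regime_representatives()
  stopifnot(all(c("tag", "T42", "T53") %in% names(representatives)))
  dir.create(file.path(out_dir, "deterministic"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "stochastic"), showWarnings = FALSE)
  files <- character(0)
  fmt <- function(df) {
    df[] <- lapply(df, function(v)
      if (is.numeric(v)) sprintf("%.17g", v) else v)
    df
  }
  put <- function(df, rel) {
    path <- file.path(out_dir, rel)
    utils::write.csv(fmt(df), path, row.names = FALSE, quote = FALSE)
    files <<- c(files, rel)
  }

  ## (a) deterministic series, one bundle per representative regime
  for (r in seq_len(nrow(representatives))) {
    p <- bgct_params(T42 = representatives$T42[r],
                     T53 = representatives$T53[r])
    cs <- attractor_census(p, n_box = 16)
    series <- list()
    for (i in seq_len(nrow(cs$equilibria))) {
      x <- as.numeric(cs$equilibria[i, paste0("x", 1:7)])
      tr <- integrate_bgct(p, x + 0.05, 600, dt_report = 0.5)
      series[[length(series) + 1]] <- cbind(series_id = length(series) + 1,
                                            kind = "steady_state", tr)
    }
    for (cc in cs$cycles) {
      x <- as.numeric(cc$sample_orbit[1, paste0("x", 1:7)])
      tr <- integrate_bgct(p, x, max(600, 5 * cc$period), dt_report = 0.5)
      series[[length(series) + 1]] <- cbind(series_id = length(series) + 1,
                                            kind = "limit_cycle", tr)
    }
    df <- do.call(rbind, series)
    put(df, file.path("deterministic",
                      sprintf("regime_%s_T42_%g_T53_%g.csv",
                              gsub("[+]", "_", cs$regime_tag),
                              representatives$T42[r],
                              representatives$T53[r])))
  }

  ## (b) seeded stochastic bundles at a monostable and an oscillatory point
  sseed <- stage_seed(seed, "fixtures")
  mono <- representatives[representatives$tag == "1SS+0LC", ][1, ]
  osc <- representatives[grepl("1LC|2LC", representatives$tag), ][1, ]
  k <- 0
  for (rp in list(mono, osc)) {
    k <- k + 1
    p <- bgct_params(T42 = rp$T42, T53 = rp$T53)
    eq <- find_equilibria(p)
    x0 <- as.numeric(eq[1, paste0("x", 1:7)])
    tr <- langevin_simulate(p, x0, 2000,
                            noise_spec(D = 1e-6, seed = sseed + k),
                            record_dt = 1)
    put(tr, file.path("stochastic",
                      sprintf("langevin_T42_%g_T53_%g_seed_%d.csv",
                              rp$T42, rp$T53, sseed + k)))
  }

  ## (c) drift regression fixture at default parameters
  p0 <- bgct_params()
  reg <- do.call(rbind, lapply(seq_along(.bgct_pinned_states), function(i) {
    x <- .bgct_pinned_states[[i]]
    data.frame(state_id = i,
               t(stats::setNames(x, paste0("x", 1:7))),
               t(stats::setNames(bgct_drift(x, p0), paste0("f", 1:7))))
  }))
  put(reg, "drift_regression.csv")

  man <- list(seed = seed, stage_seed = sseed,
              representatives = representatives, files = files,
              version = as.character(utils::packageVersion("bgctdyn")))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Built-in regime representatives in the (T42, T53) plane
#'
#' One interior point per stable dynamical configuration, chosen from the
#' package's own bifurcation analysis of the direct/indirect-pathway
#' plane (the published analysis does not print its representative
#' parameter choices, so these are this package's own).
#'
#' @return data.frame with columns `tag`, `T42`, `T53`.
#' @export
regime_representatives <- function() {
  data.frame(
    tag = c("1SS+0LC", "2SS+0LC", "0SS+1LC", "3SS+0LC", "1SS+1LC",
            "2SS+1LC", "0SS+2LC"),
    T42 = c(1.0, 2.0, 5.0, 4.5, 6.0, 5.5, 6.8),
    T53 = c(1.0, 0.0, 4.0, 6.0, 6.0, 7.0, 6.0),
    stringsAsFactors = FALSE
  )
}
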