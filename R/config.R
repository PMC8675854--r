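## Run configuration, manifests and seed fan-out ------------------------------

.bgct_stages <- c("census", "scan1d", "scan2d", "landscape", "fixtures")

#' Derive a per-stage seed from the global seed
#'
#' A single global seed fans out to one sub-seed per pipeline stage via a
#' fixed counter scheme, `(seed + 10007 * stage_index) mod (2^31 - 1)`,
#' so each stage is independently reproducible.
#'
#' @param seed global integer seed.
#' @param stage one of `"census"`, `"scan1d"`, `"scan2d"`, `"landscape"`,
#'   `"fixtures"`.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  i <- match(stage, .bgct_stages)
  if (is.na(i)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) + 10007 * i) %% 2147483647)
}

#' Load a run configuration file
#'
#' The configuration is a YAML mapping with optional keys:
#' `params_file` (a flat parameter file, see [read_params()]), `set`
#' (parameter overrides by canonical name), `stages` (subset of the
#' pipeline stages), `out_dir`, `seed`, and `tolerances` (named numeric
#' overrides passed through to the analysis functions).  Defaults are the
#' published typical values; unknown parameter names or invalid values
#' (e.g. a non-positive Hill index) are errors naming the key, while
#' weights outside the explored `[0, 7]` range are accepted with a
#' warning.
#'
#' @param path configuration file path.
#' @param overrides extra `name = value` parameter overrides applied on
#'   top of the file (e.g. from a command line).
#' @return a list of class `bgct_run_config` with elements `params`
#'   (a resolved [bgct_params()]), `stages`, `out_dir`, `seed`,
#'   `tolerances`, and `source`.
#' @export
load_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("malformed config file: ", path)
  if (!is.null(cfg$set)) names(cfg$set) <- fix_yaml_n(names(cfg$set))
  known <- c("params_file", "set", "stages", "out_dir", "seed",
             "tolerances")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  params <- if (!is.null(cfg$params_file)) {
    read_params(if (file.exists(cfg$params_file)) cfg$params_file
                else file.path(dirname(path), cfg$params_file))
  } else bgct_params()
  sets <- c(as.list(cfg$set), as.list(overrides))
  if (length(sets))
    params <- do.call(update_params, c(list(params), sets))
  stages <- cfg$stages %||% .bgct_stages
  bad <- setdiff(stages, .bgct_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(params = params, stages = stages,
                 out_dir = cfg$out_dir %||% ".",
                 seed = as.integer(cfg$seed %||% 1L),
                 tolerances = as.list(cfg$tolerances),
                 source = normalizePath(path)),
            class = "bgct_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML 1.1 parses a bare key `n` as the boolean FALSE; restore it, since
# `n` (the Hill index) is a legitimate parameter key
fix_yaml_n <- function(nms) {
  nms[nms %in% c("FALSE", "no")] <- "n"
  nms
}

#' Write a run manifest
#'
#' Echoes the fully resolved configuration (every parameter value, stage
#' seeds, package version) as JSON next to a run's outputs, so any run
#' can be reproduced exactly from its manifest.
#'
#' @param config a `bgct_run_config` (or parameters via `params`).
#' @param path output JSON path.
#' @param extra optional named list of additional fields to record.
#' @export
write_manifest <- function(config, path, extra = list()) {
  stopifnot(inherits(config, "bgct_run_config"))
  man <- list(
    package = "bgctdyn",
    version = as.character(utils::packageVersion("bgctdyn")),
    parameters = as.list(unclass(config$params)),
    stages = config$stages,
    seed = config$seed,
    stage_seeds = stats::setNames(
      lapply(.bgct_stages, function(s) stage_seed(config$seed, s)),
      .bgct_stages),
    tolerances = config$tolerances,
    out_dir = config$out_dir
  )
  jsonlite::write_json(c(man, extra), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
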