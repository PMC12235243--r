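config_cell_keys <- c("label", "mu_m", "K_sr", "K_50", "sd_e")
config_process_keys <- c("X_s", "X_m", "S", "n_flask_init", "n_flask_max",
                         "Np_grid", "th_grid", "psene_min", "pconf_max",
                         "ncell_min", "M", "pi", "xm_cv", "seed")

#' Load a cell-source / process configuration file
#'
#' Reads a YAML file with two blocks, `cell_source` (keys `label`, `mu_m`,
#' `K_sr`, `K_50`, `sd_e`) and `process` (keys matching the arguments of
#' [process_config()]). Unknown keys are rejected so typos cannot silently
#' fall back to defaults; omitted `process` keys take the case-study
#' defaults. Two fixture configurations ship with the package:
#' `system.file("extdata", "bm.yaml", package = "mscpassage")` (bone-marrow
#' MSCs) and `"uc.yaml"` (umbilical-cord MSCs).
#'
#' @param path Path to a YAML configuration file.
#' @return A list with elements `params` ([cell_source_params()]) and
#'   `config` ([process_config()]).
#' @examples
#' bm <- load_config(system.file("extdata", "bm.yaml", package = "mscpassage"))
#' bm$params
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("cell_source", "process"))
  if (length(bad))
    stop("unknown top-level key(s): ", paste(bad, collapse = ", "))
  if (is.null(raw$cell_source)) stop("missing 'cell_source' block")

  cs <- raw$cell_source
  bad <- setdiff(names(cs), config_cell_keys)
  if (length(bad))
    stop("unknown cell_source key(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(setdiff(config_cell_keys, "label"), names(cs))
  if (length(missing))
    stop("missing cell_source key(s): ", paste(missing, collapse = ", "))
  params <- cell_source_params(as.numeric(cs$mu_m), as.numeric(cs$K_sr),
                               as.numeric(cs$K_50), as.numeric(cs$sd_e),
                               label = if (is.null(cs$label)) "cells" else cs$label)

  pr <- if (is.null(raw$process)) list() else raw$process
  bad <- setdiff(names(pr), config_process_keys)
  if (length(bad))
    stop("unknown process key(s): ", paste(bad, collapse = ", "))
  config <- do.call(process_config, lapply(pr, unlist))
  list(params = params, config = config)
}

#' Write a configuration file
#'
#' Serialises a parameter set and process configuration back to the YAML
#' schema read by [load_config()]; `load_config(write_config(...))` is an
#' identity on the stored values.
#'
#' @param params A [cell_source_params()] object.
#' @param config A [process_config()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, config, path) {
  stopifnot(inherits(params, "cell_source_params"),
            inherits(config, "process_config"))
  out <- list(
    cell_source = list(label = params$label, mu_m = params$mu_m,
                       K_sr = params$K_sr, K_50 = params$K_50,
                       sd_e = params$sd_e),
    process = unclass(config))
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read growth-rate observations from delimited text
#'
#' Expects a header with columns `sample_id`, `passage`, `cPDL`, `mu_exp`.
#'
#' @param path Input path (CSV).
#' @return A validated observations data frame.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observations file not found: ", path)
  validate_observations(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write growth-rate observations to delimited text
#'
#' @param observations Observations data frame (or a `synthetic_experiment`,
#'   whose `$observations` are written).
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  if (inherits(observations, "synthetic_experiment"))
    observations <- observations$observations
  observations <- validate_observations(observations)
  utils::write.csv(observations[, c("sample_id", "passage", "cPDL", "mu_exp")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a passage trajectory to delimited text
#'
#' Columns: `passage`, `mu`, `Xh`, `PDL`, `cPDL`, `nflask`.
#'
#' @param run A `passage_run` from [run_passage_culture()] (or its
#'   trajectory data frame).
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(run, path) {
  traj <- if (inherits(run, "passage_run")) run$trajectory else run
  utils::write.csv(traj[, c("passage", "mu", "Xh", "PDL", "cPDL", "nflask")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a probability map in long format
#'
#' One row per grid cell with provenance columns
#' (`cell_source`, `Np`, `th`, `spec`, `h`, `M`, `seed`). Harvesting times
#' are printed with two decimals (the grid is 0.25-day stepped).
#'
#' @param map A map from [probability_map()], or the `maps` element of a
#'   [determine_design_space()] result.
#' @param path Output path (CSV).
#' @param spec Specification label recorded in the file (defaults to the
#'   map's own, else `"A"`).
#' @return `path`, invisibly.
#' @export
write_probability_map <- function(map, path, spec = NULL) {
  if (is.null(spec)) spec <- attr(map, "spec")
  if (is.null(spec)) spec <- "A"
  n <- nrow(map)
  out <- data.frame(cell_source = rep_len(attr(map, "label"), n),
                    Np = map$Np, th = sprintf("%.2f", map$th),
                    spec = rep_len(spec, n), h = map$h,
                    M = rep_len(attr(map, "M"), n),
                    seed = rep_len(attr(map, "seed"), n))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a design-space report as JSON
#'
#' Compact report listing the feasible cells with their probabilities plus
#' run provenance (`pi`, `M`, `seed`, cell source).
#'
#' @param ds A `design_space` from [determine_design_space()].
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_ds_report <- function(ds, path) {
  stopifnot(inherits(ds, "design_space"))
  report <- list(cell_source = ds$label, pi = ds$pi, M = ds$M,
                 seed = ds$seed,
                 n_grid = nrow(ds$maps), n_feasible = nrow(ds$feasible),
                 feasible = ds$feasible)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
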