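CONFIG_KEYS <- c("preset", "params", "experiment", "grids", "seed",
                 "out_dir", "control", "verbose")

EXPERIMENTS <- c("run", "sweep-kcn", "sweep-pathway", "heatmap", "ic-scan",
                 "stochastic", "sugar-variant", "co2-scan")

#' Load a run configuration
#'
#' Reads a YAML run configuration. Every key is optional; defaults come from
#' the standard preset. Recognized top-level keys: `preset` (one of
#' `"standard"`, `"slow_kcn"`, `"fast_kcn"`, `"null"`), `params` (named
#' overrides as in [protocell_params()], with `k_in` / `n_c2` as nested
#' maps), `experiment` (one of `run`, `sweep-kcn`, `sweep-pathway`,
#' `heatmap`, `ic-scan`, `stochastic`, `sugar-variant`, `co2-scan`),
#' `grids` (per-experiment grid definitions), `seed`, `out_dir`, `control`
#' (overrides for [sim_control()]) and `verbose`. Unknown keys are rejected.
#' Numbers accept scientific notation; grids accept either an explicit list
#' or a `{start, stop, n, scale: linear|log}` map.
#'
#' @param path Path to a YAML file. An empty file yields the full defaults.
#' @return A list of class `"protocell_config"` with fields `params`
#'   (validated `"protocell_params"`), `preset`, `experiment`, `grids`,
#'   `seed`, `out_dir`, `control`, `verbose`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "protoflux_config_error")
  }
  ## Keep YAML 1.1 boolean-like scalars ("n", "y", "yes", ...) as strings:
  ## "n" is a species key in this model, not a logical. Booleans and
  ## scientific-notation numbers are re-coerced field by field below.
  keep <- function(x) x
  raw <- tryCatch(yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                                        "bool#no" = keep)),
                  error = function(e)
                    abort(sprintf("cannot parse config %s: %s", path,
                                  conditionMessage(e)),
                          class = "protoflux_config_error"))
  if (is.null(raw)) raw <- list()
  as_config(raw)
}

## YAML 1.1 resolves "1.0e3" (no sign in the exponent) as a string; accept
## scientific notation by re-coercing numeric-looking character scalars.
coerce_numbers <- function(x) {
  if (is.list(x)) return(lapply(x, coerce_numbers))
  if (is.character(x)) {
    v <- suppressWarnings(as.numeric(x))
    if (all(!is.na(v))) return(stats::setNames(v, names(x)))
  }
  x
}

as_bool <- function(x) {
  isTRUE(x) || (is.character(x) && tolower(x) %in% c("true", "yes", "y", "on"))
}

as_config <- function(raw) {
  bad <- setdiff(names(raw), CONFIG_KEYS)
  if (length(bad) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
          class = "protoflux_config_error")
  }
  preset_name <- raw$preset %||% "standard"
  p <- preset(preset_name)
  if (!is.null(raw$params)) {
    bad <- setdiff(names(raw$params), names(unclass(p)))
    if (length(bad) > 0) {
      abort(sprintf("unknown parameter key(s): %s", paste(bad, collapse = ", ")),
            class = "protoflux_config_error")
    }
    overrides <- lapply(raw$params, function(v)
      if (is.list(v)) unlist(coerce_numbers(v)) else coerce_numbers(v))
    p <- do.call(update_params, c(list(p), overrides))
  }
  experiment <- raw$experiment
  if (!is.null(experiment) && !experiment %in% EXPERIMENTS) {
    abort(sprintf("unknown experiment '%s' (use one of: %s)", experiment,
                  paste(EXPERIMENTS, collapse = ", ")),
          class = "protoflux_config_error")
  }
  control <- do.call(experiment_control,
                     lapply(as.list(raw$control %||% list()), coerce_numbers))
  raw_grids <- lapply(raw$grids %||% list(), coerce_numbers)
  ## "pathway" and "n_seeds" ride along in the grids block but are not
  ## numeric axes.
  grids <- lapply(seq_along(raw_grids), function(i) {
    if (names(raw_grids)[i] %in% c("pathway")) as.character(raw_grids[[i]])
    else if (names(raw_grids)[i] %in% c("n_seeds")) as.integer(raw_grids[[i]])
    else parse_grid(raw_grids[[i]])
  })
  names(grids) <- names(raw_grids)
  structure(
    list(params = p, preset = preset_name, experiment = experiment,
         grids = grids, seed = as.integer(coerce_numbers(raw$seed %||% 1L)),
         out_dir = raw$out_dir %||% ".",
         control = control, verbose = as_bool(raw$verbose)),
    class = "protocell_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a grid definition
#'
#' Accepts an explicit numeric vector/list, or a `{start, stop, n, scale}`
#' quadruple where `scale` is `"linear"` (default) or `"log"` (log-spaced
#' between `start` and `stop`).
#'
#' @param g Grid definition.
#' @return Numeric vector.
#' @export
parse_grid <- function(g) {
  if (is.numeric(g)) return(as.numeric(g))
  if (is.list(g) && is.null(names(g))) return(as.numeric(unlist(g)))
  if (is.list(g) && all(c("start", "stop", "n") %in% names(g))) {
    scale <- g$scale %||% "linear"
    if (scale == "log") {
      if (g$start <= 0 || g$stop <= 0) {
        abort("log grids need positive endpoints",
              class = "protoflux_config_error")
      }
      return(10^seq(log10(g$start), log10(g$stop), length.out = g$n))
    }
    if (scale == "linear") {
      return(seq(g$start, g$stop, length.out = g$n))
    }
    abort(sprintf("unknown grid scale '%s'", scale),
          class = "protoflux_config_error")
  }
  abort("a grid is either a list of numbers or {start, stop, n, scale}",
        class = "protoflux_config_error")
}

#' Write a run configuration
#'
#' Serializes a `"protocell_config"` back to YAML such that
#' [load_config()] reproduces it (round-trip identity on all fields).
#'
#' @param config A `"protocell_config"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- config_as_list(config)
  yaml::write_yaml(raw, path, precision = 17)
  invisible(path)
}

config_as_list <- function(config) {
  p <- unclass(config$params)
  list(
    preset = config$preset,
    params = lapply(p, function(v)
      if (!is.null(names(v))) as.list(v) else unname(v)),
    experiment = config$experiment,
    grids = config$grids,
    seed = config$seed,
    out_dir = config$out_dir,
    control = unclass(config$control),
    verbose = config$verbose)
}

#' @export
print.protocell_config <- function(x, ...) {
  cat(sprintf("<protocell_config> preset=%s experiment=%s seed=%s out_dir=%s\n",
              x$preset, x$experiment %||% "(none)", x$seed, x$out_dir))
  invisible(x)
}

#' Run the experiment named in a configuration
#'
#' Dispatches to the experiment layer, writes the result table as RFC-4180
#' CSV into `out_dir`, and writes a sibling JSON manifest carrying the full
#' effective configuration (parameters, grids, seed, control settings and
#' package version) so the run can be reproduced bit-identically.
#'
#' @param config A `"protocell_config"` (see [load_config()]).
#' @param out_dir Optional override of the configured output directory.
#' @return Invisibly, a list with the result object and the paths written.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.null(config$experiment)) {
    abort("configuration names no experiment", class = "protoflux_config_error")
  }
  out_dir <- out_dir %||% config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- config$params
  ctl <- config$control
  g <- config$grids
  name <- config$experiment
  result <- switch(
    name,
    "run" = {
      lin <- run_lineage(p, control = ctl)
      ss <- steady_state(lin)
      dplyr::bind_cols(glance(ss),
                       tibble(!!!setNames(
                         as.list(unname(ss$eq_concentrations[SPECIES])),
                         paste0("eq_", SPECIES))))
    },
    "sweep-kcn" = sweep_kcn(p, kcn_grid = g$kcn %||% c(0, 10^(0:4)),
                            control = ctl),
    "sweep-pathway" = sweep_pathway(
      p, pathway = g$pathway %||% "aa",
      kin_grid = g$kin %||% c(0, 0.33, 0.66, 0.99), control = ctl),
    "heatmap" = heatmap_autocatalysis(
      p, knn_grid = g$knn %||% 10^seq(-2, 4, length.out = 13),
      kcn_grid = g$kcn %||% 10^seq(0, 4, length.out = 13), control = ctl),
    "ic-scan" = initial_condition_scan(
      p, scale_grid = g$scale %||% c(0.1, 1, 10),
      skew_grid = g$skew %||% c(0.25, 1, 4), control = ctl),
    "stochastic" = stochastic_segregation(
      p, noise_grid = g$noise %||% c(0, 0.25, 0.5, 0.75, 1),
      n_seeds = g$n_seeds %||% 20, base_seed = config$seed, control = ctl),
    "sugar-variant" = sugar_cost_variant(
      p, n_c2_s_grid = g$n_c2_s %||% c(1, 8),
      kin_grid = g$kin %||% c(0, 0.33, 0.66, 0.99), control = ctl),
    "co2-scan" = co2_scan(p, co2_grid = g$co2 %||% c(0, 0.5, 1, 2),
                          control = ctl)
  )
  tbl <- if (inherits(result, "protocell_heatmap")) result$table else result
  stem <- gsub("-", "_", name)
  csv_path <- file.path(out_dir, paste0(stem, ".csv"))
  manifest_path <- file.path(out_dir, paste0(stem, "_manifest.json"))
  write.csv(as.data.frame(tbl), csv_path, row.names = FALSE)
  manifest <- c(config_as_list(config),
                list(package_version = as.character(utils::packageVersion("protoflux")),
                     output = basename(csv_path)))
  ## 17 significant digits so every double round-trips bit-identically
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(list(result = result, csv = csv_path, manifest = manifest_path))
}
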