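# CSV / YAML / JSON interfaces. Tabular data travel as comma-separated
# UTF-8 with a required header; configurations as YAML; single results as
# JSON. A missing occasion-2 diameter (dead tree) is an empty field, never 0.

tree_cols <- c(plot_id = "plot_id", tree_id = "tree_id", dbh_t1 = "dbh_t1_cm",
               alive_t2 = "alive_t2", dbh_t2 = "dbh_t2_cm")

#' Read a tree table
#'
#' Expects columns `plot_id,tree_id,dbh_t1_cm,alive_t2,dbh_t2_cm` (the last
#' empty for dead trees) and validates the population invariants: diameters
#' above the calliper threshold, no shrinkage, no diameter on dead trees, no
#' duplicate tree ids.
#'
#' @param path CSV file path.
#' @param plot_area_m2 Plot area, m2.
#' @param n_plots Population size; defaults to the largest plot id.
#' @param dbh_min Calliper threshold used for validation, cm.
#' @return A `tree_population` tibble.
#' @export
read_tree_table <- function(path, plot_area_m2 = 400, n_plots = NULL,
                            dbh_min = 15) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  miss <- setdiff(unname(tree_cols), header)
  if (length(miss)) {
    abort(paste0(path, ": missing columns: ", paste(miss, collapse = ", ")))
  }
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          plot_id = readr::col_integer(),
                          tree_id = readr::col_integer(),
                          dbh_t1_cm = readr::col_double(),
                          alive_t2 = readr::col_logical(),
                          dbh_t2_cm = readr::col_double()
                        ))
  names(df)[match(unname(tree_cols), names(df))] <- names(tree_cols)
  as_tree_population(df, n_plots = n_plots, plot_area_m2 = plot_area_m2,
                     dbh_min = dbh_min)
}

#' Write a tree table
#'
#' @param pop A `tree_population`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tree_table <- function(pop, path) {
  df <- as_tibble(pop)
  names(df)[match(names(tree_cols), names(df))] <- unname(tree_cols)
  readr::write_csv(df, path, na = "")
  invisible(path)
}

panel_cols <- c(plot_id = "plot_id", x_t1 = "x_t1_tha",
                y_t2_undisturbed = "y_t2_undist_tha",
                y_t2_disturbed = "y_t2_dist_tha",
                affected = "affected", scenario = "scenario")

#' Read / write a plot panel
#'
#' Columns `plot_id,x_t1_tha,y_t2_undist_tha,y_t2_dist_tha,affected,scenario`.
#'
#' @param path CSV file path.
#' @return [read_plot_panel()]: a plot panel tibble.
#' @export
read_plot_panel <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(unname(panel_cols), names(df))
  if (length(miss)) {
    abort(paste0(path, ": missing columns: ", paste(miss, collapse = ", ")))
  }
  names(df)[match(unname(panel_cols), names(df))] <- names(panel_cols)
  if (any(df$y_t2_disturbed > df$y_t2_undisturbed + 1e-9)) {
    abort(paste0(path, ": disturbed occasion-2 biomass exceeds undisturbed"))
  }
  df
}

#' @rdname read_plot_panel
#' @param panel A plot panel tibble.
#' @export
write_plot_panel <- function(panel, path) {
  df <- panel
  names(df)[match(names(panel_cols), names(df))] <- unname(panel_cols)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read / write generator parameters as YAML
#'
#' @param path YAML file mirroring the [population_params()] field names.
#' @return [read_population_params()]: a `population_params` list.
#' @export
read_population_params <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(population_params))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    abort(paste0(path, ": unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(population_params, y)
}

#' @rdname read_population_params
#' @param params A `population_params` list.
#' @export
write_population_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' Read / write scenario definitions as YAML
#'
#' The file holds a list of entries with `name`, `fraction`, `rule` and
#' (for threshold rules) `threshold`.
#'
#' @param path YAML file path.
#' @return [read_scenarios()]: named list of [scenario_spec()].
#' @export
read_scenarios <- function(path) {
  y <- yaml::read_yaml(path)
  specs <- lapply(y, function(e) do.call(scenario_spec, e))
  setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' @rdname read_scenarios
#' @param scenarios List of [scenario_spec()].
#' @export
write_scenarios <- function(scenarios, path) {
  yaml::write_yaml(lapply(unname(scenarios), function(s) {
    s <- unclass(s)
    s[!vapply(s, is.null, TRUE)]
  }), path)
  invisible(path)
}

#' Read design definitions as YAML
#'
#' @param path YAML file with a list of `design`, `n_t1_only`,
#'   `n_permanent`, `n_t2_only` entries.
#' @return Named list of [design_spec()].
#' @export
read_designs <- function(path) {
  y <- yaml::read_yaml(path)
  specs <- lapply(y, function(e) do.call(design_spec, e))
  setNames(specs, vapply(specs, `[[`, "", "design"))
}

#' Read an experiment configuration
#'
#' YAML with blocks: `population` (either `params: {...}` inline or
#' `trees: path.csv`), `scenarios` (inline list or `file:`), `designs`
#' (inline list or `file:`), and scalars `iterations`, `master_seed`,
#' `spr_variance_mode`.
#'
#' @param path YAML file path.
#' @return A list ready to drive [run_experiment()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- list(
    iterations = y$iterations %||% 1000,
    master_seed = y$master_seed %||% 1,
    spr_mode = y$spr_variance_mode %||% "corrected"
  )
  if (cfg$iterations < 1) abort("`iterations` must be >= 1")
  popblock <- y$population %||% list()
  if (!is.null(popblock$trees)) {
    cfg$pop <- read_tree_table(file.path(dirname(path), popblock$trees))
    cfg$pop_seed <- NULL
  } else {
    cfg$params <- do.call(population_params, popblock$params %||% list())
    cfg$pop_seed <- popblock$seed %||% NULL
  }
  cfg$scenarios <- if (is.null(y$scenarios)) {
    default_scenarios()
  } else if (!is.null(y$scenarios$file)) {
    read_scenarios(file.path(dirname(path), y$scenarios$file))
  } else {
    specs <- lapply(y$scenarios, function(e) do.call(scenario_spec, e))
    setNames(specs, vapply(specs, `[[`, "", "name"))
  }
  cfg$designs <- if (is.null(y$designs)) {
    default_designs()
  } else if (!is.null(y$designs$file)) {
    read_designs(file.path(dirname(path), y$designs$file))
  } else {
    specs <- lapply(y$designs, function(e) do.call(design_spec, e))
    setNames(specs, vapply(specs, `[[`, "", "design"))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write Monte Carlo results with a run manifest
#'
#' Writes `iterations.csv` (iteration-level results), `summary.csv`
#' (per-cell aggregates) and `manifest.json` tying both to a configuration
#' hash, the master seed and the package version.
#'
#' @param results An `mc_results` tibble.
#' @param dir Output directory (created if absent).
#' @param config The configuration object that produced `results` (hashed
#'   into the manifest).
#' @param master_seed Master seed of the run.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(results, dir, config = list(), master_seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(results, file.path(dir, "iterations.csv"))
  summary_tab <- if (nrow(results) &&
                     min(table(results$scenario, results$design, results$bias)) >= 2) {
    summarize_experiment(results)
  } else {
    tibble(scenario = character(), design = character(), bias = logical())
  }
  readr::write_csv(summary_tab, file.path(dir, "summary.csv"))
  counts <- if (nrow(results)) {
    results %>%
      dplyr::count(.data$scenario, .data$design, .data$bias, name = "iterations")
  } else {
    tibble(scenario = character(), design = character(), bias = logical(),
           iterations = integer())
  }
  manifest <- list(
    config_hash = rlang::hash(config),
    master_seed = master_seed,
    package_version = as.character(packageVersion("sprforest")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    cells = counts
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}
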