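#' Read a run configuration from YAML
#'
#' A run configuration holds the grid specification (any [sim_condition()]
#' field may be a list, expanded factorially), a master seed, the alpha
#' thresholds, and an optional replicate override. Unknown keys are rejected
#' so typos fail loudly. The configuration round-trips losslessly through
#' [yaml::write_yaml()].
#'
#' @param path Path to a YAML file.
#' @return A named list of class `sib_run_config` with elements `grid`
#'   (named list of field vectors), `seed`, `alpha`, `reps`, `strict`.
#' @examples
#' cfg_file <- system.file("extdata", "example-grid.yaml", package = "sibcontrol")
#' read_run_config(cfg_file)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "sibcontrol_config_error")
  }
  raw <- yaml::read_yaml(path)
  known_top <- c("grid", "seed", "alpha", "reps", "strict")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    abort(
      paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
      class = "sibcontrol_config_error"
    )
  }
  grid <- raw$grid %||% list()
  grid_fields <- c(
    "n_pairs", "n_reps", "rho_obs", "reliability", "beta",
    "outcome_kind", "symmetry", "shared_outcome_frac", "loading", "k_siblings"
  )
  unknown <- setdiff(names(grid), grid_fields)
  if (length(unknown)) {
    abort(
      paste0("Unknown grid field(s): ", paste(unknown, collapse = ", ")),
      class = "sibcontrol_config_error"
    )
  }
  structure(
    list(
      grid = lapply(grid, unlist),
      seed = as.integer(raw$seed %||% 1L),
      alpha = as.numeric(unlist(raw$alpha %||% c(0.05, 0.01, 0.001))),
      reps = if (!is.null(raw$reps)) as.integer(raw$reps) else NULL,
      strict = isTRUE(raw$strict)
    ),
    class = "sib_run_config"
  )
}

#' Expand a run configuration into a condition table
#'
#' Applies [condition_grid()] to the configured grid lists. Under
#' `strict: true` any infeasible cell (observed correlation above
#' reliability) is an error; otherwise such cells are flagged and skipped
#' downstream.
#'
#' @param config A `sib_run_config` from [read_run_config()].
#' @return A condition tibble as from [condition_grid()].
#' @export
conditions_from_config <- function(config) {
  stopifnot(inherits(config, "sib_run_config"))
  args <- config$grid
  if (!is.null(config$reps)) args$n_reps <- config$reps
  args$seed <- config$seed
  conds <- do.call(condition_grid, args)
  if (config$strict && any(!conds$feasible)) {
    abort(
      sprintf(
        "Strict mode: %d impossible grid cell(s) (observed correlation exceeds reliability).",
        sum(!conds$feasible)
      ),
      class = "sibcontrol_impossible_condition"
    )
  }
  conds
}
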