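#' True sibling exposure correlation implied by an observed correlation
#'
#' Classical measurement error is uncorrelated between siblings, so it dilutes
#' the observed correlation between two siblings' exposure measures relative to
#' the correlation of their error-free (true) exposures. The true correlation
#' is the observed correlation divided by the reliability of the measure.
#'
#' @param rho_obs Observed correlation between siblings' measured exposures,
#'   in `[0, 1)`.
#' @param reliability Reliability of the exposure measure (true-score variance
#'   over total variance), in `(0, 1]`.
#'
#' @return The implied true-score correlation `rho_obs / reliability`.
#'   Vectorized over both arguments.
#'
#' @details A combination with `rho_obs > reliability` would imply a true
#'   correlation above one and is rejected with an error of class
#'   `"sibcontrol_impossible_condition"`. Such cells arise, e.g., for
#'   monozygotic-twin exposures observed at correlation 0.8 under an
#'   instrument with reliability 0.7.
#'
#' @examples
#' true_correlation(0.6, 0.6) # 1: siblings' true exposures are identical
#' true_correlation(0.4, 1.0) # perfect measurement, observed = true
#' @export
true_correlation <- function(rho_obs, reliability) {
  stopifnot(is.numeric(rho_obs), is.numeric(reliability))
  if (any(rho_obs < 0 | rho_obs >= 1)) {
    abort("`rho_obs` must lie in [0, 1).", class = "sibcontrol_bad_parameter")
  }
  if (any(reliability <= 0 | reliability > 1)) {
    abort("`reliability` must lie in (0, 1].", class = "sibcontrol_bad_parameter")
  }
  rho_t <- rho_obs / reliability
  if (any(rho_t > 1 + 1e-12)) {
    bad <- which(rho_t > 1 + 1e-12)[1L]
    abort(
      sprintf(
        paste0(
          "Impossible condition: observed correlation %.3g exceeds ",
          "reliability %.3g, implying a true sibling correlation above one."
        ),
        rho_obs[bad], reliability[bad]
      ),
      class = "sibcontrol_impossible_condition"
    )
  }
  pmin(rho_t, 1)
}

#' Define one simulation condition
#'
#' A condition is one cell of the study design: the family structure, the
#' measurement properties of the exposure, the true causal effect, and the
#' outcome model. All latent scales are standardized (mean 0, variance 1).
#'
#' @param n_pairs Number of families (sibling pairs by default).
#' @param n_reps Number of Monte Carlo replicates the condition is meant to be
#'   run for.
#' @param rho_obs Observed sibling correlation of the measured exposure.
#' @param reliability Exposure reliability \eqn{\lambda}: true-score variance
#'   over total observed variance. `1 - reliability` is the fraction of
#'   observed exposure variance that is measurement error.
#' @param beta True causal effect of the (true) exposure on the latent outcome,
#'   both on standardized scales. Must satisfy `beta^2 <= 1`.
#' @param outcome_kind `"single_item"` (one 5-category ordinal item, analysed
#'   by ordered probit) or `"aggregate5"` (mean of five ordinal items, analysed
#'   by a random-intercept linear model).
#' @param symmetry Marginal shape of the ordinal response categories:
#'   `"symmetric"`, `"moderate"`, or `"high"` asymmetry (see
#'   [symmetry_props()]).
#' @param shared_outcome_frac Fraction of the residual latent-outcome variance
#'   that is shared within family. Default 0: outcome clustering then arises
#'   only through the correlated true exposures.
#' @param loading Standardized loading of each ordinal item on the latent
#'   outcome for `aggregate5` outcomes (default 0.7, so the latent factor
#'   explains 49% of each item's variance).
#' @param k_siblings Siblings per family (default 2).
#' @param seed Master seed for this condition; replicate `r` uses a
#'   deterministically derived sub-seed so replicates are individually
#'   reproducible and order-independent.
#'
#' @return A one-row tibble of class `sib_condition`.
#' @seealso [condition_grid()] to expand factorial designs, and
#'   [simulate_siblings()] to draw data.
#' @examples
#' sim_condition(n_pairs = 500, rho_obs = 0.4, reliability = 0.7)
#' @export
sim_condition <- function(n_pairs = 2000,
                          n_reps = 500,
                          rho_obs = 0.4,
                          reliability = 1,
                          beta = 0.3,
                          outcome_kind = c("single_item", "aggregate5"),
                          symmetry = c("symmetric", "moderate", "high"),
                          shared_outcome_frac = 0,
                          loading = 0.7,
                          k_siblings = 2,
                          seed = 1L) {
  outcome_kind <- rlang::arg_match(outcome_kind)
  symmetry <- rlang::arg_match(symmetry)
  cond <- tibble::tibble(
    n_pairs = as.integer(n_pairs),
    n_reps = as.integer(n_reps),
    rho_obs = as.numeric(rho_obs),
    reliability = as.numeric(reliability),
    beta = as.numeric(beta),
    outcome_kind = outcome_kind,
    symmetry = symmetry,
    shared_outcome_frac = as.numeric(shared_outcome_frac),
    loading = as.numeric(loading),
    k_siblings = as.integer(k_siblings),
    seed = as.integer(seed)
  )
  validate_condition(cond)
  class(cond) <- c("sib_condition", class(cond))
  cond
}

validate_condition <- function(cond) {
  stopifnot(nrow(cond) == 1L)
  if (cond$n_pairs < 1L) {
    abort("`n_pairs` must be a positive integer.", class = "sibcontrol_bad_parameter")
  }
  if (cond$n_reps < 1L) {
    abort("`n_reps` must be a positive integer.", class = "sibcontrol_bad_parameter")
  }
  if (cond$k_siblings < 2L) {
    abort("`k_siblings` must be at least 2.", class = "sibcontrol_bad_parameter")
  }
  if (cond$beta^2 > 1) {
    abort(
      "`beta^2` must not exceed 1: the latent outcome has unit variance.",
      class = "sibcontrol_bad_parameter"
    )
  }
  if (cond$shared_outcome_frac < 0 || cond$shared_outcome_frac > 1) {
    abort("`shared_outcome_frac` must lie in [0, 1].", class = "sibcontrol_bad_parameter")
  }
  if (cond$loading^2 >= 1 || cond$loading <= 0) {
    abort("`loading` must lie in (0, 1).", class = "sibcontrol_bad_parameter")
  }
  # signals sibcontrol_impossible_condition when rho_obs > reliability
  true_correlation(cond$rho_obs, cond$reliability)
  invisible(cond)
}

#' Is a condition feasible?
#'
#' A condition is infeasible ("impossible") when the observed sibling
#' correlation exceeds the exposure reliability, which would imply a true
#' correlation above one.
#'
#' @param rho_obs,reliability Vectors of observed correlations and
#'   reliabilities.
#' @return Logical vector.
#' @export
is_feasible_condition <- function(rho_obs, reliability) {
  rho_obs <= reliability + 1e-12
}

#' Expand a factorial grid of simulation conditions
#'
#' Takes vectors for each design dimension and returns their Cartesian
#' product as a tibble of conditions, one row per cell. Infeasible cells
#' (observed correlation above reliability) are retained but flagged
#' `feasible = FALSE` with a reason, so a whole grid never fails because of
#' one impossible corner; duplicated cells are dropped with a warning.
#'
#' @inheritParams sim_condition
#' @param seed Single master seed; each cell receives a deterministic
#'   sub-seed derived from it, so cells are reproducible in any run order.
#' @return A tibble with one row per condition, the columns of
#'   [sim_condition()] plus `condition_id`, `feasible`, and `reason`.
#' @examples
#' condition_grid(reliability = c(1, 0.8), rho_obs = c(0.2, 0.4))
#' @export
condition_grid <- function(n_pairs = 2000,
                           n_reps = 500,
                           rho_obs = 0.4,
                           reliability = 1,
                           beta = 0.3,
                           outcome_kind = "single_item",
                           symmetry = "symmetric",
                           shared_outcome_frac = 0,
                           loading = 0.7,
                           k_siblings = 2,
                           seed = 1L) {
  dims <- list(
    n_pairs = n_pairs, n_reps = n_reps, rho_obs = rho_obs,
    reliability = reliability, beta = beta, outcome_kind = outcome_kind,
    symmetry = symmetry, shared_outcome_frac = shared_outcome_frac,
    loading = loading, k_siblings = k_siblings
  )
  empty <- vapply(dims, length, 1L) == 0L
  if (any(empty)) {
    abort(
      paste0("Empty grid dimension(s): ", paste(names(dims)[empty], collapse = ", ")),
      class = "sibcontrol_config_error"
    )
  }
  grid <- tidyr::expand_grid(!!!dims)
  ndup <- nrow(grid) - nrow(dplyr::distinct(grid))
  if (ndup > 0L) {
    warn(sprintf("Dropping %d duplicated grid cell(s).", ndup))
    grid <- dplyr::distinct(grid)
  }
  grid <- grid |>
    dplyr::mutate(
      condition_id = dplyr::row_number(),
      seed = derive_seed(as.integer(seed)[1L], .data$condition_id),
      feasible = is_feasible_condition(.data$rho_obs, .data$reliability),
      reason = dplyr::if_else(
        .data$feasible, NA_character_,
        "impossible: observed correlation exceeds reliability"
      )
    ) |>
    dplyr::relocate("condition_id")
  grid
}

#' @export
print.sib_condition <- function(x, ...) {
  cat(sprintf(
    "<sib_condition> %d families x %d siblings, %s/%s outcome\n",
    x$n_pairs, x$k_siblings, x$outcome_kind, x$symmetry
  ))
  NextMethod()
}
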