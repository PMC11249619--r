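condition_cols <- c(
  "n_pairs", "n_reps", "rho_obs", "reliability", "beta",
  "outcome_kind", "symmetry", "shared_outcome_frac", "loading",
  "k_siblings", "seed"
)

as_condition_tbl <- function(conditions) {
  stopifnot(is.data.frame(conditions), all(condition_cols %in% names(conditions)))
  out <- tibble::as_tibble(conditions)
  if (!"condition_id" %in% names(out)) out$condition_id <- seq_len(nrow(out))
  if (!"feasible" %in% names(out)) {
    out$feasible <- is_feasible_condition(out$rho_obs, out$reliability)
    out$reason <- dplyr::if_else(
      out$feasible, NA_character_,
      "impossible: observed correlation exceeds reliability"
    )
  }
  out
}

#' Run a Monte Carlo grid of sibling-control simulations
#'
#' For every feasible condition, repeatedly simulates a replicate and fits
#' the requested model variants — uncontrolled (exposure only) and sibling
#' control (exposure plus family-mean exposure) — with the model family
#' matching the condition's outcome kind: ordered probit for `single_item`,
#' random-intercept linear model for `aggregate5`. Returns all per-term
#' results in one tidy table; the expensive simulate-and-fit stage is thereby
#' decoupled from summarizing, so risks at new thresholds can be computed
#' later without re-simulating.
#'
#' Infeasible cells are skipped (recorded in `attr(, "skipped")`), not fatal.
#' Replicates whose fit fails to converge are kept with `converged = FALSE`
#' and excluded by the summary functions; a condition with more than 1%
#' failed replicates aborts with a diagnostic, since its summaries would be
#' untrustworthy.
#'
#' The run is deterministic given the condition seeds: each replicate draws
#' from its own derived sub-seed, so results are identical whatever the
#' execution order.
#'
#' @param conditions A condition table from [condition_grid()] or
#'   [sim_condition()].
#' @param models Character subset of `c("uncontrolled", "controlled")`.
#' @param reps Optional override of each condition's `n_reps` (e.g. a quick
#'   look at 50 replicates).
#' @param progress Print one line per condition as it completes.
#' @return A tibble of class `sib_grid`: condition columns plus `replicate`,
#'   `model`, `term`, `estimate`, `std_estimate`, `std_error`, `statistic`,
#'   `p_value`, `converged`. Attributes: `conditions` (the expanded input),
#'   `skipped` (infeasible cells and their reasons).
#' @examples
#' grid <- condition_grid(n_pairs = 200, n_reps = 5, reliability = c(1, 0.7))
#' res <- run_grid(grid)
#' confounding_risk(res)
#' @export
run_grid <- function(conditions,
                     models = c("uncontrolled", "controlled"),
                     reps = NULL, progress = FALSE) {
  conditions <- as_condition_tbl(conditions)
  models <- match.arg(models, several.ok = TRUE)

  skipped <- dplyr::filter(conditions, !.data$feasible)
  runnable <- dplyr::filter(conditions, .data$feasible)

  results <- purrr::map(seq_len(nrow(runnable)), function(i) {
    cond <- runnable[i, ]
    n_reps <- if (is.null(reps)) cond$n_reps else as.integer(reps)
    fitter <- if (cond$outcome_kind == "single_item") {
      fit_ordered_probit
    } else {
      fit_linear_mixed
    }
    rows <- purrr::map(seq_len(n_reps), function(r) {
      d <- simulate_siblings(cond, rep = r)
      purrr::map(models, function(m) {
        fit <- fitter(d, controlled = (m == "controlled"))
        dplyr::mutate(
          tidy(fit),
          replicate = r, model = m, converged = fit$converged,
          .before = 1L
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()

    n_failed <- rows |>
      dplyr::distinct(.data$replicate, .data$model, .data$converged) |>
      dplyr::filter(!.data$converged) |>
      nrow()
    if (n_failed > 0.01 * n_reps * length(models)) {
      abort(
        sprintf(
          "Condition %d: %d of %d fits failed to converge (> 1%%); summaries would be untrustworthy.",
          cond$condition_id, n_failed, n_reps * length(models)
        ),
        class = "sibcontrol_convergence_failure"
      )
    }
    if (progress) {
      message(sprintf(
        "condition %d/%d done (%d replicates, %d non-converged fits)",
        i, nrow(runnable), n_reps, n_failed
      ))
    }
    dplyr::bind_cols(
      cond[rep(1L, nrow(rows)), c("condition_id", condition_cols)],
      rows
    )
  }) |> purrr::list_rbind()

  structure(
    results,
    conditions = conditions,
    skipped = skipped,
    class = c("sib_grid", class(tibble::tibble()))
  )
}

grid_slice <- function(grid, model, term) {
  stopifnot(inherits(grid, "sib_grid") || is.data.frame(grid))
  out <- dplyr::filter(
    tibble::as_tibble(grid),
    .data$model == !!model, .data$term == !!term, .data$converged
  )
  if (nrow(out) == 0L) {
    abort(
      sprintf("No converged replicates for model '%s', term '%s'.", model, term),
      class = "sibcontrol_empty_summary"
    )
  }
  out
}

#' Risk of falsely concluding that familial confounding exists
#'
#' In the generating model the family-mean exposure has a true coefficient of
#' zero — there is no familial confounding. The proportion of replicates in
#' which its p-value nevertheless falls at or below a threshold \eqn{\alpha}
#' is the risk of falsely concluding that confounding exists when that
#' threshold is read as evidence for it. A binomial Monte Carlo standard
#' error accompanies each proportion. The comparison is weak (`p <= alpha`).
#'
#' @param grid A [run_grid()] result.
#' @param alpha Thresholds at which to evaluate the risk.
#' @param term Term whose p-value is thresholded (default `"family_mean"`).
#' @param model Which fitted variant to use (default the sibling-control
#'   model, the only one containing the family-mean term).
#' @return A tibble: condition columns, `term`, `alpha`, `n_reps_used`,
#'   `risk` (proportion in `[0, 1]`), `mc_se`.
#' @export
confounding_risk <- function(grid, alpha = c(0.05, 0.01, 0.001),
                             term = "family_mean", model = "controlled") {
  rows <- grid_slice(grid, model, term)
  purrr::map(sort(alpha, decreasing = TRUE), function(a) {
    rows |>
      dplyr::summarise(
        term = term[1L],
        alpha = a,
        n_reps_used = dplyr::n(),
        risk = mean(.data$p_value <= a),
        mc_se = sqrt(risk * (1 - risk) / n_reps_used),
        .by = dplyr::all_of(c("condition_id", condition_cols))
      )
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$condition_id, dplyr::desc(.data$alpha))
}

#' Power to detect the (attenuated) causal effect
#'
#' Proportion of replicates in which the sibling-control model's exposure
#' coefficient has p at or below the threshold. Because measurement error
#' attenuates the within-family effect, this is the power actually available
#' to a sibling-control study; at `reliability == rho_obs` the true within
#' effect is zero and the proportion drops to the test's level.
#'
#' @inheritParams confounding_risk
#' @return A tibble as in [confounding_risk()] with column `power`.
#' @export
causal_power <- function(grid, alpha = 0.05,
                         term = "exposure", model = "controlled") {
  out <- confounding_risk(grid, alpha = alpha, term = term, model = model)
  dplyr::rename(out, power = "risk")
}

#' Monte Carlo distribution of estimates per condition, model, and term
#'
#' Mean, SD, and Monte Carlo standard error of the raw and (for probit)
#' latent-scale standardized estimates across converged replicates.
#'
#' @param grid A [run_grid()] result.
#' @param terms Terms to keep (default the two regression terms).
#' @return A tibble: condition columns, `model`, `term`, `n_reps_used`,
#'   `mean_estimate`, `sd_estimate`, `mc_se`, `mean_std_estimate`,
#'   `sd_std_estimate`, `mc_se_std`.
#' @export
summarize_estimates <- function(grid, terms = c("exposure", "family_mean")) {
  rows <- dplyr::filter(
    tibble::as_tibble(grid),
    .data$term %in% terms, .data$converged
  )
  if (nrow(rows) == 0L) {
    abort("No converged replicates to summarize.", class = "sibcontrol_empty_summary")
  }
  rows |>
    dplyr::summarise(
      n_reps_used = dplyr::n(),
      mean_estimate = mean(.data$estimate),
      sd_estimate = sd(.data$estimate),
      mc_se = sd_estimate / sqrt(n_reps_used),
      mean_std_estimate = mean(.data$std_estimate),
      sd_std_estimate = sd(.data$std_estimate),
      mc_se_std = sd_std_estimate / sqrt(n_reps_used),
      .by = dplyr::all_of(c("condition_id", condition_cols, "model", "term"))
    ) |>
    dplyr::arrange(.data$condition_id, .data$model, .data$term)
}

#' Empirical CDF of p-values across replicates
#'
#' The cumulative proportion of replicates with p-value at or below each
#' observed p — the curve whose height at \eqn{\alpha} is the risk of a
#' false confounding conclusion (for the family-mean term) or the power
#' (for the exposure term).
#'
#' @inheritParams confounding_risk
#' @return A tibble: condition columns, `term`, `p_value` (sorted),
#'   `cum_prop` (non-decreasing, reaching 1 at the largest p).
#' @export
pvalue_ecdf <- function(grid, term = "family_mean", model = "controlled") {
  rows <- grid_slice(grid, model, term)
  rows |>
    dplyr::arrange(.data$p_value) |>
    dplyr::mutate(
      term = term,
      cum_prop = dplyr::row_number() / dplyr::n(),
      .by = "condition_id"
    ) |>
    dplyr::select(dplyr::all_of(c(
      "condition_id", condition_cols, "term", "p_value", "cum_prop"
    )))
}
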