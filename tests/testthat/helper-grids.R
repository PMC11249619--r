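# Shared Monte Carlo runs, computed once per test session and reused across
# test files (testthat sources helpers before every file; the cache lives in
# the package-level helper environment).
.grid_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .grid_cache)) {
    assign(key, force(expr), envir = .grid_cache)
  }
  get(key, envir = .grid_cache)
}

# Main single-item probit runs at the reported study scale: n = 2000 pairs,
# sibling-control model only. Conditions: reliability 0.7 / 0.6 / 1.0 at
# observed correlation 0.4, the monozygotic-range cell (0.9, 0.8), and the
# fully discordance-free cell (0.6, 0.6).
probit_main_grid <- function() cached("probit_main", {
  extra <- condition_grid(
    n_pairs = 2000, n_reps = 400, rho_obs = c(0.8, 0.6),
    reliability = c(0.9, 0.6), beta = 0.3, seed = 616
  )
  extra <- extra[extra$feasible & !(extra$rho_obs == 0.6 & extra$reliability == 0.9), ]
  extra$condition_id <- extra$condition_id + 3L
  conds <- dplyr::bind_rows(
    condition_grid(
      n_pairs = 2000, n_reps = 400, rho_obs = 0.4,
      reliability = c(0.7, 0.6, 1.0), beta = 0.3, seed = 20240616
    ),
    extra
  )
  run_grid(conds, models = "controlled")
})

# Aggregate-outcome (mean of five ordinal items) linear mixed runs.
aggregate_main_grid <- function() cached("aggregate_main", {
  conds <- dplyr::bind_rows(
    condition_grid(
      n_pairs = 2000, n_reps = 300, rho_obs = 0.4,
      reliability = c(0.7, 0.6), beta = 0.3,
      outcome_kind = "aggregate5", seed = 20240617
    ),
    condition_grid(
      n_pairs = 2000, n_reps = 300, rho_obs = 0.8, reliability = 0.9,
      beta = 0.3, outcome_kind = "aggregate5", seed = 617
    ) |>
      dplyr::mutate(condition_id = 3L)
  )
  run_grid(conds, models = "controlled")
})

risk_at <- function(risks, rel, rho, a, col = "risk") {
  row <- dplyr::filter(
    risks,
    abs(.data$reliability - rel) < 1e-9,
    abs(.data$rho_obs - rho) < 1e-9,
    abs(.data$alpha - a) < 1e-12
  )
  stopifnot(nrow(row) == 1L)
  row[[col]]
}

# Minimal hand-built grid table (condition columns + p-values) for summary
# bookkeeping tests that need known inputs rather than simulation output.
fake_grid <- function(p_values, term = "family_mean", model = "controlled",
                      estimate = 0.1) {
  n <- length(p_values)
  tibble::tibble(
    condition_id = 1L, n_pairs = 100L, n_reps = n, rho_obs = 0.4,
    reliability = 0.8, beta = 0.3, outcome_kind = "single_item",
    symmetry = "symmetric", shared_outcome_frac = 0, loading = 0.7,
    k_siblings = 2L, seed = 1L,
    replicate = seq_len(n), model = model, term = term,
    estimate = rep_len(estimate, n), std_estimate = rep_len(estimate, n),
    std_error = 0.05, statistic = 2, p_value = p_values, converged = TRUE
  )
}
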