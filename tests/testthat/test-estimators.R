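# independent ordered-probit log-likelihood for spot checks
probit_loglik <- function(y, X, beta, zeta) {
  eta <- drop(as.matrix(X) %*% beta)
  cuts <- c(-Inf, zeta, Inf)
  sum(log(pnorm(cuts[y + 1L] - eta) - pnorm(cuts[y] - eta)))
}

test_that("near-null probit recovers the saturated cutpoints", {
  counts <- c(36, 238, 452, 238, 36)
  y <- rep(1:5, counts)
  set.seed(1)
  d <- tibble::tibble(outcome = y, x_obs = rnorm(1000))
  fit <- fit_ordered_probit(d)
  td <- tidy(fit)
  cuts <- td[td$term %in% c("1|2", "2|3", "3|4", "4|5"), ]
  expected <- qnorm(cumsum(counts / 1000)[1:4])
  expect_true(all(abs(cuts$estimate - expected) < 3 * cuts$std_error))
  # slope of an unrelated predictor is near zero
  expect_lt(abs(td$estimate[td$term == "exposure"]), 3 * td$std_error[td$term == "exposure"])
})

test_that("probit fit is at a local optimum of the likelihood", {
  cond <- sim_condition(n_pairs = 300, rho_obs = 0.4, reliability = 0.8, seed = 21)
  d <- simulate_siblings(cond)
  fit <- fit_ordered_probit(d, controlled = TRUE)
  td <- tidy(fit)
  beta <- td$estimate[match(c("exposure", "family_mean"), td$term)]
  zeta <- td$estimate[match(c("1|2", "2|3", "3|4", "4|5"), td$term)]
  X <- cbind(d$x_obs, d$family_mean_x)
  ll_hat <- probit_loglik(d$outcome, X, beta, zeta)
  expect_equal(ll_hat, fit$log_lik, tolerance = 1e-6)
  set.seed(99)
  for (i in 1:5) {
    pert <- rnorm(6, sd = 0.02)
    ll_pert <- probit_loglik(d$outcome, X, beta + pert[1:2], sort(zeta + pert[3:6]))
    expect_lt(ll_pert, ll_hat)
  }
})

test_that("latent-scale standardization divides by sqrt(lp variance + 1)", {
  # all-zero coefficients: nothing to rescale
  x <- rnorm(100)
  expect_equal(standardize_probit(c(a = 0, b = 0), data.frame(a = x, b = x)),
               c(a = 0, b = 0))
  # unit-sample-variance predictor with coefficient 1 -> 1/sqrt(2)
  xs <- drop(scale(rnorm(200)))
  expect_equal(unname(standardize_probit(c(x = 1), data.frame(x = xs))),
               1 / sqrt(2), tolerance = 1e-12)
})

test_that("uncontrolled and controlled probit agree at perfect reliability", {
  cond <- sim_condition(n_pairs = 5000, rho_obs = 0.4, reliability = 1, seed = 13)
  d <- simulate_siblings(cond)
  unc <- tidy(fit_ordered_probit(d, controlled = FALSE))
  con <- tidy(fit_ordered_probit(d, controlled = TRUE))
  b_unc <- unc[unc$term == "exposure", ]
  b_con <- con[con$term == "exposure", ]
  expect_lt(abs(b_unc$std_estimate - 0.3), 3 * b_unc$std_error)
  expect_lt(abs(b_con$std_estimate - 0.3), 3 * b_con$std_error)
  expect_lt(abs(b_unc$std_estimate - b_con$std_estimate), 3 * b_con$std_error)
})

test_that("family-mean and within-deviation parameterizations are equivalent", {
  cond <- sim_condition(n_pairs = 500, rho_obs = 0.4, reliability = 0.7, seed = 17)
  d <- simulate_siblings(cond)
  d$x_dev <- d$x_obs - d$family_mean_x

  # ordered probit: exposure slope invariant; the family-mean coefficient in
  # the deviation parameterization picks up the exposure slope
  f_xm <- tidy(fit_ordered_probit(d, controlled = TRUE))
  f_dev <- tidy(fit_ordered_probit(d, controlled = TRUE, exposure = "x_dev"))
  b <- function(td, t) td$estimate[td$term == t]
  expect_equal(b(f_xm, "exposure"), b(f_dev, "exposure"), tolerance = 1e-3)
  expect_equal(
    b(f_dev, "family_mean") - b(f_xm, "family_mean"),
    b(f_xm, "exposure"),
    tolerance = 1e-3
  )

  # linear mixed model: same identity, essentially exact
  conda <- sim_condition(
    n_pairs = 500, rho_obs = 0.4, reliability = 0.7,
    outcome_kind = "aggregate5", seed = 18
  )
  da <- simulate_siblings(conda)
  da$x_dev <- da$x_obs - da$family_mean_x
  l_xm <- tidy(fit_linear_mixed(da, controlled = TRUE))
  l_dev <- tidy(fit_linear_mixed(da, controlled = TRUE, exposure = "x_dev"))
  expect_equal(b(l_xm, "exposure"), b(l_dev, "exposure"), tolerance = 1e-6)
  expect_equal(
    b(l_dev, "family_mean") - b(l_xm, "family_mean"),
    b(l_xm, "exposure"),
    tolerance = 1e-6
  )
})

test_that("mixed-model fixed effects match the GLS closed form", {
  cond <- sim_condition(
    n_pairs = 50, rho_obs = 0.4, reliability = 0.8,
    outcome_kind = "aggregate5", shared_outcome_frac = 0.4, seed = 23
  )
  d <- simulate_siblings(cond)
  fit <- fit_linear_mixed(d, controlled = TRUE)
  td <- tidy(fit)
  tau2 <- td$estimate[td$term == "sd__(Intercept)"]^2
  sig2 <- td$estimate[td$term == "sd__Observation"]^2

  # GLS with the fitted variance components, block-diagonal pair covariance
  X <- cbind(1, d$x_obs, d$family_mean_x)
  V_inv_blocks <- solve(matrix(c(tau2 + sig2, tau2, tau2, tau2 + sig2), 2))
  XtVX <- matrix(0, 3, 3)
  XtVy <- numeric(3)
  for (f in unique(d$family_id)) {
    idx <- which(d$family_id == f)
    Xi <- X[idx, , drop = FALSE]
    XtVX <- XtVX + t(Xi) %*% V_inv_blocks %*% Xi
    XtVy <- XtVy + t(Xi) %*% V_inv_blocks %*% d$outcome[idx]
  }
  gls <- drop(solve(XtVX, XtVy))
  est <- td$estimate[match(c("(Intercept)", "exposure", "family_mean"), td$term)]
  expect_equal(est, gls, tolerance = 1e-5)
})

test_that("zero between-family residual variance collapses to OLS on the boundary", {
  set.seed(4)
  n <- 200
  d <- tibble::tibble(
    family_id = rep(1:n, each = 2),
    x_obs = rnorm(2 * n),
    outcome = NA_real_
  )
  d <- add_family_mean(d)
  d$outcome <- 0.2 * d$x_obs + rnorm(2 * n) # residuals fully independent
  fit <- fit_linear_mixed(d, controlled = TRUE)
  expect_true(fit$converged)
  td <- tidy(fit)
  tau <- td$estimate[td$term == "sd__(Intercept)"]
  sig <- td$estimate[td$term == "sd__Observation"]
  expect_lt(tau^2 / (tau^2 + sig^2), 0.05) # intraclass correlation near zero
  ols <- coef(lm(outcome ~ x_obs + family_mean_x, data = d))
  est <- td$estimate[match(c("(Intercept)", "exposure", "family_mean"), td$term)]
  expect_equal(est, unname(ols), tolerance = 0.02)
})

test_that("degenerate outcomes and unidentified slopes are flagged", {
  d <- tibble::tibble(
    family_id = rep(1:20, each = 2), x_obs = rnorm(40), outcome = rep(3L, 40)
  )
  d <- add_family_mean(d)
  expect_error(fit_ordered_probit(d), class = "sibcontrol_degenerate_outcome")

  d2 <- tibble::tibble(
    family_id = rep(1:50, each = 2),
    x_obs = 1, # zero variance: slope unidentified
    outcome = rep(rep(1:5, 10), each = 2)
  )
  d2 <- add_family_mean(d2)
  expect_error(fit_ordered_probit(d2), class = "sibcontrol_unidentified_predictor")
  expect_error(fit_linear_mixed(d2), class = "sibcontrol_unidentified_predictor")
})

test_that("glance reports model bookkeeping", {
  cond <- sim_condition(n_pairs = 100, rho_obs = 0.4, reliability = 0.8, seed = 6)
  d <- simulate_siblings(cond)
  g <- glance(fit_ordered_probit(d, controlled = TRUE))
  expect_equal(g$model, "ordered_probit")
  expect_true(g$controlled)
  expect_equal(g$n_obs, 200L)
  expect_equal(g$n_families, 100L)
})
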