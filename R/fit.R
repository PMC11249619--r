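new_sib_fit <- function(tidy, model, controlled, converged, boundary = FALSE,
                        n_obs = NA_integer_, n_families = NA_integer_,
                        log_lik = NA_real_) {
  structure(
    list(
      tidy = tidy, model = model, controlled = controlled,
      converged = converged, boundary = boundary,
      n_obs = n_obs, n_families = n_families, log_lik = log_lik
    ),
    class = "sib_fit"
  )
}

#' @export
print.sib_fit <- function(x, ...) {
  cat(sprintf(
    "<sib_fit> %s (%s)%s, %d obs in %d families\n",
    x$model, if (x$controlled) "sibling control" else "uncontrolled",
    if (!x$converged) " [NOT CONVERGED]" else if (x$boundary) " [boundary]" else "",
    x$n_obs, x$n_families
  ))
  print(x$tidy, ...)
  invisible(x)
}

#' @rdname sib_fit_tidiers
#' @method tidy sib_fit
#' @export
tidy.sib_fit <- function(x, ...) x$tidy

#' Tidy and summarize fitted sibling-control models
#'
#' `tidy()` returns one row per model term with raw and (for ordered probit)
#' latent-scale standardized estimates; `glance()` returns a one-row model
#' summary.
#'
#' @param x A `sib_fit` from [fit_ordered_probit()] or [fit_linear_mixed()].
#' @param ... Unused.
#' @return A tibble.
#' @name sib_fit_tidiers
#' @method glance sib_fit
#' @export
glance.sib_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    controlled = x$controlled,
    converged = x$converged,
    boundary = x$boundary,
    n_obs = x$n_obs,
    n_families = x$n_families,
    log_lik = x$log_lik
  )
}

#' Standardize probit coefficients on the latent response scale
#'
#' An ordered probit fixes the latent residual variance at 1, so the total
#' latent-outcome variance grows with the variance explained by the linear
#' predictor; adding a predictor therefore re-scales all coefficients.
#' Standardizing divides each regression coefficient by the implied latent
#' outcome standard deviation \eqn{\sqrt{\hat v + 1}}, where \eqn{\hat v} is
#' the sample variance of the fitted linear predictor (regression terms only,
#' cutpoints excluded). Coefficients from models with different predictor
#' sets are then comparable; Wald p-values are unaffected.
#'
#' @param coefs Named numeric vector of regression coefficients.
#' @param predictors Data frame or matrix whose columns match `names(coefs)`.
#' @return Numeric vector of standardized coefficients.
#' @examples
#' x <- rnorm(500)
#' standardize_probit(c(x = 1), data.frame(x = x / sd(x)))
#' @export
standardize_probit <- function(coefs, predictors) {
  predictors <- as.matrix(predictors)[, names(coefs), drop = FALSE]
  lp <- drop(predictors %*% coefs)
  coefs / sqrt(var(lp) + 1)
}

# Shared tidy-row builder for Wald (normal-reference) inference.
wald_rows <- function(term, estimate, std_error, std_estimate = NA_real_) {
  statistic <- estimate / std_error
  tibble::tibble(
    term = term,
    estimate = estimate,
    std_estimate = std_estimate,
    std_error = std_error,
    statistic = statistic,
    p_value = 2 * pnorm(-abs(statistic))
  )
}

#' Fit an uncontrolled or sibling-control ordered probit model
#'
#' Maximum-likelihood ordered probit ([MASS::polr] with a probit link) of an
#' ordinal outcome on the observed exposure, optionally adding the
#' family-mean exposure (the sibling-control model). The latent residual
#' variance is fixed at 1; regression coefficients are additionally reported
#' standardized with respect to the latent response (see
#' [standardize_probit()]). Wald p-values use the standard-normal reference.
#' No family-clustering adjustment is applied, mirroring how single-item
#' ordinal outcomes are commonly analysed in this design.
#'
#' @param data One replicate, e.g. from [simulate_siblings()]; must contain
#'   the `outcome`, `exposure`, and (if `controlled`) `family_mean` columns.
#' @param controlled Include the family-mean exposure term (sibling-control
#'   model)?
#' @param outcome,exposure,family_mean Column names.
#' @return A `sib_fit`; see [tidy.sib_fit()]. Terms are `exposure`,
#'   `family_mean` (if controlled), and the cutpoints (`1|2`, ..., with
#'   `std_estimate = NA`). On persistent non-convergence the fit is returned
#'   with `converged = FALSE` and `NA` estimates.
#' @examples
#' cond <- sim_condition(n_pairs = 300, rho_obs = 0.4, reliability = 0.7)
#' d <- simulate_siblings(cond)
#' tidy(fit_ordered_probit(d, controlled = TRUE))
#' @export
fit_ordered_probit <- function(data, controlled = FALSE,
                               outcome = "outcome", exposure = "x_obs",
                               family_mean = "family_mean_x") {
  y <- data[[outcome]]
  if (length(unique(y)) < 2L) {
    abort(
      "Degenerate outcome: fewer than 2 observed categories.",
      class = "sibcontrol_degenerate_outcome"
    )
  }
  vars <- c(exposure, if (controlled) family_mean)
  check_predictors(data, vars)
  df <- data.frame(.y = factor(y, ordered = TRUE), data[vars])
  fml <- stats::reformulate(vars, response = ".y")

  fit <- tryCatch(
    suppressWarnings(MASS::polr(fml, data = df, method = "probit", Hess = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # retry from a perturbed start: slope(s) 0, cutpoints at marginal quantiles
    k <- nlevels(df$.y)
    start <- c(rep(0.01, length(vars)), qnorm(cumsum(prop.table(table(df$.y)))[-k]))
    fit <- tryCatch(
      suppressWarnings(
        MASS::polr(fml, data = df, method = "probit", Hess = TRUE, start = start)
      ),
      error = function(e) NULL
    )
  }
  n_fam <- length(unique(data[["family_id"]] %||% seq_len(nrow(data))))
  if (is.null(fit) || fit$convergence != 0) {
    terms <- c(rename_terms(vars, exposure, family_mean))
    return(new_sib_fit(
      wald_rows(terms, NA_real_, NA_real_),
      "ordered_probit", controlled,
      converged = FALSE, n_obs = nrow(df), n_families = n_fam
    ))
  }

  beta <- fit$coefficients
  zeta <- fit$zeta
  se <- sqrt(diag(vcov(fit)))
  std_beta <- standardize_probit(beta, df[names(beta)])
  rows <- dplyr::bind_rows(
    wald_rows(rename_terms(names(beta), exposure, family_mean),
              unname(beta), unname(se[names(beta)]), unname(std_beta)),
    wald_rows(names(zeta), unname(zeta), unname(se[names(zeta)]))
  )
  new_sib_fit(
    rows, "ordered_probit", controlled,
    converged = TRUE, n_obs = nrow(df), n_families = n_fam,
    log_lik = as.numeric(stats::logLik(fit))
  )
}

check_predictors <- function(data, vars) {
  bad <- vars[vapply(vars, function(v) {
    x <- data[[v]]
    !all(is.finite(x)) || stats::var(x) == 0
  }, logical(1))]
  if (length(bad)) {
    abort(
      paste0(
        "Unidentified slope: predictor(s) with zero variance or non-finite values: ",
        paste(bad, collapse = ", ")
      ),
      class = "sibcontrol_unidentified_predictor"
    )
  }
}

rename_terms <- function(terms, exposure, family_mean) {
  terms[terms == exposure] <- "exposure"
  terms[terms == family_mean] <- "family_mean"
  terms
}

#' Fit an uncontrolled or sibling-control random-intercept linear model
#'
#' Linear mixed model ([lme4::lmer]) of an aggregate (mean-score) outcome on
#' the observed exposure with a random intercept for family, optionally
#' adding the family-mean exposure (the sibling-control model). Fitted by
#' REML; if the random-intercept variance hits the zero boundary the model is
#' refit by plain maximum likelihood and flagged `boundary` (not an error:
#' with no shared residual variance the truth *is* on the boundary). Fixed
#' effect Wald p-values use the standard-normal reference, appropriate at the
#' simulated sample sizes (hundreds to thousands of families).
#'
#' @inheritParams fit_ordered_probit
#' @param family Column name of the family identifier.
#' @return A `sib_fit` with terms `(Intercept)`, `exposure`, `family_mean`
#'   (if controlled), and the variance components `sd__(Intercept)`,
#'   `sd__Observation` (no p-values).
#' @examples
#' cond <- sim_condition(
#'   n_pairs = 300, rho_obs = 0.4, reliability = 0.7,
#'   outcome_kind = "aggregate5"
#' )
#' d <- simulate_siblings(cond)
#' tidy(fit_linear_mixed(d, controlled = TRUE))
#' @export
fit_linear_mixed <- function(data, controlled = FALSE,
                             outcome = "outcome", exposure = "x_obs",
                             family_mean = "family_mean_x",
                             family = "family_id") {
  vars <- c(exposure, if (controlled) family_mean)
  check_predictors(data, vars)
  fml <- stats::as.formula(
    paste(outcome, "~", paste(vars, collapse = " + "), "+ (1 |", family, ")")
  )
  quiet_lmer <- function(reml) {
    tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(fml, data = data, REML = reml)
      )),
      error = function(e) NULL
    )
  }
  fit <- quiet_lmer(TRUE)
  boundary <- !is.null(fit) && lme4::isSingular(fit)
  if (boundary) {
    ml <- quiet_lmer(FALSE)
    if (!is.null(ml)) fit <- ml
  }
  n_fam <- length(unique(data[[family]]))
  conv_ok <- function(f) {
    msgs <- f@optinfo$conv$lme4$messages
    is.null(msgs) || all(grepl("boundary", msgs, ignore.case = TRUE))
  }
  if (is.null(fit) || !conv_ok(fit)) {
    terms <- c("(Intercept)", rename_terms(vars, exposure, family_mean))
    return(new_sib_fit(
      wald_rows(terms, NA_real_, NA_real_),
      "linear_mixed", controlled,
      converged = FALSE, n_obs = nrow(data), n_families = n_fam
    ))
  }

  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  fixed_terms <- names(b)
  fixed_terms[-1] <- rename_terms(fixed_terms[-1], exposure, family_mean)
  vc <- as.data.frame(lme4::VarCorr(fit))
  rows <- dplyr::bind_rows(
    wald_rows(fixed_terms, unname(b), unname(se)),
    tibble::tibble(
      term = c("sd__(Intercept)", "sd__Observation"),
      estimate = c(vc$sdcor[vc$grp == family][1L],
                   vc$sdcor[vc$grp == "Residual"][1L]),
      std_estimate = NA_real_, std_error = NA_real_,
      statistic = NA_real_, p_value = NA_real_
    )
  )
  new_sib_fit(
    rows, "linear_mixed", controlled,
    converged = TRUE, boundary = boundary,
    n_obs = nrow(data), n_families = n_fam,
    log_lik = as.numeric(stats::logLik(fit))
  )
}
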