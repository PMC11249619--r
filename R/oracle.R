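#' Closed-form expected slopes under classical measurement error
#'
#' For a *continuous* outcome regressed on the observed exposure (and, in the
#' sibling-control model, the family-mean exposure), the population slopes
#' under the generating model have closed forms. With reliability
#' \eqn{\lambda}, observed sibling correlation \eqn{\rho}, and true effect
#' \eqn{\beta}:
#' \deqn{b_{uncontrolled} = \beta\lambda}
#' \deqn{b_{within} = \beta(\lambda - \rho)/(1 - \rho)}
#' \deqn{b_{family\,mean} = 2\beta\rho(1 - \lambda)/(1 - \rho^2)}
#' all per unit of observed exposure. Measurement error attenuates the
#' within-family slope more than the uncontrolled slope (differencing
#' removes shared true-score variance but none of the error variance), and
#' the deficit loads onto the family-mean term — the signature
#' conventionally read as familial confounding. At \eqn{\rho = \lambda} the
#' siblings' true exposures are perfectly correlated and the within slope is
#' exactly zero.
#'
#' For ordinal outcomes these serve as qualitative references only:
#' categorization and latent-scale standardization introduce additional
#' (mild) attenuation.
#'
#' @param reliability Exposure reliability \eqn{\lambda} in (0, 1]. Vectorized.
#' @param rho_obs Observed sibling exposure correlation in `[0, 1)`. Vectorized.
#' @param beta True causal effect. Vectorized.
#' @return A tibble with columns `reliability`, `rho_obs`, `beta`,
#'   `uncontrolled_slope`, `within_slope`, `family_mean_slope`.
#' @examples
#' expected_slopes(0.7, 0.4, 0.3)
#' expected_slopes(c(1, 0.8, 0.6), 0.4, 0.3)
#' @export
expected_slopes <- function(reliability, rho_obs, beta) {
  args <- vctrs_recycle(reliability = reliability, rho_obs = rho_obs, beta = beta)
  # errors on rho_obs > reliability ("impossible") and range violations
  true_correlation(args$rho_obs, args$reliability)
  with(args, tibble::tibble(
    reliability = reliability,
    rho_obs = rho_obs,
    beta = beta,
    uncontrolled_slope = beta * reliability,
    within_slope = beta * (reliability - rho_obs) / (1 - rho_obs),
    family_mean_slope = 2 * beta * rho_obs * (1 - reliability) / (1 - rho_obs^2)
  ))
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(vapply(args, length, 1L))
  lapply(args, rep_len, length.out = n)
}
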