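#' Plot mean estimates against exposure reliability
#'
#' One panel per observed sibling correlation; points are Monte Carlo mean
#' estimates (latent-scale standardized where available, i.e. for ordered
#' probit) for the uncontrolled exposure effect, the sibling-control exposure
#' effect, and the family-mean coefficient, with the true causal effect as a
#' dashed reference line. Reliability decreases left to right, so bias grows
#' along the x-axis.
#'
#' @param estimates Output of [summarize_estimates()] (or a [run_grid()]
#'   result, which is summarized first).
#' @return A ggplot object.
#' @export
plot_estimates <- function(estimates) {
  if (inherits(estimates, "sib_grid")) estimates <- summarize_estimates(estimates)
  df <- estimates |>
    dplyr::filter(!(.data$model == "uncontrolled" & .data$term == "family_mean")) |>
    dplyr::mutate(
      shown = dplyr::coalesce(.data$mean_std_estimate, .data$mean_estimate),
      what = dplyr::case_when(
        .data$model == "uncontrolled" ~ "exposure, uncontrolled",
        .data$term == "exposure" ~ "exposure, sibling control",
        TRUE ~ "family mean, sibling control"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$reliability, levels = sort(unique(.data$reliability), decreasing = TRUE)),
    y = .data$shown, shape = .data$what, colour = .data$what
  )) +
    ggplot2::geom_hline(
      ggplot2::aes(yintercept = .data$beta), linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_wrap(~rho_obs, labeller = ggplot2::label_both) +
    ggplot2::scale_shape_manual(values = c(
      "exposure, uncontrolled" = 17,
      "exposure, sibling control" = 16,
      "family mean, sibling control" = 15
    )) +
    ggplot2::labs(
      x = "Exposure reliability (decreasing)", y = "Mean estimate",
      shape = NULL, colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the p-value ECDF of the family-mean coefficient
#'
#' Cumulative proportion of replicates with p-values at or below each value,
#' per condition: the height of the curve at a chosen threshold is the risk
#' of falsely concluding familial confounding at that threshold.
#'
#' @param grid A [run_grid()] result.
#' @inheritParams pvalue_ecdf
#' @return A ggplot object.
#' @export
plot_pvalue_ecdf <- function(grid, term = "family_mean", model = "controlled") {
  df <- pvalue_ecdf(grid, term = term, model = model)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$p_value, y = .data$cum_prop,
    colour = factor(.data$reliability), group = .data$condition_id
  )) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::facet_wrap(~rho_obs, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "p-value", y = "Cumulative proportion of replicates",
      colour = "Reliability"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot sib_grid
#' @export
autoplot.sib_grid <- function(object, type = c("estimates", "ecdf"), ...) {
  type <- rlang::arg_match(type)
  switch(type,
    estimates = plot_estimates(object),
    ecdf = plot_pvalue_ecdf(object, ...)
  )
}
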