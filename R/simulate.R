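#' Simulate one replicate of sibling-pair data
#'
#' Draws one sample from the population model: siblings' true exposures are
#' standard normal with an exchangeable within-family correlation
#' `rho_obs / reliability`; the observed exposure adds independent normal
#' measurement error with variance `(1 - reliability) / reliability`, so the
#' true score accounts for exactly `reliability` of the observed variance;
#' the latent outcome is `beta` times the true exposure plus residual noise
#' scaled to unit total variance (optionally split into a family-shared and
#' an individual part). There is no confounding of any kind: the family-mean
#' exposure has a true coefficient of zero.
#'
#' Single-item outcomes discretize the latent outcome at fixed normal
#' quantile cutpoints into codes 1-5. Aggregate outcomes generate five
#' ordinal items, each loading `loading` on the latent outcome with
#' independent item-specific noise, and average the five codes.
#'
#' @param cond A condition from [sim_condition()] (or a one-row slice of
#'   [condition_grid()]).
#' @param rep Replicate index (>= 1). Output is bit-identical for identical
#'   `(cond$seed, rep)`, independent of how many other replicates were drawn.
#' @param prop_full Fraction of families contributing all `k_siblings`
#'   members; the remainder contribute 2. Only relevant for `k_siblings > 2`
#'   (multi-sibling designs with partial participation).
#' @param keep_latent Keep the latent columns `x_true` and `y_latent`
#'   (default `TRUE`; set `FALSE` for lean output).
#'
#' @return A tibble with one row per sibling: `family_id`, `sibling`,
#'   `x_true`, `x_obs`, `y_latent`, `outcome` (integer codes 1-5 for
#'   `single_item`, mean of five codes for `aggregate5`), and
#'   `family_mean_x`, the within-family mean of `x_obs`.
#' @examples
#' cond <- sim_condition(n_pairs = 100, rho_obs = 0.4, reliability = 0.7)
#' simulate_siblings(cond, rep = 1)
#' @export
simulate_siblings <- function(cond, rep = 1L, prop_full = 1, keep_latent = TRUE) {
  validate_condition(cond)
  stopifnot(rep >= 1L, prop_full >= 0, prop_full <= 1)
  rho_t <- true_correlation(cond$rho_obs, cond$reliability)

  with_sub_seed(cond$seed, rep, {
    n_fam <- cond$n_pairs
    sizes <- rep.int(cond$k_siblings, n_fam)
    if (cond$k_siblings > 2L && prop_full < 1) {
      n_full <- round(prop_full * n_fam)
      sizes[seq_len(n_fam) > n_full] <- 2L
    }
    n_obs <- sum(sizes)
    family_id <- rep.int(seq_len(n_fam), sizes)

    # exchangeable T: shared factor + individual part, both standard normal
    a_fam <- rnorm(n_fam)
    x_true <- sqrt(rho_t) * a_fam[family_id] + sqrt(1 - rho_t) * rnorm(n_obs)
    err_var <- (1 - cond$reliability) / cond$reliability
    x_obs <- x_true + rnorm(n_obs, sd = sqrt(err_var))

    res_var <- 1 - cond$beta^2
    s <- cond$shared_outcome_frac
    u_shared <- rnorm(n_fam, sd = sqrt(s * res_var))
    y_latent <- cond$beta * x_true + u_shared[family_id] +
      rnorm(n_obs, sd = sqrt((1 - s) * res_var))

    thr <- ordinal_thresholds(symmetry_props(cond$symmetry))
    outcome <- if (cond$outcome_kind == "single_item") {
      cut_latent(y_latent, thr)
    } else {
      item_sd <- sqrt(1 - cond$loading^2)
      codes <- vapply(1:5, function(j) {
        cut_latent(cond$loading * y_latent + rnorm(n_obs, sd = item_sd), thr)
      }, integer(n_obs))
      rowMeans(codes)
    }

    out <- tibble::tibble(
      family_id = family_id,
      sibling = stats::ave(family_id, family_id, FUN = seq_along),
      x_true = x_true,
      x_obs = x_obs,
      y_latent = y_latent,
      outcome = outcome,
      family_mean_x = stats::ave(x_obs, family_id)
    )
    if (!keep_latent) out$x_true <- out$y_latent <- NULL
    out
  })
}

#' Add the family-mean exposure to a sibling dataset
#'
#' The sibling-control model augments the individual exposure with the
#' within-family mean of the exposure over all participating siblings. The
#' individual exposure is left uncentered: its coefficient is then the
#' within-family effect, and the family-mean coefficient is the between
#' minus within contrast whose true value is zero absent familial
#' confounding.
#'
#' @param data Data frame with one row per sibling.
#' @param exposure,family Column names (strings) of the individual exposure
#'   and the family identifier.
#' @param col Name of the column to add.
#' @return `data` as a tibble with the family-mean column appended.
#'   Errors (class `"sibcontrol_singleton_family"`) if any family has a
#'   single member, since the family mean then equals the exposure and the
#'   design is collinear.
#' @examples
#' d <- tibble::tibble(family_id = c(1, 1, 2, 2), x_obs = c(1, 3, 2, 2))
#' add_family_mean(d)
#' @export
add_family_mean <- function(data, exposure = "x_obs", family = "family_id",
                            col = "family_mean_x") {
  stopifnot(is.data.frame(data), exposure %in% names(data), family %in% names(data))
  sizes <- table(data[[family]])
  if (any(sizes < 2L)) {
    singletons <- names(sizes)[sizes < 2L]
    abort(
      paste0(
        "Family mean is collinear with the exposure for singleton families: ",
        paste(utils::head(singletons, 5L), collapse = ", "),
        if (length(singletons) > 5L) sprintf(" (and %d more)", length(singletons) - 5L) else ""
      ),
      class = "sibcontrol_singleton_family"
    )
  }
  out <- tibble::as_tibble(data)
  out[[col]] <- stats::ave(out[[exposure]], out[[family]])
  out
}

#' Write one simulated replicate to CSV
#'
#' Convenience dump of a replicate in a plain-text layout
#' (`family_id, sibling_index, x_observed, x_true, outcome, family_mean_x`).
#'
#' @param data Output of [simulate_siblings()].
#' @param path File path to write.
#' @param debug Include the latent `x_true` column.
#' @return `path`, invisibly.
#' @export
write_replicate_csv <- function(data, path, debug = FALSE) {
  out <- data.frame(
    family_id = data$family_id,
    sibling_index = data$sibling,
    x_observed = data$x_obs
  )
  if (debug && !is.null(data$x_true)) out$x_true <- data$x_true
  out$outcome <- data$outcome
  out$family_mean_x <- data$family_mean_x
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
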