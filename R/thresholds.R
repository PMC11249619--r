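#' Marginal category proportions for the ordinal outcome
#'
#' Built-in 5-category marginal distributions for the simulated ordinal
#' responses, from symmetric through highly asymmetric (skewed towards the
#' lowest category, as with rare symptoms).
#'
#' @param symmetry One of `"symmetric"`, `"moderate"`, `"high"`.
#' @return Numeric vector of 5 proportions summing to 1.
#' @examples
#' symmetry_props("symmetric")
#' @export
symmetry_props <- function(symmetry = c("symmetric", "moderate", "high")) {
  symmetry <- rlang::arg_match(symmetry)
  switch(symmetry,
    symmetric = c(0.036, 0.238, 0.452, 0.238, 0.036),
    moderate  = c(0.752, 0.091, 0.068, 0.051, 0.038),
    high      = c(0.900, 0.040, 0.030, 0.020, 0.010)
  )
}

#' Latent thresholds reproducing target ordinal proportions
#'
#' The ordinal outcome is generated by partitioning a standard-normal latent
#' response at fixed cutpoints. Cutpoint \eqn{j} is the standard-normal
#' quantile of the cumulative sum of the first \eqn{j} target proportions, so
#' the implied category masses equal the targets by construction.
#'
#' @param target_props Vector of positive category probabilities summing to 1
#'   (within 1e-6). Length 5 in the shipped designs, but any length >= 2 works.
#' @return An object of class `sib_thresholds`: list with `cutpoints`
#'   (strictly increasing, length `length(target_props) - 1`) and
#'   `target_props`.
#' @examples
#' ordinal_thresholds(symmetry_props("symmetric"))
#' @export
ordinal_thresholds <- function(target_props) {
  stopifnot(is.numeric(target_props), length(target_props) >= 2L)
  if (any(target_props <= 0)) {
    abort(
      "All category proportions must be strictly positive (zero mass puts a cutpoint at infinity).",
      class = "sibcontrol_invalid_proportions"
    )
  }
  if (abs(sum(target_props) - 1) > 1e-6) {
    abort(
      "Category proportions must sum to 1 (tolerance 1e-6).",
      class = "sibcontrol_invalid_proportions"
    )
  }
  cutpoints <- qnorm(cumsum(target_props)[-length(target_props)])
  structure(
    list(cutpoints = cutpoints, target_props = target_props),
    class = "sib_thresholds"
  )
}

#' @export
print.sib_thresholds <- function(x, ...) {
  cat("<sib_thresholds>\n")
  cat("  cutpoints:", paste(sprintf("%.4f", x$cutpoints), collapse = ", "), "\n")
  cat("  target proportions:", paste(sprintf("%.3f", x$target_props), collapse = ", "), "\n")
  invisible(x)
}

# Discretize a latent vector into ordinal codes 1..K at the given thresholds.
cut_latent <- function(latent, thresholds) {
  findInterval(latent, thresholds$cutpoints) + 1L
}
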