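# Synthetic GPR targets driven by known feature subsets. Used by recovery
# tests: the label is a stated nonlinear function of selected features plus
# Gaussian noise, so model-ranking and importance-recovery claims can be
# checked against a known ground truth.

#' Synthetic gamma-passing-rate labels from a feature table
#'
#' Builds a GPR-like target as a deterministic nonlinear function of chosen
#' features plus `N(0, noise_sd)` noise. Features enter through their
#' within-cohort rank fraction (a strictly monotone transform), so the map
#' is scale-free and genuinely nonlinear with an interaction term:
#'
#' * `"interaction"` (default):
#'   `100 - 12 u_w u_m - 4 u_d^2 + 2 u_d`, with `u_w`, `u_m`, `u_d` the rank
#'   fractions of the weighted MLC position RMSE, MCS and dose rate —
#'   smooth, interaction-dominated, favouring flexible learners.
#' * `"dose_rate"`: `100 - 8 u_d^2 - 0.3 u_w` — dominated by dose rate, for
#'   importance-recovery checks.
#'
#' @param features Data frame/matrix containing the 13 feature columns.
#' @param seed Integer seed for the noise.
#' @param noise_sd Label noise SD in GPR % (default 0.5).
#' @param mode `"interaction"` or `"dose_rate"`.
#' @return Numeric vector of synthetic GPR percentages.
#' @export
synthetic_gpr <- function(features, seed = 1L, noise_sd = 0.5,
                          mode = c("interaction", "dose_rate")) {
  mode <- match.arg(mode)
  n <- nrow(features)
  u <- function(col) average_ranks(as.numeric(features[[col]])) / n
  u_w <- u("weighted_mlc_position_rmse")
  u_m <- u("mcs")
  u_d <- u("dose_rate")
  g <- switch(mode,
    interaction = 100 - 12 * u_w * u_m - 4 * u_d^2 + 2 * u_d,
    dose_rate = 100 - 8 * u_d^2 - 0.3 * u_w)
  g + with_seed(seed, rnorm(n, 0, noise_sd))
}
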