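# The 13 log-derived predictors: RMS errors of gantry and MLC kinematics,
# MU-weighted MLC RMSEs, field-opening RMSE, mean dose rate, MU per arc, and
# the modulation complexity score (MCS).

#' Feature names, in canonical order
#' @return Character vector of the 13 feature-vector field names.
#' @export
feature_names <- function() {
  c("field_opening_rmse",
    "gantry_position_rmse", "gantry_velocity_rmse", "gantry_acceleration_rmse",
    "mlc_position_rmse", "mlc_velocity_rmse", "mlc_acceleration_rmse",
    "weighted_mlc_position_rmse", "weighted_mlc_velocity_rmse",
    "weighted_mlc_acceleration_rmse",
    "dose_rate", "mu_per_arc", "mcs")
}

#' Root-mean-square error between a planned and an actual series
#'
#' `sqrt(mean((planned - actual)^2))` over exactly the N stored samples.
#'
#' @param planned,actual Numeric vectors of equal positive length. A list
#'   with `$planned` and `$actual` components may be given as the first
#'   argument instead.
#' @return Non-negative scalar in the units of the series.
#' @export
axis_rmse <- function(planned, actual = NULL) {
  if (is.list(planned) && is.null(actual)) {
    actual <- planned$actual
    planned <- planned$planned
  }
  if (length(planned) == 0 || length(planned) != length(actual)) {
    stop("axis_rmse: series must be non-empty and of equal length",
         call. = FALSE)
  }
  sqrt(mean((planned - actual)^2))
}

#' Velocity and acceleration series by central differences
#'
#' Velocity is the central difference of position (one-sided at the two
#' ends), acceleration the same operator applied to velocity; both have the
#' same length as the input. Central differences are exact on linear
#' (velocity) and quadratic (acceleration) motion.
#'
#' @param positions Numeric vector (or matrix, column-wise) of length >= 3.
#' @param dt Sampling interval in seconds (> 0).
#' @return List with `velocity` and `acceleration` (units/s and units/s^2).
#' @export
derive_kinematics <- function(positions, dt) {
  stopifnot(dt > 0)
  n <- if (is.matrix(positions)) nrow(positions) else length(positions)
  if (n < 3) stop("derive_kinematics: need at least 3 samples", call. = FALSE)
  v <- central_diff(positions, dt)
  a <- central_diff(v, dt)
  list(velocity = v, acceleration = a)
}

# Central difference with one-sided ends; works on vectors and matrices.
central_diff <- function(x, dt) {
  if (is.matrix(x)) {
    n <- nrow(x)
    d <- (x[c(2:n, n), , drop = FALSE] - x[c(1, 1:(n - 1)), , drop = FALSE]) /
      (dt * c(1, rep(2, n - 2), 1))
    d
  } else {
    n <- length(x)
    (x[c(2:n, n)] - x[c(1, 1:(n - 1))]) / (dt * c(1, rep(2, n - 2), 1))
  }
}

# Order-resolved planned/actual MLC matrices over moving (non-parked) leaves.
mlc_order_series <- function(log, order = c("position", "velocity",
                                            "acceleration")) {
  order <- match.arg(order)
  parked <- parked_pairs(log)
  if (all(parked)) stop("no moving leaves in log", call. = FALSE)
  cols <- c(which(!parked), 60L + which(!parked))
  P <- log$mlc$planned[, cols, drop = FALSE]
  A <- log$mlc$actual[, cols, drop = FALSE]
  if (order != "position") {
    dt <- log$sampling_interval
    P <- derive_kinematics(P, dt)[[if (order == "velocity") "velocity"
                                   else "acceleration"]]
    A <- derive_kinematics(A, dt)[[if (order == "velocity") "velocity"
                                   else "acceleration"]]
  }
  list(planned = P, actual = A)
}

#' Pooled MLC RMSE over all moving leaves
#'
#' Squared planned-actual deviations are pooled over every moving leaf and
#' every sample into a single scalar RMSE. Leaves parked closed for the
#' whole field (constant planned position, gap below the 0.5 mm closed
#' tolerance) are excluded so they cannot dilute the statistic toward zero.
#'
#' @param log A valid `trajectory_log`.
#' @param order `"position"` (mm), `"velocity"` (mm/s) or
#'   `"acceleration"` (mm/s^2); kinematic orders are derived with
#'   [derive_kinematics()] at the log's sampling interval.
#' @return Non-negative scalar.
#' @export
mlc_rmse <- function(log, order = c("position", "velocity", "acceleration")) {
  s <- mlc_order_series(log, order)
  sqrt(mean((s$planned - s$actual)^2))
}

# Per-sample delivered MU from a cumulative series: d_1 = mu_1, d_i = diff.
mu_increments <- function(mu) c(mu[1], diff(mu))

#' MU-weighted MLC RMSE
#'
#' Each sample's leaf positions are weighted by that sample's share of the
#' total delivered MU before the planned/actual comparison: with
#' `w_i = dMU_i(actual) / sum dMU(actual)` applied to the planned series and
#' `wh_i = dMU_i(planned) / sum dMU(planned)` applied to the actual series,
#' the statistic is
#' `sqrt( (1/N) * sum_i mean_leaf (w_i * x_il - wh_i * xh_il)^2 )`.
#' Positions equal plus actual MU increments a constant multiple of planned
#' gives exactly zero (the weights normalise the multiple away).
#'
#' @inheritParams mlc_rmse
#' @return Non-negative scalar (mm, mm/s or mm/s^2 scaled by MU fractions).
#' @export
weighted_mlc_rmse <- function(log, order = c("position", "velocity",
                                             "acceleration")) {
  tot_p <- sum(mu_increments(log$mu$planned))
  tot_a <- sum(mu_increments(log$mu$actual))
  if (tot_p <= 0 || tot_a <= 0) {
    stop("weighted_mlc_rmse: total MU must be positive", call. = FALSE)
  }
  w_act <- mu_increments(log$mu$actual) / tot_a
  w_pln <- mu_increments(log$mu$planned) / tot_p
  s <- mlc_order_series(log, order)
  term <- s$planned * w_act - s$actual * w_pln
  sqrt(mean(rowMeans(term^2)))
}

#' Per-sample open aperture area
#'
#' Aperture area in mm^2 at each sample: sum over leaf pairs of
#' `gap x pair width`, counting only gaps above the 0.5 mm closed-leaf
#' tolerance.
#'
#' @param log A valid `trajectory_log`.
#' @param which `"planned"` or `"actual"`.
#' @return Numeric vector of length N (mm^2).
#' @export
field_opening_series <- function(log, which = c("planned", "actual")) {
  g <- leaf_gaps(log, which)
  g[g <= CLOSED_GAP_TOL] <- 0
  as.numeric(g %*% leaf_pair_widths())
}

#' Modulation complexity score (MCS)
#'
#' MU-weighted sum over control points of leaf-sequence variability (LSV)
#' times aperture-area variability (AAV), with each 20 ms sample treated as
#' a control point and weighted by its delivered MU share. LSV multiplies
#' one factor per bank, each measuring how uniform adjacent in-field leaf
#' positions are relative to the bank's position spread at that sample
#' (spread zero gives the factor's limiting value 1). AAV is the open area
#' relative to the per-pair maximal opening over the whole field. A static
#' uniform rectangle scores exactly 1; heavier modulation drives the score
#' toward 0. Invariant under uniform MU rescaling.
#'
#' @param log A valid `trajectory_log` with at least 2 samples.
#' @param which `"planned"` or `"actual"` trajectory (default actual, the
#'   delivered modulation).
#' @return Scalar in (0, 1].
#' @export
compute_mcs <- function(log, which = c("actual", "planned")) {
  which <- match.arg(which)
  if (n_samples(log) < 2) stop("compute_mcs: need >= 2 samples", call. = FALSE)
  mu <- log$mu[[which]]
  d <- mu_increments(mu)
  tot <- sum(d)
  if (tot <= 0) stop("compute_mcs: total MU must be positive", call. = FALSE)

  M <- log$mlc[[which]]
  A <- M[, 1:60, drop = FALSE]
  B <- M[, 61:120, drop = FALSE]
  g <- B - A
  ever_open <- which(apply(g, 2, max) > CLOSED_GAP_TOL)
  if (length(ever_open) == 0) {
    stop("compute_mcs: aperture never opens", call. = FALSE)
  }
  Ao <- A[, ever_open, drop = FALSE]
  Bo <- B[, ever_open, drop = FALSE]
  go <- Bo - Ao

  lsv_bank <- function(P) {
    # P: N x m in-field leaf positions of one bank
    m <- ncol(P)
    if (m < 2) return(rep(1, nrow(P)))
    pos_max <- apply(P, 1, max) - apply(P, 1, min)
    adj <- abs(P[, -1, drop = FALSE] - P[, -m, drop = FALSE])
    num <- rowSums(pos_max - adj)
    den <- (m - 1) * pos_max
    out <- ifelse(den > 0, num / den, 1)
    pmax(out, 0)
  }
  lsv <- lsv_bank(Ao) * lsv_bank(Bo)
  # AAV denominator: maximal per-pair opening achieved anywhere in the field
  den_aav <- sum(apply(Bo, 2, max) - apply(Ao, 2, min))
  aav <- rowSums(go) / den_aav
  sum(d / tot * lsv * aav)
}

#' Extract the 13-feature vector from a trajectory log
#'
#' Populates every predictor: RMSEs of gantry position/velocity/acceleration
#' and of pooled MLC position/velocity/acceleration, their MU-weighted MLC
#' counterparts, the field-opening (aperture-area) RMSE, the mean actual
#' dose rate over beam-on samples, MU per arc, and the MCS of the actual
#' trajectory.
#'
#' @param log A valid `trajectory_log`.
#' @return Named numeric vector of length 13 (see [feature_names()]).
#' @export
extract_features <- function(log) {
  dt <- log$sampling_interval
  gk_p <- derive_kinematics(log$gantry$planned, dt)
  gk_a <- derive_kinematics(log$gantry$actual, dt)
  d_act <- mu_increments(log$mu$actual)
  beam_on <- d_act > 0
  dose_rate <- if (any(beam_on)) mean(log$dose_rate_actual[beam_on]) else 0
  out <- c(
    field_opening_rmse = axis_rmse(field_opening_series(log, "planned"),
                                   field_opening_series(log, "actual")),
    gantry_position_rmse = axis_rmse(log$gantry$planned, log$gantry$actual),
    gantry_velocity_rmse = axis_rmse(gk_p$velocity, gk_a$velocity),
    gantry_acceleration_rmse = axis_rmse(gk_p$acceleration, gk_a$acceleration),
    mlc_position_rmse = mlc_rmse(log, "position"),
    mlc_velocity_rmse = mlc_rmse(log, "velocity"),
    mlc_acceleration_rmse = mlc_rmse(log, "acceleration"),
    weighted_mlc_position_rmse = weighted_mlc_rmse(log, "position"),
    weighted_mlc_velocity_rmse = weighted_mlc_rmse(log, "velocity"),
    weighted_mlc_acceleration_rmse = weighted_mlc_rmse(log, "acceleration"),
    dose_rate = dose_rate,
    mu_per_arc = max(log$mu$actual) / log$meta$num_arcs,
    mcs = compute_mcs(log, "actual"))
  stopifnot(!anyNA(out))
  out
}

#' Extract features for a list of logs
#'
#' @param logs List of `trajectory_log`s.
#' @return Data frame with `field_id`, `site` and the 13 feature columns.
#' @export
extract_features_cohort <- function(logs) {
  rows <- lapply(logs, function(log) {
    data.frame(field_id = log$meta$field_id, site = log$meta$site_label,
               as.list(extract_features(log)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
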