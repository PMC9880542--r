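# Synthetic VMAT plan generation and parametric delivery-error injection.
#
# The clinical cohort behind this analysis (578 TrueBeam trajectory logs) is
# not publicly deposited, so the package generates its own: multi-control-
# point single-arc VMAT plans for three site archetypes, resampled onto the
# 20 ms log grid, with delivery errors injected along exactly the axes whose
# RMSEs form the feature set (MLC lag/jitter/stuck leaves, gantry lag/jitter,
# dose-rate fluctuation).

GANTRY_SPEED_DEG_S <- 6        # TrueBeam maximum gantry speed
MAX_DOSE_RATE_MU_S <- 1400 / 60  # 1400 MU/min (FFF)

#' Plan-generation configuration
#'
#' @param n_control_points Number of control points (>= 2) at which leaf
#'   shapes are defined; shapes are interpolated linearly in gantry angle
#'   onto the 20 ms sample grid.
#' @param arc_start_deg,arc_stop_deg Arc start/stop gantry angles (degrees);
#'   span must be non-zero.
#' @param total_mu Total monitor units delivered over the arc (> 0).
#' @param pattern Aperture pattern archetype: `"sliding_window"` (a window
#'   sweeping across the field), `"conformal_ellipse"` (elliptical aperture,
#'   optionally breathing with gantry angle), or `"random_modulated"`
#'   (smooth random per-leaf trajectories).
#' @param aperture_scale_mm Characteristic aperture half-size (mm, > 0).
#' @param modulation_depth Degree of aperture modulation in `[0, 1]`
#'   (0 = static shape).
#' @param max_leaf_speed_mm_s Maximum allowed planned leaf speed
#'   (default 25 mm/s, the Millennium 120 limit).
#' @param seed Integer seed controlling any random shape content.
#' @return A `plan_config` list.
#' @export
plan_config <- function(n_control_points = 90,
                        arc_start_deg = 181, arc_stop_deg = 179,
                        total_mu = 400,
                        pattern = c("conformal_ellipse", "sliding_window",
                                    "random_modulated"),
                        aperture_scale_mm = 50,
                        modulation_depth = 0.3,
                        max_leaf_speed_mm_s = 25,
                        seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(n_control_points >= 2,
            is.finite(arc_start_deg), is.finite(arc_stop_deg),
            abs(arc_stop_deg - arc_start_deg) > 0,
            total_mu > 0, aperture_scale_mm > 0,
            modulation_depth >= 0, modulation_depth <= 1,
            max_leaf_speed_mm_s > 0)
  structure(list(n_control_points = as.integer(n_control_points),
                 arc_start_deg = arc_start_deg, arc_stop_deg = arc_stop_deg,
                 total_mu = total_mu, pattern = pattern,
                 aperture_scale_mm = aperture_scale_mm,
                 modulation_depth = modulation_depth,
                 max_leaf_speed_mm_s = max_leaf_speed_mm_s,
                 seed = as.integer(seed)),
            class = "plan_config")
}

#' Delivery-error model
#'
#' Parametric errors applied to a planned trajectory to produce the "actual"
#' axes. Each axis is independently excitable so that every RMSE feature can
#' be driven in isolation.
#'
#' @param mlc_lag_mm Systematic leaf offset magnitude (mm), applied in the
#'   direction of leaf travel: bank A leaves move by `-lag`, bank B by
#'   `+lag` (aperture widening for positive lag).
#' @param mlc_jitter_sd_mm SD of white Gaussian noise on every non-parked
#'   leaf position (mm, >= 0).
#' @param gantry_jitter_sd_deg SD of white Gaussian gantry-angle noise
#'   (degrees, >= 0).
#' @param gantry_lag_deg Systematic signed gantry offset (degrees).
#' @param dose_rate_fluctuation_sd_frac SD of fractional multiplicative noise
#'   on per-sample delivered MU (>= 0).
#' @param stuck_leaf_prob Probability, per non-parked leaf per field, that
#'   the leaf is stuck at its initial position for the whole delivery.
#' @param seed Integer seed.
#' @return An `error_model` list.
#' @export
error_model <- function(mlc_lag_mm = 0, mlc_jitter_sd_mm = 0,
                        gantry_jitter_sd_deg = 0, gantry_lag_deg = 0,
                        dose_rate_fluctuation_sd_frac = 0,
                        stuck_leaf_prob = 0, seed = 1L) {
  stopifnot(mlc_jitter_sd_mm >= 0, gantry_jitter_sd_deg >= 0,
            dose_rate_fluctuation_sd_frac >= 0,
            stuck_leaf_prob >= 0, stuck_leaf_prob <= 1)
  structure(list(mlc_lag_mm = mlc_lag_mm,
                 mlc_jitter_sd_mm = mlc_jitter_sd_mm,
                 gantry_jitter_sd_deg = gantry_jitter_sd_deg,
                 gantry_lag_deg = gantry_lag_deg,
                 dose_rate_fluctuation_sd_frac = dose_rate_fluctuation_sd_frac,
                 stuck_leaf_prob = stuck_leaf_prob,
                 seed = as.integer(seed)),
            class = "error_model")
}

# Control-point aperture shapes: returns list(A = K x 60, B = K x 60)
# matrices of leaf edges (A = left edge, B = right edge, gap = B - A >= 0).
# Inactive pairs are parked closed and constant at x = 0.
cp_shapes <- function(config, max_step_mm = Inf) {
  K <- config$n_control_points
  centers <- leaf_pair_centers()
  a_y <- config$aperture_scale_mm
  active <- abs(centers) < a_y
  A <- matrix(0, K, N_LEAF_PAIRS)
  B <- matrix(0, K, N_LEAF_PAIRS)
  u <- seq(0, 1, length.out = K)
  depth <- config$modulation_depth
  with_seed(config$seed, {
    if (config$pattern == "conformal_ellipse") {
      # breathing ellipse: x half-width scales sinusoidally with arc position
      sk <- 1 + depth * 0.4 * sin(2 * pi * u)
      hw <- config$aperture_scale_mm *
        sqrt(pmax(0, 1 - (centers[active] / a_y)^2))
      for (k in seq_len(K)) {
        A[k, active] <- -hw * sk[k]
        B[k, active] <- hw * sk[k]
      }
    } else if (config$pattern == "sliding_window") {
      # window sweeping left -> right; width breathes per pair with a random
      # phase when modulation_depth > 0
      phase <- runif(sum(active), 0, 2 * pi)
      span <- config$aperture_scale_mm
      for (k in seq_len(K)) {
        ctr <- -span + 2 * span * u[k]
        w <- span * (0.35 + 0.25 * depth * sin(4 * pi * u[k] + phase))
        w <- pmax(w, 2)
        A[k, active] <- ctr - w / 2
        B[k, active] <- ctr + w / 2
      }
    } else { # random_modulated
      # smooth random per-leaf trajectories around an elliptical envelope
      hw <- config$aperture_scale_mm *
        sqrt(pmax(0, 1 - (centers[active] / a_y)^2))
      n_act <- sum(active)
      smooth_noise <- function() {
        z <- matrix(rnorm(K * n_act), K, n_act)
        # moving-average smoothing along control points
        for (j in seq_len(n_act)) z[, j] <- stats::filter(
          z[, j], rep(1 / 7, 7), sides = 2, circular = TRUE)
        z
      }
      dA <- smooth_noise(); dB <- smooth_noise()
      scale <- depth * config$aperture_scale_mm * 0.6
      Aa <- -matrix(hw, K, n_act, byrow = TRUE) + scale * dA
      Bb <- matrix(hw, K, n_act, byrow = TRUE) + scale * dB
      # decompose into centre and half-gap, clamp the gap open, and
      # rate-limit both so per-leaf speed (|dc| + |dh|) stays within the
      # machine limit by construction
      ctr <- (Aa + Bb) / 2
      hg <- pmax((Bb - Aa) / 2, 1)
      if (is.finite(max_step_mm)) {
        cap_c <- max_step_mm * 0.5
        cap_h <- max_step_mm * 0.4
        for (k in 2:K) {
          ctr[k, ] <- ctr[k - 1, ] +
            pmin(pmax(ctr[k, ] - ctr[k - 1, ], -cap_c), cap_c)
          hg[k, ] <- pmax(1, hg[k - 1, ] +
            pmin(pmax(hg[k, ] - hg[k - 1, ], -cap_h), cap_h))
        }
      }
      A[, active] <- ctr - hg
      B[, active] <- ctr + hg
    }
  })
  list(A = A, B = B, active = active)
}

#' Generate a planned VMAT arc as a trajectory log
#'
#' Produces a `trajectory_log` whose actual arrays equal the planned arrays
#' (an error-free delivery). The gantry moves linearly from `arc_start_deg`
#' to `arc_stop_deg`; cumulative MU rises linearly in time to `total_mu`;
#' control-point leaf shapes are interpolated linearly in gantry angle onto
#' the 20 ms grid. Arc duration is set by the machine limits
#' `max(span / 6 deg/s, MU / 23.3 MU/s)`.
#'
#' @param config A [plan_config()].
#' @return A valid `trajectory_log` with `actual == planned`.
#' @export
generate_plan <- function(config) {
  stopifnot(inherits(config, "plan_config"))
  dt <- 0.020
  span <- abs(config$arc_stop_deg - config$arc_start_deg)
  T_total <- max(span / GANTRY_SPEED_DEG_S,
                 config$total_mu / MAX_DOSE_RATE_MU_S)
  n <- max(3L, as.integer(ceiling(T_total / dt)) + 1L)
  tgrid <- (seq_len(n) - 1) * dt
  u <- tgrid / tgrid[n]                      # 0..1 arc fraction
  gantry <- config$arc_start_deg +
    u * (config$arc_stop_deg - config$arc_start_deg)
  mu <- u * config$total_mu

  K <- config$n_control_points
  dt_cp <- tgrid[n] / (K - 1)
  shp <- cp_shapes(config, max_step_mm = config$max_leaf_speed_mm_s * dt_cp)
  ucp <- seq(0, 1, length.out = K)
  # feasibility: planned leaf speed between control points
  spd <- pmax(apply(abs(diff(shp$A)), 1, max),
              apply(abs(diff(shp$B)), 1, max)) / dt_cp
  if (any(spd > config$max_leaf_speed_mm_s)) {
    stop(sprintf(
      "infeasible plan: leaf speed %.1f mm/s exceeds %.1f mm/s at control point %d",
      max(spd), config$max_leaf_speed_mm_s, which.max(spd) + 1L),
      call. = FALSE)
  }
  interp_cols <- function(M) {
    out <- matrix(0, n, ncol(M))
    for (j in seq_len(ncol(M))) {
      out[, j] <- approx(ucp, M[, j], xout = u, rule = 2)$y
    }
    out
  }
  mlc <- matrix(0, n, N_LEAVES)
  mlc[, which(shp$active)] <- interp_cols(shp$A[, shp$active, drop = FALSE])
  mlc[, 60L + which(shp$active)] <- interp_cols(shp$B[, shp$active, drop = FALSE])

  d_mu <- c(mu[1], diff(mu))
  dose_rate <- d_mu / dt * 60
  dose_rate[1] <- 0
  trajectory_log(sampling_interval = dt,
                 gantry_planned = gantry, gantry_actual = gantry,
                 mlc_planned = mlc, mlc_actual = mlc,
                 mu_planned = mu, mu_actual = mu,
                 dose_rate_actual = dose_rate,
                 field_id = sprintf("%s_seed%d", config$pattern, config$seed))
}

#' Inject delivery errors into a planned trajectory log
#'
#' Replaces the actual arrays of an error-free log with
#' `planned + systematic lag + N(0, sd)` noise per the model; stuck leaves
#' hold their first position for the whole field; actual MU increments are
#' the planned increments times `(1 + fluctuation noise)`, clipped to remain
#' non-decreasing, and the actual dose-rate series is recomputed from them.
#' Planned arrays are untouched. Any leaf-pair gap driven negative is clamped
#' to zero (collision guard) and counted in the `injection_issues` attribute;
#' the returned log is always valid.
#'
#' @param plan A `trajectory_log` with `actual == planned`.
#' @param model An [error_model()].
#' @return A valid `trajectory_log`; attribute `injection_issues` holds the
#'   number of gap-clamped (sample, pair) cells.
#' @export
inject_errors <- function(plan, model) {
  stopifnot(inherits(plan, "trajectory_log"), inherits(model, "error_model"))
  n <- n_samples(plan)
  dt <- plan$sampling_interval
  out <- plan
  with_seed(model$seed, {
    # gantry
    out$gantry$actual <- plan$gantry$planned + model$gantry_lag_deg +
      (if (model$gantry_jitter_sd_deg > 0)
        rnorm(n, 0, model$gantry_jitter_sd_deg) else 0)

    # MLC: operate on non-parked leaves only (parked = constant and closed)
    parked <- parked_pairs(plan)
    act_pairs <- which(!parked)
    cols <- c(act_pairs, 60L + act_pairs)
    M <- plan$mlc$planned
    A <- M
    if (length(cols)) {
      lag_vec <- rep(c(-1, 1) * model$mlc_lag_mm, each = length(act_pairs))
      A[, cols] <- sweep(M[, cols, drop = FALSE], 2, lag_vec, "+")
      if (model$mlc_jitter_sd_mm > 0) {
        A[, cols] <- A[, cols, drop = FALSE] +
          matrix(rnorm(n * length(cols), 0, model$mlc_jitter_sd_mm),
                 n, length(cols))
      }
      if (model$stuck_leaf_prob > 0) {
        stuck <- cols[runif(length(cols)) < model$stuck_leaf_prob]
        for (j in stuck) A[, j] <- M[1, j]
      }
      # collision guard: clamp negative gaps to zero at the midpoint
      gA <- A[, 60L + act_pairs, drop = FALSE] - A[, act_pairs, drop = FALSE]
      neg <- gA < 0
      n_clamped <- sum(neg)
      if (n_clamped > 0) {
        mid <- (A[, act_pairs, drop = FALSE] +
                  A[, 60L + act_pairs, drop = FALSE]) / 2
        Aa <- A[, act_pairs, drop = FALSE]
        Ab <- A[, 60L + act_pairs, drop = FALSE]
        Aa[neg] <- mid[neg]
        Ab[neg] <- mid[neg]
        A[, act_pairs] <- Aa
        A[, 60L + act_pairs] <- Ab
      }
      attr(out, "injection_issues") <- n_clamped
    } else attr(out, "injection_issues") <- 0L
    out$mlc$actual <- A

    # MU: perturb per-sample increments multiplicatively, keep non-decreasing
    if (model$dose_rate_fluctuation_sd_frac > 0) {
      d <- c(plan$mu$planned[1], diff(plan$mu$planned))
      d_act <- pmax(0, d * (1 + rnorm(n, 0, model$dose_rate_fluctuation_sd_frac)))
      out$mu$actual <- cumsum(d_act)
      dr <- d_act / dt * 60
      dr[1] <- 0
      out$dose_rate_actual <- dr
    }
  })
  out
}

# Pairs parked closed for the whole field: planned gap <= closed tolerance at
# every sample and both planned leaves constant.
parked_pairs <- function(log) {
  g <- leaf_gaps(log, "planned")
  closed <- apply(g, 2, function(x) all(x <= CLOSED_GAP_TOL))
  constA <- apply(log$mlc$planned[, 1:60, drop = FALSE], 2,
                  function(x) diff(range(x)) < 1e-12)
  constB <- apply(log$mlc$planned[, 61:120, drop = FALSE], 2,
                  function(x) diff(range(x)) < 1e-12)
  closed & constA & constB
}

#' Site preset: distributions of plan and error parameters for one archetype
#'
#' A preset specifies uniform ranges for each [plan_config()] and
#' [error_model()] parameter; cohort generation draws one value per log.
#' The three default archetypes create between-site heterogeneity (aperture
#' size, modulation, MU) without claiming clinical realism.
#'
#' @param name `"prostate"`, `"spine"` or `"thorax"`.
#' @param plan_ranges,error_ranges Named lists of `c(lo, hi)` ranges (scalars
#'   allowed) overriding the archetype defaults.
#' @return A `site_preset` list.
#' @export
site_preset <- function(name = c("prostate", "spine", "thorax"),
                        plan_ranges = list(), error_ranges = list()) {
  name <- match.arg(name)
  base <- switch(name,
    prostate = list(
      pattern = "conformal_ellipse",
      n_control_points = c(60, 100), arc_span_deg = c(150, 200),
      total_mu = c(250, 450), aperture_scale_mm = c(45, 65),
      modulation_depth = c(0.1, 0.4)),
    spine = list(
      pattern = "sliding_window",
      n_control_points = c(80, 120), arc_span_deg = c(160, 200),
      total_mu = c(400, 650), aperture_scale_mm = c(18, 32),
      modulation_depth = c(0.5, 0.9)),
    thorax = list(
      pattern = "random_modulated",
      n_control_points = c(70, 110), arc_span_deg = c(120, 180),
      total_mu = c(300, 550), aperture_scale_mm = c(30, 50),
      modulation_depth = c(0.3, 0.7)))
  err <- switch(name,
    prostate = list(mlc_lag_mm = c(0, 0.15), mlc_jitter_sd_mm = c(0.02, 0.25),
                    gantry_jitter_sd_deg = c(0.02, 0.15),
                    gantry_lag_deg = c(-0.1, 0.1),
                    dose_rate_fluctuation_sd_frac = c(0.005, 0.03),
                    stuck_leaf_prob = c(0, 0.004)),
    spine = list(mlc_lag_mm = c(0, 0.15), mlc_jitter_sd_mm = c(0.05, 0.35),
                 gantry_jitter_sd_deg = c(0.02, 0.2),
                 gantry_lag_deg = c(-0.15, 0.15),
                 dose_rate_fluctuation_sd_frac = c(0.01, 0.05),
                 stuck_leaf_prob = c(0, 0.008)),
    thorax = list(mlc_lag_mm = c(0, 0.15), mlc_jitter_sd_mm = c(0.03, 0.3),
                  gantry_jitter_sd_deg = c(0.02, 0.18),
                  gantry_lag_deg = c(-0.12, 0.12),
                  dose_rate_fluctuation_sd_frac = c(0.008, 0.04),
                  stuck_leaf_prob = c(0, 0.006)))
  base[names(plan_ranges)] <- plan_ranges
  err[names(error_ranges)] <- error_ranges
  structure(list(name = name, plan = base, error = err),
            class = "site_preset")
}

#' Default site presets (prostate, spine, thorax)
#' @return Named list of three [site_preset()] objects.
#' @export
default_site_presets <- function() {
  list(prostate = site_preset("prostate"),
       spine = site_preset("spine"),
       thorax = site_preset("thorax"))
}

draw_range <- function(r) if (length(r) == 1) r else runif(1, r[1], r[2])

# Draw one (plan_config, error_model) pair from a preset, deterministically
# for a given seed.
draw_from_preset <- function(preset, seed) {
  with_seed(seed, {
    span <- draw_range(preset$plan$arc_span_deg)
    start <- runif(1, 0, 360 - span)
    pc <- plan_config(
      n_control_points = round(draw_range(preset$plan$n_control_points)),
      arc_start_deg = start, arc_stop_deg = start + span,
      total_mu = draw_range(preset$plan$total_mu),
      pattern = preset$plan$pattern,
      aperture_scale_mm = draw_range(preset$plan$aperture_scale_mm),
      modulation_depth = draw_range(preset$plan$modulation_depth),
      seed = derive_seed(seed, "plan"))
    em <- error_model(
      mlc_lag_mm = draw_range(preset$error$mlc_lag_mm),
      mlc_jitter_sd_mm = draw_range(preset$error$mlc_jitter_sd_mm),
      gantry_jitter_sd_deg = draw_range(preset$error$gantry_jitter_sd_deg),
      gantry_lag_deg = draw_range(preset$error$gantry_lag_deg),
      dose_rate_fluctuation_sd_frac =
        draw_range(preset$error$dose_rate_fluctuation_sd_frac),
      stuck_leaf_prob = draw_range(preset$error$stuck_leaf_prob),
      seed = derive_seed(seed, "error"))
    list(plan_config = pc, error_model = em)
  })
}

#' Generate a synthetic VMAT cohort
#'
#' Draws `n_per_site` error-injected deliveries per site preset. Per-log
#' seeds are derived reproducibly from the master seed, site name and index,
#' so cohorts are identical across runs (and under any generation order).
#'
#' @param presets List of [site_preset()] objects
#'   (default [default_site_presets()]).
#' @param n_per_site Number of logs per site.
#' @param seed Master integer seed.
#' @return List of valid `trajectory_log`s with `site_label` set; attribute
#'   `manifest` is a data frame of per-log seeds and error parameters.
#' @export
generate_cohort <- function(presets = default_site_presets(),
                            n_per_site = 10, seed = 1L) {
  logs <- list()
  man <- list()
  for (preset in presets) {
    for (i in seq_len(n_per_site)) {
      log_seed <- derive_seed(seed, preset$name, i)
      drawn <- draw_from_preset(preset, log_seed)
      log <- inject_errors(generate_plan(drawn$plan_config),
                           drawn$error_model)
      log$meta$site_label <- preset$name
      log$meta$field_id <- sprintf("%s_%03d", preset$name, i)
      logs[[length(logs) + 1L]] <- log
      man[[length(man) + 1L]] <- data.frame(
        field_id = log$meta$field_id, site = preset$name, seed = log_seed,
        n_samples = n_samples(log),
        total_mu = max(log$mu$planned),
        drawn$error_model[setdiff(names(drawn$error_model), "seed")],
        stringsAsFactors = FALSE)
    }
  }
  attr(logs, "manifest") <- do.call(rbind, man)
  logs
}

#' Stream a synthetic cohort into a feature (and optionally label) table
#'
#' Generates one log at a time, extracts its features and optionally its
#' gamma-passing-rate labels, and discards the log, so arbitrarily large
#' cohorts fit in memory.
#'
#' @inheritParams generate_cohort
#' @param label If `TRUE`, compute GPR labels for each log via [label_log()].
#' @param criteria List of `c(dose_percent, distance_mm)` gamma criteria
#'   (used when `label = TRUE`).
#' @param ... Further arguments passed to [label_log()].
#' @return Data frame: `field_id`, `site`, the 13 feature columns and, when
#'   labelling, one `gpr_<dose>_<dist>` column per criterion.
#' @export
simulate_dataset <- function(presets = default_site_presets(),
                             n_per_site = 10, seed = 1L, label = FALSE,
                             criteria = default_gamma_criteria(), ...) {
  rows <- list()
  for (preset in presets) {
    for (i in seq_len(n_per_site)) {
      log_seed <- derive_seed(seed, preset$name, i)
      drawn <- draw_from_preset(preset, log_seed)
      log <- inject_errors(generate_plan(drawn$plan_config),
                           drawn$error_model)
      log$meta$site_label <- preset$name
      log$meta$field_id <- sprintf("%s_%03d", preset$name, i)
      fv <- extract_features(log)
      row <- data.frame(field_id = log$meta$field_id, site = preset$name,
                        as.list(fv), stringsAsFactors = FALSE)
      if (label) {
        g <- label_log(log, criteria = criteria, ...)
        row <- cbind(row, as.list(g))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
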