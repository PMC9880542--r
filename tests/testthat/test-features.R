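# The 13 predictors: hand-computed examples, algebraic identities,
# Monte-Carlo checks, and loop-based oracle equivalence.

test_that("axis_rmse matches hand evaluations and the offset identity", {
  expect_equal(axis_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(axis_rmse(c(0, 0), c(3, 4)), sqrt((9 + 16) / 2))
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    d <- runif(1, -10, 10)
    x <- rnorm(n)
    expect_equal(axis_rmse(x, x + d), abs(d))
  }
  expect_error(axis_rmse(numeric(0), numeric(0)), "non-empty")
})

test_that("central-difference kinematics are exact on polynomial motion", {
  dt <- 0.02
  t <- seq(0, 1, by = dt)
  k <- derive_kinematics(3.5 * t + 1, dt)            # linear ramp
  expect_equal(k$velocity, rep(3.5, length(t)))
  # acceleration is exact strictly inside the one-sided boundary stencils
  inner <- 3:(length(t) - 2)
  expect_equal(k$acceleration[inner], rep(0, length(inner)))
  k2 <- derive_kinematics(0.5 * 4 * t^2, dt)         # quadratic, a = 4
  expect_equal(k2$acceleration[inner], rep(4, length(inner)))
  k3 <- derive_kinematics(rep(2, 30), dt)
  expect_equal(k3$velocity, rep(0, 30))
  expect_equal(k3$acceleration, rep(0, 30))
  expect_error(derive_kinematics(c(1, 2), dt), "at least 3")
})

test_that("mlc_rmse pools moving leaves and excludes parked pairs", {
  plan <- cached("small_plan", small_plan())
  for (ord in c("position", "velocity", "acceleration")) {
    expect_equal(mlc_rmse(plan, ord), 0)
  }
  lag <- inject_errors(plan, error_model(mlc_lag_mm = 1, seed = 2))
  expect_equal(mlc_rmse(lag, "position"), 1.0)
  # a parked pair with an error on it must not dilute the statistic:
  # corrupting a parked pair's actual has no effect
  lag2 <- lag
  lag2$mlc$actual[, 1] <- lag2$mlc$actual[, 1] - 5
  lag2$mlc$actual[, 61] <- lag2$mlc$actual[, 61] - 5
  expect_equal(mlc_rmse(lag2, "position"), 1.0)
})

test_that("velocity-order MLC RMSE matches differenced-white-noise theory", {
  # white N(0, s) position noise: central-difference velocity error has
  # sd = s * sqrt(2) / (2 dt) at interior samples
  n <- 10000
  s <- 0.3
  dt <- 0.02
  m <- matrix(0, n, 120)
  m[, 30] <- -20; m[, 90] <- 20
  m[, 30] <- m[, 30] + seq(0, 1, length.out = n)  # moving pair
  base <- trajectory_log(gantry_planned = rep(0, n), gantry_actual = rep(0, n),
                         mlc_planned = m, mlc_actual = m,
                         mu_planned = seq_len(n), mu_actual = seq_len(n),
                         dose_rate_actual = rep(60, n))
  noisy <- inject_errors(base, error_model(mlc_jitter_sd_mm = s, seed = 5))
  expect_equal(mlc_rmse(noisy, "velocity"), s * sqrt(2) / (2 * dt),
               tolerance = 0.10)
})

test_that("weighted MLC RMSE obeys its algebraic identities", {
  plan <- cached("small_plan", small_plan())
  for (ord in c("position", "velocity", "acceleration")) {
    expect_equal(weighted_mlc_rmse(plan, ord), 0)
  }
  # actual MU a constant multiple of planned, positions equal -> exactly 0
  scaled <- plan
  scaled$mu$actual <- plan$mu$planned * 2.7
  scaled$dose_rate_actual <- plan$dose_rate_actual * 2.7
  expect_equal(weighted_mlc_rmse(scaled, "position"), 0)
})

test_that("uniform lag with uniform per-sample MU gives |lag|/N", {
  n <- 50
  m <- matrix(0, n, 120)
  m[, 25] <- -10 - seq(0, 1, length.out = n)
  m[, 85] <- 10
  ma <- m
  ma[, c(25, 85)] <- ma[, c(25, 85)] + c(-1, 1)[rep(1:2, each = n)]
  mu <- seq_len(n) / n * 100  # every sample delivers 2 MU
  log <- trajectory_log(gantry_planned = rep(0, n), gantry_actual = rep(0, n),
                        mlc_planned = m, mlc_actual = ma,
                        mu_planned = mu, mu_actual = mu,
                        dose_rate_actual = rep(300, n))
  expect_equal(weighted_mlc_rmse(log, "position"), 1 / n)
})

test_that("field opening series matches geometry", {
  rect <- rect_log(pairs = 21:40, half_mm = 50)     # 100 x 100 mm field
  expect_equal(field_opening_series(rect, "planned"), rep(10000, 10))
  closed <- rect_log(pairs = 21:40, half_mm = 0.2)  # below closed tolerance
  expect_equal(field_opening_series(closed, "planned"), rep(0, 10))
  # ellipse aperture area converges to pi * a * b
  ell <- generate_plan(plan_config(n_control_points = 5, arc_start_deg = 0,
                                   arc_stop_deg = 20, total_mu = 10,
                                   pattern = "conformal_ellipse",
                                   aperture_scale_mm = 50,
                                   modulation_depth = 0, seed = 1))
  expect_equal(field_opening_series(ell, "planned")[1], pi * 50 * 50,
               tolerance = 0.05)
})

test_that("MCS is 1 for a static uniform rectangle and bounded in (0, 1]", {
  expect_equal(compute_mcs(rect_log()), 1)
  for (seed in 1:8) {
    log <- inject_errors(small_plan(seed = seed),
                         error_model(mlc_jitter_sd_mm = 0.3, seed = seed))
    m <- compute_mcs(log, "actual")
    expect_gt(m, 0)
    expect_lte(m, 1)
  }
})

test_that("modulated sliding-window plans score lower MCS than static conformal", {
  for (seed in 1:10) {
    sw <- generate_plan(plan_config(n_control_points = 30, arc_start_deg = 0,
                                    arc_stop_deg = 60, total_mu = 80,
                                    pattern = "sliding_window",
                                    aperture_scale_mm = 40,
                                    modulation_depth = 0.7, seed = seed))
    st <- generate_plan(plan_config(n_control_points = 30, arc_start_deg = 0,
                                    arc_stop_deg = 60, total_mu = 80,
                                    pattern = "conformal_ellipse",
                                    aperture_scale_mm = 40,
                                    modulation_depth = 0, seed = seed))
    expect_lt(compute_mcs(sw), compute_mcs(st))
  }
})

test_that("MCS is invariant under uniform MU rescaling", {
  log <- cached("small_plan", small_plan())
  scaled <- log
  scaled$mu$planned <- log$mu$planned * 13.7
  scaled$mu$actual <- log$mu$actual * 13.7
  expect_equal(compute_mcs(scaled), compute_mcs(log))
})

test_that("extract_features populates all 13 fields with correct zeros", {
  f <- extract_features(cached("small_plan", small_plan()))
  expect_named(f, feature_names())
  rmse_fields <- grep("rmse", names(f), value = TRUE)
  expect_equal(unname(f[rmse_fields]), rep(0, 10))
  expect_true(all(f[c("dose_rate", "mu_per_arc", "mcs")] > 0))
  expect_true(f["mcs"] <= 1)
})

test_that("each error axis perturbs only its own feature group", {
  plan <- cached("small_plan", small_plan())
  mlc_feats <- c("mlc_position_rmse", "mlc_velocity_rmse",
                 "mlc_acceleration_rmse", "field_opening_rmse")
  gantry_feats <- c("gantry_position_rmse", "gantry_velocity_rmse",
                    "gantry_acceleration_rmse")
  f_g <- extract_features(inject_errors(plan,
    error_model(gantry_jitter_sd_deg = 0.3, seed = 1)))
  expect_true(all(f_g[gantry_feats] > 0))
  expect_equal(unname(f_g[mlc_feats]), rep(0, 4))
  f_m <- extract_features(inject_errors(plan,
    error_model(mlc_jitter_sd_mm = 0.3, seed = 1)))
  expect_true(all(f_m[mlc_feats] > 0))
  expect_equal(unname(f_m[gantry_feats]), rep(0, 3))
})

test_that("feature matrix over a cohort is complete and finite", {
  logs <- cached("tiny_cohort", generate_cohort(n_per_site = 5, seed = 42))
  tab <- extract_features_cohort(logs)
  expect_equal(dim(tab), c(15, 15))  # field_id, site + 13 features
  expect_false(anyNA(tab))
})

test_that("scaling all MLC deviations by c scales mlc_position_rmse by c", {
  log <- inject_errors(cached("small_plan", small_plan()),
                       error_model(mlc_jitter_sd_mm = 0.2, seed = 9))
  base <- mlc_rmse(log, "position")
  for (c_scale in c(0.5, 3)) {
    scaled <- log
    scaled$mlc$actual <- log$mlc$planned +
      c_scale * (log$mlc$actual - log$mlc$planned)
    expect_equal(mlc_rmse(scaled, "position"), c_scale * base)
  }
})

test_that("RMSE operations agree with naive loop references on random logs", {
  for (seed in 1:30) {
    log <- random_log(seed, n = 8)
    expect_equal(axis_rmse(log$gantry), rmse_ref(log$gantry$planned,
                                                 log$gantry$actual),
                 tolerance = 1e-9)
    for (ord in c("position", "velocity", "acceleration")) {
      expect_equal(mlc_rmse(log, ord), mlc_rmse_ref(log, ord),
                   tolerance = 1e-9)
      expect_equal(weighted_mlc_rmse(log, ord),
                   weighted_mlc_rmse_ref(log, ord), tolerance = 1e-9)
    }
  }
})
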