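# Independent brute-force reference implementations (plain loops, no shared
# code with the package internals) plus small fixture builders. Oracles stay
# deliberately naive.

# ---- fixture builders -------------------------------------------------------

# Fully random but valid trajectory log (non-negative gaps, monotone MU).
random_log <- function(seed, n = 20) {
  set.seed(seed)
  A <- matrix(runif(n * 60, -60, 0), n, 60)
  gap <- matrix(runif(n * 60, 0, 40), n, 60)
  mu <- cumsum(runif(n, 0, 0.5))
  trajectory_log(
    gantry_planned = cumsum(runif(n, 0, 0.2)),
    gantry_actual = cumsum(runif(n, 0, 0.2)),
    mlc_planned = cbind(A, A + gap),
    mlc_actual = cbind(A + rnorm(n * 60, 0, 0.2),
                       A + gap + rnorm(n * 60, 0, 0.2)) |>
      (\(m) { g <- m[, 61:120] - m[, 1:60]
              m[, 61:120][g < 0] <- m[, 1:60][g < 0]; m })(),
    mu_planned = mu, mu_actual = mu * runif(1, 0.9, 1.1),
    dose_rate_actual = runif(n, 0, 600))
}

# Static rectangular field: uniform gap `width_mm` over `pairs`, constant.
rect_log <- function(n = 10, pairs = 21:40, half_mm = 50, total_mu = 100) {
  m <- matrix(0, n, 120)
  m[, pairs] <- -half_mm
  m[, 60 + pairs] <- half_mm
  trajectory_log(gantry_planned = seq_len(n), gantry_actual = seq_len(n),
                 mlc_planned = m, mlc_actual = m,
                 mu_planned = seq_len(n) / n * total_mu,
                 mu_actual = seq_len(n) / n * total_mu,
                 dose_rate_actual = rep(300, n))
}

# Small error-free plan used across tests (about 500 samples).
small_plan <- function(seed = 3, pattern = "sliding_window",
                       aperture = 30, depth = 0.5, mu = 70, span = 50) {
  generate_plan(plan_config(n_control_points = 40, arc_start_deg = 0,
                            arc_stop_deg = span, total_mu = mu,
                            pattern = pattern, aperture_scale_mm = aperture,
                            modulation_depth = depth, seed = seed))
}

# Lazy per-session cache for expensive shared fixtures.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# ---- naive reference computations ------------------------------------------

rmse_ref <- function(planned, actual) {
  s <- 0
  for (i in seq_along(planned)) s <- s + (planned[i] - actual[i])^2
  sqrt(s / length(planned))
}

central_diff_ref <- function(x, dt) {
  n <- length(x)
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  for (i in 2:(n - 1)) v[i] <- (x[i + 1] - x[i - 1]) / (2 * dt)
  v
}

moving_pair_cols_ref <- function(log) {
  keep <- integer(0)
  for (p in 1:60) {
    a <- log$mlc$planned[, p]
    b <- log$mlc$planned[, 60 + p]
    parked <- all(b - a <= 0.5) && diff(range(a)) < 1e-12 &&
      diff(range(b)) < 1e-12
    if (!parked) keep <- c(keep, p, 60 + p)
  }
  keep
}

order_series_ref <- function(x, order, dt) {
  if (order == "position") return(x)
  v <- central_diff_ref(x, dt)
  if (order == "velocity") return(v)
  central_diff_ref(v, dt)
}

mlc_rmse_ref <- function(log, order) {
  cols <- moving_pair_cols_ref(log)
  s <- 0
  n_terms <- 0
  for (j in cols) {
    p <- order_series_ref(log$mlc$planned[, j], order, log$sampling_interval)
    a <- order_series_ref(log$mlc$actual[, j], order, log$sampling_interval)
    for (i in seq_along(p)) {
      s <- s + (p[i] - a[i])^2
      n_terms <- n_terms + 1
    }
  }
  sqrt(s / n_terms)
}

weighted_mlc_rmse_ref <- function(log, order) {
  cols <- moving_pair_cols_ref(log)
  n <- length(log$mu$planned)
  d_act <- c(log$mu$actual[1], diff(log$mu$actual))
  d_pln <- c(log$mu$planned[1], diff(log$mu$planned))
  w <- d_act / sum(d_act)
  wh <- d_pln / sum(d_pln)
  tot <- 0
  for (i in seq_len(n)) {
    s_leaf <- 0
    for (j in cols) {
      p <- order_series_ref(log$mlc$planned[, j], order,
                            log$sampling_interval)[i]
      a <- order_series_ref(log$mlc$actual[, j], order,
                            log$sampling_interval)[i]
      s_leaf <- s_leaf + (w[i] * p - wh[i] * a)^2
    }
    tot <- tot + s_leaf / length(cols)
  }
  sqrt(tot / n)
}

r2_ref <- function(truth, pred) {
  m <- mean(truth)
  num <- 0
  den <- 0
  for (i in seq_along(truth)) {
    num <- num + (truth[i] - pred[i])^2
    den <- den + (truth[i] - m)^2
  }
  1 - num / den
}

rmse_score_ref <- function(truth, pred) rmse_ref(truth, pred)

# Exhaustive pixel-only gamma (no interpolation): the stated search oracle.
gamma_brute_ref <- function(ref, ev, spacing, dose_pct, dist_mm,
                            thresh_frac = 0.1, radius_mm = 3 * dist_mm) {
  nr <- nrow(ref)
  nc <- ncol(ref)
  dose_tol <- dose_pct / 100 * max(ref)
  thresh <- thresh_frac * max(ref)
  m <- floor(radius_mm / spacing)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (ref[r, c] < thresh) next
      best <- Inf
      for (i in -m:m) {
        for (j in -m:m) {
          r2 <- (i * spacing)^2 + (j * spacing)^2
          if (r2 > radius_mm^2 + 1e-12) next
          rr <- r + i
          cc <- c + j
          if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
          g2 <- ((ev[rr, cc] - ref[r, c]) / dose_tol)^2 + r2 / dist_mm^2
          if (g2 < best) best <- g2
        }
      }
      out[r, c] <- sqrt(best)
    }
  }
  out
}

# Random smooth map pair for gamma oracle tests.
random_map_pair <- function(seed, n = 64) {
  set.seed(seed)
  base <- matrix(0, n, n)
  cx <- runif(1, n * 0.35, n * 0.65)
  cy <- runif(1, n * 0.35, n * 0.65)
  rad <- runif(1, n * 0.2, n * 0.3)
  for (r in seq_len(n)) {
    d2 <- (r - cy)^2 + (seq_len(n) - cx)^2
    base[r, ] <- 100 * exp(-d2 / (2 * rad^2))
  }
  pert <- base * (1 + matrix(rnorm(n * n, 0, 0.01), n, n)) +
    matrix(rnorm(n * n, 0, 0.3), n, n)
  pert[pert < 0] <- 0
  list(ref = base, ev = pert)
}
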