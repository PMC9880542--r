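# Fluence accumulation and global gamma analysis.

test_that("a static open square field maps to a flat 100 plateau", {
  fm <- compute_fluence(rect_log(pairs = 21:40, half_mm = 50), "planned")
  v <- fm$values
  expect_equal(unname(v[91:110, 81:120]), matrix(100, 20, 40))  # interior
  expect_equal(v[50, 50], 0)
  expect_true(all(v >= 0))
})

test_that("two equal-MU disjoint apertures accumulate to equal values", {
  n <- 2
  m1 <- matrix(0, n, 120)
  m1[1, 25] <- -40; m1[1, 85] <- -10   # sample 1: left box, pair 25
  m1[2, 25] <- 10; m1[2, 85] <- 40     # sample 2: right box, same pair
  log <- trajectory_log(gantry_planned = c(0, 1), gantry_actual = c(0, 1),
                        mlc_planned = m1, mlc_actual = m1,
                        mu_planned = c(5, 10), mu_actual = c(5, 10),
                        dose_rate_actual = c(300, 300), validate = FALSE)
  fm <- compute_fluence(log, "planned")
  # pair 25 spans y in [-30, -25] mm -> row 74 is y = -27 mm
  left <- fm$values[74, 75]    # x = -26 mm, inside the left box
  right <- fm$values[74, 125]  # x = +24 mm, inside the right box
  expect_equal(left, 100)
  expect_equal(right, 100)
})

test_that("zero-error logs give pixel-identical planned and actual maps", {
  plan <- cached("small_plan", small_plan())
  expect_identical(compute_fluence(plan, "planned")$values,
                   compute_fluence(plan, "actual")$values)
})

test_that("apertures outside the extent raise an error naming the sample", {
  expect_error(compute_fluence(rect_log(half_mm = 80), "planned",
                               extent_mm = 100),
               "sample 1")
})

test_that("identical maps give gamma 0 and GPR 100", {
  plan <- cached("small_plan", small_plan())
  fm <- compute_fluence(plan, "planned")
  g <- gamma_index(fm, fm, 1, 1)
  expect_equal(g$gpr_percent, 100)
  expect_equal(max(g$gamma_map, na.rm = TRUE), 0)
  expect_equal(g$n_evaluated, sum(!is.na(g$gamma_map)))
})

test_that("uniform dose scaling hits the closed-form gamma exactly", {
  ref <- fluence_map(matrix(100, 40, 40), 1, c(0, 0))
  ev1 <- fluence_map(matrix(100 * 1.01, 40, 40), 1, c(0, 0))
  g1 <- gamma_index(ref, ev1, 1, 1)
  expect_equal(max(abs(g1$gamma_map - 1)), 0, tolerance = 1e-9)
  expect_equal(g1$gpr_percent, 100)  # gamma = 1 passes inclusively
  ev2 <- fluence_map(matrix(100 * 1.02, 40, 40), 1, c(0, 0))
  g2 <- gamma_index(ref, ev2, 1, 1)
  expect_equal(max(abs(g2$gamma_map - 2)), 0, tolerance = 1e-9)
  expect_equal(g2$gpr_percent, 0)
})

test_that("a pure translation in a uniform gradient matches the closed form", {
  # for eval = ref shifted by d in a uniform gradient s, the continuum gamma
  # minimises ((d - x) s / D)^2 + (x / b)^2 over the retraction x, giving
  # gamma = d * sqrt(alpha beta / (alpha + beta)), alpha = s^2/D^2, b = DTA
  n <- 60
  ramp <- matrix(rep(seq(40, 100, length.out = n), each = n), n, n)
  shift <- 2L  # pixels = 2 mm
  ev <- ramp
  ev[, (shift + 1):n] <- ramp[, 1:(n - shift)]
  ev[, 1:shift] <- ramp[, 1]
  dose_pct <- 3
  dta <- 2
  g <- gamma_index(fluence_map(ramp, 1, c(0, 0)), fluence_map(ev, 1, c(0, 0)),
                   dose_pct, dta, search_radius_mm = 8)
  s <- 60 / (n - 1)                      # gradient in %/mm
  alpha <- (s / (dose_pct / 100 * 100))^2
  beta <- 1 / dta^2
  expected <- shift * sqrt(alpha * beta / (alpha + beta))
  interior <- g$gamma_map[20:40, 20:40]
  expect_equal(max(abs(interior - expected)), 0, tolerance = 0.02)
})

test_that("grid mismatch and bad search radius are configuration errors", {
  a <- fluence_map(matrix(10, 8, 8), 1, c(0, 0))
  b <- fluence_map(matrix(10, 9, 9), 1, c(0, 0))
  expect_error(gamma_index(a, b, 2, 2), "grids differ")
  expect_error(gamma_index(a, a, 2, 2, search_radius_mm = 1),
               "search_radius")
})

test_that("raising the low-dose threshold never increases n_evaluated", {
  pair <- random_map_pair(5)
  ref <- fluence_map(pair$ref, 1, c(0, 0))
  ev <- fluence_map(pair$ev, 1, c(0, 0))
  n_prev <- Inf
  for (thr in c(0.05, 0.1, 0.3, 0.6)) {
    n_now <- gamma_index(ref, ev, 2, 2,
                         low_dose_threshold_frac = thr)$n_evaluated
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("optimised gamma agrees with the exhaustive pixel search", {
  # the sub-pixel grid contains all pixel centres, so the optimised search
  # can only improve on the pixel-only oracle; the improvement is bounded by
  # the within-cell variation of the distance and dose terms
  for (seed in 1:6) {
    pair <- random_map_pair(seed, n = 48)
    ref <- fluence_map(pair$ref, 1, c(0, 0))
    ev <- fluence_map(pair$ev, 1, c(0, 0))
    g_opt <- gamma_index(ref, ev, 2, 2)$gamma_map
    g_ref <- gamma_brute_ref(pair$ref, pair$ev, 1, 2, 2)
    expect_true(all(g_opt <= g_ref + 1e-9, na.rm = TRUE))
    grad <- max(abs(diff(pair$ev)), abs(t(diff(t(pair$ev)))))
    bound <- sqrt(2) / 2 * (1 / 2 + grad / (0.02 * max(pair$ref)))
    expect_true(all(g_ref - g_opt <= bound + 1e-9, na.rm = TRUE))
  }
})

test_that("label_log returns the four named criteria and 100 for zero error", {
  g <- label_log(cached("small_plan", small_plan()))
  expect_named(g, c("gpr_2_2", "gpr_2_1", "gpr_1_2", "gpr_1_1"))
  expect_equal(unname(g), rep(100, 4))
})

test_that("composite GPR reduces to the per-field result for one log", {
  plan <- cached("small_plan", small_plan())
  noisy <- inject_errors(plan, error_model(mlc_jitter_sd_mm = 0.3, seed = 2))
  expect_equal(label_composite(list(noisy), criteria = list(c(1, 1))),
               label_log(noisy, criteria = list(c(1, 1))))
  expect_equal(unname(label_composite(list(plan, plan))), rep(100, 4))
})

test_that("fluence maps export as plain text grids", {
  fm <- compute_fluence(rect_log(), "planned", pixel_spacing_mm = 4)
  path <- withr::local_tempfile(fileext = ".txt")
  write_fluence(fm, path)
  back <- as.matrix(utils::read.table(path))
  expect_equal(unname(back), unname(fm$values))
})
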