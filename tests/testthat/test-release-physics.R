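test_that("lateral surface area is the mid-wall cylinder with sealed ends", {
  expect_equal(lateral_surface_area(default_config(40, 0.2)),
               pi * 2.3 * 40)
  expect_equal(lateral_surface_area(default_config(40, 0.2)), 289.03,
               tolerance = 1e-4)
  expect_equal(lateral_surface_area(default_config(10, 0.2)), 72.26,
               tolerance = 1e-4)
  # log-mean correction approaches the mid-wall value for thin walls
  thin <- default_config(40, 0.01)
  expect_equal(lateral_surface_area(thin, "logmean"),
               lateral_surface_area(thin, "midwall"), tolerance = 1e-5)
  expect_error(implant_config(0, 0.2), "length")
  expect_error(implant_config(40, 1.3), "wall_thickness")
  expect_error(implant_config(40, 0), "wall_thickness")
})

test_that("release rate follows the steady-state membrane law", {
  a <- lateral_surface_area(default_config(40, 0.2))
  expect_equal(release_rate(0.1, 12.4, 0.2, a), 1.792, tolerance = 1e-3)
  expect_equal(release_rate(0.1, 12.4, 0.2, a),
               0.1 * 0.0124 * a / 0.2)
  expect_equal(membrane_flux(0.1, 12.4, 0.2), release_rate(0.1, 12.4, 0.2, a) / a)
  expect_error(release_rate(0, 12.4, 0.2, a), "domain")
  expect_error(release_rate(0.1, -1, 0.2, a), "domain")
})

test_that("release rate scales linearly in Dk, CsE, area and as 1/L", {
  set.seed(41)
  for (i in 1:25) {
    dk <- runif_log(1, 1e-3, 1); cse <- runif_log(1, 0.01, 80)
    L <- runif(1, 0.05, 0.3); a <- runif(1, 50, 400)
    r <- release_rate(dk, cse, L, a)
    expect_equal(release_rate(2 * dk, cse, L, a), 2 * r)
    expect_equal(release_rate(dk, 3 * cse, L, a), 3 * r)
    expect_equal(release_rate(dk, cse, L, 2 * a), 2 * r)
    expect_equal(release_rate(dk, cse, 2 * L, a), r / 2)
  }
})

test_that("predicted cumulative release is exactly linear and zero at t = 0", {
  expect_equal(release_rate(0.1, 12.4, 0.2, 100) * 10, 6.2)
  cfg <- default_config(40, 0.2)
  s <- predict_cumulative(0.1, 12.4, cfg, c(0, 7, 14, 35, 70))
  expect_s3_class(s, "release_series")
  expect_equal(s$cumulative_mass_mg[1], 0)
  rates <- s$cumulative_mass_mg[-1] / s$time_days[-1]
  expect_equal(rates, rep(rates[1], length(rates)))
  expect_equal(nrow(predict_cumulative(0.1, 12.4, cfg, numeric(0))), 0L)
  expect_error(predict_cumulative(0.1, 12.4, cfg, c(-1, 2)), "non-negative")
})

test_that("truncation at drug loading is opt-in and flagged", {
  cfg <- default_config(40, 0.2, loading = 10)
  t <- seq(0, 70, 7)
  free <- predict_cumulative(0.1, 12.4, cfg, t)
  expect_false(attr(free, "truncated"))
  expect_gt(max(free$cumulative_mass_mg), 10)
  capped <- predict_cumulative(0.1, 12.4, cfg, t, truncate_at_loading = TRUE)
  expect_true(attr(capped, "truncated"))
  expect_equal(max(capped$cumulative_mass_mg), 10)
})

test_that("Dk estimation inverts prediction at machine precision", {
  cfg <- default_config(40, 0.2)
  s <- suppressWarnings(predict_cumulative(0.0734, 12.4, cfg, seq(3.5, 70, 3.5)))
  e <- suppressWarnings(estimate_dk(s, cfg, 12.4))
  expect_equal(e$dk, 0.0734, tolerance = 1e-12)
  expect_equal(e$intercept_mg, 0, tolerance = 1e-10)
  expect_false(e$flagged)
})

test_that("Dk estimate under iid noise is accurate and well calibrated", {
  cfg <- default_config(40, 0.2)
  rate <- release_rate(0.1, 12.4, 0.2, lateral_surface_area(cfg))
  set.seed(123)
  t <- seq(3.5, 70, length.out = 20)
  m <- cummax(pmax(rate * t + rnorm(20, 0, 0.05), 0))
  e <- estimate_dk(release_series(t, m), cfg, 12.4)
  expect_lt(abs(e$dk - 0.1), 3 * e$standard_error)
  expect_equal(e$n_points, 20L)
})

test_that("Dk estimation slope matches brute-force normal equations", {
  cfg <- default_config(10, 0.07)
  set.seed(9)
  t <- sort(runif(12, 1, 60))
  m <- cummax(0.3 * t + rnorm(12, 0, 0.1))
  e <- estimate_dk(release_series(t, m), cfg, 5.6)
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% m)
  expect_equal(e$slope_mg_day, unname(beta[2, 1]))
  # origin-constrained option
  e0 <- estimate_dk(release_series(t, m), cfg, 5.6, intercept = FALSE)
  expect_equal(e0$slope_mg_day, sum(t * m) / sum(t^2))
})

test_that("Dk estimation rejects degenerate input and flags negative slopes", {
  cfg <- default_config(40, 0.2)
  expect_error(estimate_dk(release_series(3.5, 1.2), cfg, 12.4),
               "insufficient")
  expect_error(estimate_dk(release_series(c(1, 2, 3), c(1, 2, 3)), cfg, 0),
               "domain")
  # window can exclude all but one point
  s <- release_series(c(1, 2, 30), c(1, 2, 3))
  expect_error(estimate_dk(s, cfg, 12.4, fit_window = c(25, 40)),
               "insufficient")
  flat <- release_series(1:5, rep(2, 5))
  expect_true(suppressWarnings(estimate_dk(flat, cfg, 12.4))$flagged)
})

test_that("wall-thickness design inverts the rate law", {
  a <- lateral_surface_area(default_config(40, 0.2))
  L <- design_wall_thickness(1, 0.1, 12.4, a)
  expect_equal(L, 0.3584, tolerance = 1e-3)
  expect_equal(release_rate(0.1, 12.4, L, a), 1)
  # monotone decreasing in the target rate
  targets <- c(0.25, 0.5, 1, 2, 4)
  walls <- sapply(targets, design_wall_thickness, dk = 0.1, cse_mg_ml = 12.4,
                  area_mm2 = a)
  expect_true(all(diff(walls) < 0))
  expect_error(design_wall_thickness(0, 0.1, 12.4, a), "domain")
})

test_that("sample accounting reproduces the protocol arithmetic", {
  s <- accumulate_samples(c(0.01, 0.02), c(40, 40), c(3.5, 7))
  expect_equal(s$cumulative_mass_mg, c(0.4, 1.2))
  expect_equal(s$mass_per_interval_mg, c(0.4, 0.8))
  expect_equal(daily_release_rate(s)[2], 1.2 / 7)
  expect_equal(daily_release_rate(s)[2], 0.1714, tolerance = 1e-3)
  z <- accumulate_samples(rep(0, 4), rep(200, 4), c(3.5, 7, 10.5, 14))
  expect_equal(z$cumulative_mass_mg, rep(0, 4))
  one <- accumulate_samples(0.05, 40, 3.5)
  expect_equal(one$cumulative_mass_mg, one$mass_per_interval_mg)
  expect_error(accumulate_samples(c(1, 2), 40, c(1, 2)), "equal length")
  expect_error(accumulate_samples(c(-1, 2), c(40, 40), c(1, 2)),
               "non-negative")
})

test_that("release series constructor enforces its invariants", {
  expect_error(release_series(c(2, 1), c(0, 1)), "increasing")
  expect_error(release_series(c(-1, 1), c(0, 1)), ">= 0")
  expect_error(release_series(c(1, 2), c(2, 1)), "non-decreasing")
  expect_error(release_series(c(1, 2), c(-1, 1)), "non-negative")
  expect_silent(release_series(numeric(0), numeric(0)))
})
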