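make_fit <- function(alpha, beta, gamma, split = "te", characteristic = "mean",
                     instance = 1L, x_range = c(10, 320)) {
  structure(list(alpha = alpha, beta = beta, gamma = gamma, rss = 0,
                 converged = TRUE, degenerate = FALSE, x_range = x_range,
                 split = split, characteristic = characteristic,
                 instance = instance, n_points = 6L),
            class = "power_law_fit")
}

test_that("noiseless power-law points are recovered to 1e-6 (both signs of alpha)", {
  d <- c(10, 20, 40, 80, 160, 320)
  for (a in c(0.3, -0.3)) {
    pts <- data.frame(sample_count = d, value = a * d^-0.5 + 0.5)
    fit <- fit_power_law(pts)
    expect_true(fit$converged)
    expect_equal(fit$alpha, a, tolerance = 1e-6)
    expect_equal(fit$beta, -0.5, tolerance = 1e-6)
    expect_equal(fit$gamma, 0.5, tolerance = 1e-6)
  }
})

test_that("constant points give a degenerate fit with unidentifiable beta", {
  pts <- data.frame(sample_count = c(10, 20, 40), value = 0.7)
  fit <- fit_power_law(pts)
  expect_true(fit$converged)
  expect_true(fit$degenerate)
  expect_equal(fit$gamma, 0.7)
  expect_equal(fit$alpha, 0)
  expect_true(is.na(fit$beta))
  expect_equal(as.numeric(predict_accuracy(fit, 1000)), 0.7)
  expect_error(required_sample_size(fit, 0.6), class = "adaptsize_bad_fit")
})

test_that("prediction evaluates the closed form and flags extrapolation", {
  fit <- make_fit(0.3, -0.5, 0.5)
  p <- predict_accuracy(fit, 900)
  expect_equal(as.numeric(p), 0.51)
  expect_true(attr(p, "extrapolated"))
  expect_false(attr(predict_accuracy(fit, 100), "extrapolated"))
  expect_error(predict_accuracy(fit, 0), class = "adaptsize_bad_input")
  # monotone approach to gamma from above (alpha > 0) and below (alpha < 0)
  d <- c(10, 100, 1000, 1e5, 1e7)
  up <- as.numeric(predict_accuracy(make_fit(-0.3, -0.5, 0.5), d))
  down <- as.numeric(predict_accuracy(fit, d))
  expect_true(all(diff(up) > 0) && all(up < 0.5))
  expect_true(all(diff(down) < 0) && all(down > 0.5))
})

test_that("curve inversion matches the closed form and flags unreachable targets", {
  fit <- make_fit(-0.3, -0.5, 0.5)
  expect_equal(required_sample_size(fit, 0.49), 900, tolerance = 1e-9)
  expect_identical(required_sample_size(fit, 0.5), "unreachable")
  expect_identical(required_sample_size(fit, 0.51), "unreachable")
  # inverse consistency on reachable targets
  for (d in c(15, 90, 4000)) {
    target <- as.numeric(predict_accuracy(fit, d))
    expect_equal(required_sample_size(fit, target), d, tolerance = 1e-6 * d)
  }
})

test_that("uncertainty width is the q75 - q25 curve difference", {
  q25 <- make_fit(0.1, -0.5, 0.4, characteristic = "q25")
  q75 <- make_fit(0.1, -0.5, 0.5, characteristic = "q75")
  expect_equal(uncertainty_width(q25, q75, 10), 0.1)
  expect_equal(uncertainty_width(q25, q75, 1e6), 0.1)
  same <- make_fit(0.1, -0.5, 0.4, characteristic = "q75")
  expect_equal(uncertainty_width(q25, same, 50), 0)
  other <- make_fit(0.1, -0.5, 0.5, characteristic = "q75", instance = 2L)
  expect_error(uncertainty_width(q25, other, 10),
               class = "adaptsize_mismatched_fits")
})

test_that("quartile crossing detection brackets the analytic crossing point", {
  # equal beta: the width 0.2 d^-0.5 - 0.05 starts positive and crosses zero
  # at d* = (0.05 / 0.2)^(-2) = 16
  q25 <- make_fit(0.1, -0.5, 0.50, characteristic = "q25")
  q75 <- make_fit(0.3, -0.5, 0.45, characteristic = "q75")
  d_star <- 16
  cross <- percentile_crossing_check(q25, q75, 10000)
  expect_false(is.null(cross))
  expect_lt(abs(cross - d_star), 1)
  # ordered asymptotes with identical transients never cross
  a <- make_fit(0.2, -0.5, 0.4, characteristic = "q25")
  b <- make_fit(0.2, -0.5, 0.5, characteristic = "q75")
  expect_null(percentile_crossing_check(a, b, 1e6))
})

test_that("curves already crossed at the search start are reported there", {
  # limit ordering taken from a stabilized training-set run where the fitted
  # 25th-percentile limit (0.5057) exceeds the 75th-percentile limit (0.4902)
  q25 <- make_fit(0.2, -0.5, 0.5057, characteristic = "q25")
  q75 <- make_fit(0.2, -0.5, 0.4902, characteristic = "q75")
  expect_true(uncertainty_width(q25, q75, 50) < 0)
  cross <- percentile_crossing_check(q25, q75, 1e5)
  expect_equal(cross, 10)  # the smallest fitted sample size
})

test_that("curve-point construction selects the right abscissa and exclusions", {
  pool <- tiny_pool(100)
  cfg <- study_config(ladder = c(25, 50, 100), base_reps = 10, tolerance = 0.5,
                      seed = 9)
  study <- run_study(pool, ols_adapter(), cfg)
  pts_tr <- build_curve_points(study, "tr", "mean", 1L)
  pts_te <- build_curve_points(study, "te", "mean", 1L)
  d_ns <- vapply(study$sizes, `[[`, numeric(1), "d_n")
  expect_equal(pts_tr$sample_count, floor(0.7 * d_ns))
  expect_equal(pts_te$sample_count, d_ns - floor(0.7 * d_ns))
  # d_n = 100 with c = 0.7 puts the training point at x = 70
  expect_equal(pts_tr$sample_count[3], 70)
  # below-n0 exclusion keeps >= n0; two ladder points cannot support 3 params
  expect_error(build_curve_points(study, "te", "mean", 1L, n0 = 50),
               class = "adaptsize_underdetermined")
  # the literal rule would discard everything at and above n0
  expect_error(build_curve_points(study, "te", "mean", 1L, n0 = 50,
                                  n0_rule = "at_and_above"),
               class = "adaptsize_underdetermined")
  expect_error(fit_power_law(data.frame(sample_count = c(10, 20),
                                        value = c(0.5, 0.6))),
               class = "adaptsize_underdetermined")
})

test_that("round-trip recovery works across random parameter draws", {
  set.seed(19)
  d <- c(12, 25, 50, 100, 200, 400, 800)
  for (i in 1:10) {
    a <- stats::runif(1, -1, 1)
    if (abs(a) < 0.05) a <- 0.3
    b <- stats::runif(1, -1.5, -0.2)
    g <- stats::runif(1, 0, 1)
    fit <- fit_power_law(data.frame(sample_count = d, value = a * d^b + g))
    expect_equal(fit$alpha, a, tolerance = 1e-5)
    expect_equal(fit$beta, b, tolerance = 1e-5)
    expect_equal(fit$gamma, g, tolerance = 1e-5)
  }
})
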