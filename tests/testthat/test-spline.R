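test_that("range-average design vectors agree with adaptive quadrature", {
  knots <- c(100, 130, 160, 200)
  spec <- spline_spec(knots, left_linear = FALSE, right_linear = FALSE)
  set.seed(21)
  for (i in 1:4) {
    gvec <- runif(4, -0.02, 0.04)
    f <- function(x) vapply(x, function(xx) {
      sum(bopmeta:::point_design_row(xx, knots) * gvec)
    }, numeric(1))
    for (r in list(c(105, 145), c(100, 200), c(131.5, 158), c(160, 199))) {
      v <- range_average_design(spec, r[1], r[2])
      oracle <- integrate(f, r[1], r[2], rel.tol = 1e-12)$value / diff(r)
      expect_equal(sum(v * gvec), oracle, tolerance = 1e-8)
    }
    # degenerate range = pointwise evaluation
    expect_equal(sum(range_average_design(spec, 150, 150) * gvec), f(150))
  }
  # constant-slope spline: average over (a,b) equals the midpoint value
  g1 <- rep(0.03, 4)
  v <- range_average_design(spec, 120, 180)
  expect_equal(sum(v * g1), 0.03 * (150 - 100), tolerance = 1e-10)
  expect_error(range_average_design(spec, 90, 110), "outside")
})

test_that("noise-free fits recover the generating spline exactly", {
  knots <- c(100, 140, 170, 200)
  spec <- spline_spec(knots, right_tail_prior_sd = Inf)
  gvec_true <- c(0.01, 0.01, 0.03, 0.03)  # respects both linear tails
  t <- noise_free_rows(knots, gvec_true, n = 30, se = 0.01)
  fit <- fit_single_model(t, spec, monotone = TRUE, trim_fraction = 0)
  xs <- seq(100, 200, by = 1)
  expect_lt(max(abs(member_curve(fit, xs) -
                      bopmeta:::eval_spline(gvec_true, knots, xs))),
            1e-6)

  # flat truth -> identically zero curve
  t0 <- make_table(rep(110, 8), rep(120, 8), seq(130, 165, 5), seq(140, 175, 5),
                   log_effect = rep(0, 8), se = 0.05)
  fit0 <- fit_single_model(t0, spec, monotone = TRUE, trim_fraction = 0)
  expect_lt(max(abs(member_curve(fit0, xs))), 1e-8)
})

test_that("monotone fits are non-decreasing even when the data are not", {
  knots <- c(100, 135, 165, 200)
  spec <- spline_spec(knots)
  set.seed(8)
  t <- make_table(runif(20, 100, 120), runif(20, 120, 130),
                  runif(20, 130, 170), runif(20, 170, 200),
                  log_effect = rnorm(20, 0, 0.5), se = 0.1)
  fit <- fit_single_model(t, spec, monotone = TRUE)
  xs <- seq(100, 200, by = 1)
  expect_true(all(diff(member_curve(fit, xs)) >= -1e-9))
})

test_that("trimming removes exactly the planted outliers", {
  knots <- c(100, 140, 170, 200)
  gvec_true <- c(0.02, 0.02, 0.02, 0.02)
  t <- noise_free_rows(knots, gvec_true, n = 20, se = 0.05, seed = 33)
  planted <- c(4, 13)
  t$data$log_effect[planted] <- t$data$log_effect[planted] + 2.0
  fit <- fit_single_model(t, spline_spec(knots), monotone = TRUE,
                          trim_fraction = 0.10)
  expect_equal(sum(fit$trim_weights), round(0.9 * 20))
  expect_equal(which(fit$trim_weights == 0), planted)
})

test_that("iterative trimming matches exhaustive trimmed-likelihood search", {
  knots <- c(100, 140, 170, 200)
  gvec_true <- c(0.015, 0.015, 0.025, 0.025)
  t <- noise_free_rows(knots, gvec_true, n = 12, se = 0.08, seed = 14)
  t$data$log_effect <- t$data$log_effect + rnorm(12, 0, 0.08)
  t$data$log_effect[7] <- t$data$log_effect[7] + 1.5
  spec <- spline_spec(knots)
  fit <- fit_single_model(t, spec, monotone = TRUE, trim_fraction = 0.10)
  trimmed <- which(fit$trim_weights == 0)
  expect_length(trimmed, 1)
  expect_equal(trimmed, brute_force_trim(t, spec, h = 11))
})

test_that("ensembles average members, reproduce log-linear truth, and are seed-deterministic", {
  truth <- make_true_curve("log_linear", slope = 0.02)
  cfg <- sim_config(n_studies = 20, gamma_true = 0, se_range = c(0.019, 0.021),
                    outlier_fraction = 0, bias_effects = numeric(), seed = 2)
  sim <- simulate_table(truth, cfg)
  sim$table$data$log_effect <- sim$ledger$signal  # strip residual noise

  ens <- ensemble_fit(sim$table, n_members = 8, right_tail_prior_sd = Inf,
                      trim_fraction = 0, seed = 10)
  for (m in seq_along(ens$members)) {
    delta <- member_curve(ens$members[[m]], ens$grid) - 0.02 * (ens$grid - ens$grid[1])
    expect_lt(max(abs(delta)), 1e-4)
  }
  expect_lt(max(abs(ens$mean_log_rr - 0.02 * (ens$grid - ens$grid[1]))), 1e-4)
  expect_equal(ens$mean_log_rr[1], 0)
  expect_equal(ens$fixed_var[1], 0)
  expect_equal(sum(ens$model_weights), 1)

  one <- ensemble_fit(sim$table, n_members = 1, seed = 4)
  expect_equal(one$mean_log_rr, member_curve(one$members[[1]], one$grid))

  a <- ensemble_fit(sim$table, n_members = 5, seed = 77)
  b <- ensemble_fit(sim$table, n_members = 5, seed = 77)
  expect_identical(a$mean_log_rr, b$mean_log_rr)
  expect_identical(a$model_weights, b$model_weights)
})

test_that("the right-tail prior flattens the tail where data are weak", {
  knots <- c(100, 130, 160, 200)
  gvec_true <- rep(0.02, 4)
  t <- noise_free_rows(knots, gvec_true, n = 25, se = 0.15, seed = 51)
  free <- fit_single_model(t, spline_spec(knots, right_tail_prior_sd = Inf),
                           trim_fraction = 0)
  shrunk <- fit_single_model(t, spline_spec(knots, right_tail_prior_sd = 0.001),
                             trim_fraction = 0)
  # the prior pulls the right-tail derivative toward zero, never raises it
  expect_lt(shrunk$gvec[4], free$gvec[4])
  expect_gte(shrunk$gvec[4], 0)
  # and leaves a fit with a much weaker prior essentially unshrunk
  mild <- fit_single_model(t, spline_spec(knots, right_tail_prior_sd = 1),
                           trim_fraction = 0)
  expect_equal(mild$gvec[4], free$gvec[4], tolerance = 1e-3)
})

test_that("relative-risk predictions anchor at 1 and compose transitively", {
  truth <- make_true_curve("log_linear", slope = 0.015)
  sim <- simulate_table(truth, sim_config(n_studies = 15, seed = 6))
  ens <- ensemble_fit(sim$table, n_members = 5, seed = 6)
  expect_equal(predict_rr(ens, 130, 130), 1.0)
  r1 <- predict_rr(ens, 160, 100)
  r2 <- predict_rr(ens, 160, 130) * predict_rr(ens, 130, 100)
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(predict_rr(ens, 90, 100), "extrapolate")
  expect_silent(predict_rr(ens, 90, 100, extrapolate = TRUE))
})
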