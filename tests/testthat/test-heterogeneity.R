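sim_for_gamma <- function(gamma_true, n_studies, seed, se = c(0.05, 0.05)) {
  truth <- make_true_curve("log_linear", slope = 0.02)
  simulate_table(truth, sim_config(n_studies = n_studies, rct_fraction = 1,
                                   gamma_true = gamma_true, se_range = se,
                                   outlier_fraction = 0,
                                   bias_effects = numeric(), seed = seed))
}

test_that("gamma is near zero for homogeneous data and recovered when planted", {
  sim0 <- sim_for_gamma(0, 30, seed = 3, se = c(1e-4, 1e-4))
  ens0 <- ensemble_fit(sim0$table, n_members = 5, seed = 3)
  g0 <- estimate_gamma(sim0$table, ens0)
  expect_lte(g0$gamma, 1e-4)

  # untrimmed: nothing is planted, and trimming clean residuals would
  # truncate their distribution and deflate the variance estimate
  sim <- sim_for_gamma(0.02, 200, seed = 8)
  ens <- ensemble_fit(sim$table, n_members = 10, seed = 8, trim_fraction = 0)
  g <- estimate_gamma(sim$table, ens)
  expect_gte(g$gamma, 0.01)
  expect_lte(g$gamma, 0.03)
  expect_gt(g$se_gamma, 0)

  # noisier data carry less Fisher information about gamma (curvature of
  # the marginal likelihood at the same gamma, holding the effects fixed)
  r <- sim$table$data$log_effect - predict_signal(ens, sim$table)
  se2 <- sim$table$data$se_log_effect^2
  info_at <- function(se2) {
    nll <- bopmeta:::gamma_nll_factory(r, se2, sim$table$data$study_id)
    h <- 1e-5
    (nll(0.02 + h) - 2 * nll(0.02) + nll(0.02 - h)) / h^2
  }
  expect_gt(info_at(se2), info_at(4 * se2))

  few <- subset_table(sim$table, sim$table$data$study_id %in%
                        unique(sim$table$data$study_id)[1:2])
  expect_error(estimate_gamma(few, ens), "3 studies")
})

test_that("heterogeneity-inclusive quantiles collapse and anchor correctly", {
  sim <- sim_for_gamma(0.01, 25, seed = 5)
  ens <- ensemble_fit(sim$table, n_members = 5, seed = 5)
  g <- estimate_gamma(sim$table, ens)

  zero <- structure(list(gamma = 0, se_gamma = 0, n_studies = g$n_studies),
                    class = "bop_gamma")
  ui0 <- ui_with_heterogeneity(ens, zero, c(0.05, 0.5, 0.95))
  fe <- sqrt(ens$fixed_var)
  expect_equal(ui0[, 1], ens$mean_log_rr + qnorm(0.05) * fe)
  expect_equal(ui0[, 2], ens$mean_log_rr)  # median = mean curve
  expect_equal(ui0[, 3], ens$mean_log_rr + qnorm(0.95) * fe)

  ui <- ui_with_heterogeneity(ens, g, c(0.05, 0.95))
  expect_equal(unname(ui[1, ]), c(0, 0))  # anchored zero-uncertainty rule
})

test_that("the BPRF is the conservative quantile and matches a Monte-Carlo oracle", {
  sim <- sim_for_gamma(0.01, 30, seed = 13)
  ens <- ensemble_fit(sim$table, n_members = 8, seed = 13)
  g <- estimate_gamma(sim$table, ens)
  b <- compute_bprf(ens, g, "harmful")
  expect_true(all(b$bprf_log <= ens$mean_log_rr + 1e-12))
  expect_error(compute_bprf(ens, g, "sideways"))

  zero <- structure(list(gamma = 0, se_gamma = 0), class = "bop_gamma")
  ens_certain <- ens
  ens_certain$fixed_var[] <- 0
  b0 <- compute_bprf(ens_certain, zero, "harmful")
  expect_equal(b0$bprf_log, ens$mean_log_rr)

  set.seed(99)
  sdt <- bopmeta:::total_sd(ens, g, k = 2)
  z <- rnorm(10000)
  draws <- outer(sdt, z) + ens$mean_log_rr
  emp <- apply(draws, 1, quantile, probs = 0.05, type = 7)
  expect_lt(max(abs(emp - b$bprf_log)), 0.01)
})

test_that("ROS, averaged BPRF and percent increase obey their identities", {
  grid <- seq(100, 200, by = 1)
  const_curve <- function(val) list(grid = grid, bprf_log = rep(val, length(grid)))
  r0 <- compute_ros(const_curve(0), 107.5, 165)
  expect_equal(r0$ros, 0)
  expect_equal(r0$percent_increase, 0)

  r <- compute_ros(const_curve(log(2.01)), 107.5, 165)
  expect_equal(round(r$ros, 2), 0.70)
  expect_equal(round(compute_ros(const_curve(log(2.06)), 113.2, 168.2)$ros, 2),
               0.72)

  # percent = 100*(e^ros - 1) identically
  set.seed(1)
  for (v in runif(5, -0.5, 1.5)) {
    rr <- compute_ros(const_curve(v), 110, 160)
    expect_equal(rr$percent_increase, 100 * (exp(rr$ros) - 1))
  }
  expect_error(compute_ros(const_curve(0), 90, 160), "outside")

  # monotone in the curve: raising the BPRF cannot lower the ROS
  set.seed(2)
  base_vals <- cumsum(runif(length(grid), 0, 0.01))
  b1 <- list(grid = grid, bprf_log = base_vals)
  b2 <- list(grid = grid, bprf_log = base_vals + abs(rnorm(length(grid), 0, 0.1)))
  expect_gte(compute_ros(b2, 110, 170)$ros, compute_ros(b1, 110, 170)$ros)
})

test_that("star ratings follow the threshold table with inclusive upper bounds", {
  expect_equal(star_rating(-0.01), 1L)
  expect_equal(star_rating(0.0), 2L)
  expect_equal(star_rating(0.14), 2L)
  expect_equal(star_rating(0.140001), 3L)
  expect_equal(star_rating(0.28), 3L)
  expect_equal(star_rating(0.41), 3L)
  expect_equal(star_rating(0.59), 4L)
  expect_equal(star_rating(0.62), 4L)
  expect_equal(star_rating(0.70), 5L)
  expect_error(star_rating(NaN), "finite")
  # non-decreasing step function
  ros_seq <- seq(-0.2, 1, by = 0.01)
  expect_true(all(diff(vapply(ros_seq, star_rating, integer(1))) >= 0))
})
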