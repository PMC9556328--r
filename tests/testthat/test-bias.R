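# Base curve for covariate tests: modest ensemble is enough, the selection
# stage only needs the signal.
fit_base <- function(tab, seed = 1) {
  ensemble_fit(tab, n_members = 8, seed = seed)
}

sim_with_bias <- function(bias_effects, n_studies = 20, seed = 1,
                          se_range = c(0.05, 0.05), gamma_true = 0) {
  truth <- make_true_curve("log_linear", slope = 0.02)
  simulate_table(truth, sim_config(n_studies = n_studies, rct_fraction = 0.9,
                                   gamma_true = gamma_true,
                                   se_range = se_range, outlier_fraction = 0,
                                   bias_effects = bias_effects, seed = seed))
}

test_that("lasso ranking puts planted bias covariates first, largest first", {
  sim <- sim_with_bias(c(cv_planted = 0.5, cv_noise = 0), seed = 4)
  base <- fit_base(sim$table, seed = 4)
  rk <- rank_covariates(sim$table, base)
  expect_equal(rk[1], "cv_planted")

  sim2 <- sim_with_bias(c(cv_big = 0.5, cv_small = 0.1, cv_null = 0),
                        n_studies = 30, seed = 9)
  base2 <- fit_base(sim2$table, seed = 9)
  rk2 <- rank_covariates(sim2$table, base2)
  expect_equal(rk2[1], "cv_big")
  expect_lt(match("cv_small", rk2), match("cv_null", rk2))

  # independent oracle for first entry: the covariate with the largest
  # weighted correlation between the standardized dummy and the
  # signal-offset residual enters the path first
  d <- sim2$table$data
  w <- 1 / d$se_log_effect^2
  r <- d$log_effect - predict_signal(base2, sim2$table)
  score <- vapply(c("cv_big", "cv_small", "cv_null"), function(nm) {
    x <- d[[nm]]
    x <- (x - weighted.mean(x, w)) / sqrt(weighted.mean((x - weighted.mean(x, w))^2, w))
    abs(weighted.mean(x * r, w))
  }, numeric(1))
  expect_equal(rk2[1], names(which.max(score)))
})

test_that("degenerate covariate sets are handled", {
  sim <- sim_with_bias(numeric(), seed = 2)
  base <- fit_base(sim$table, seed = 2)
  expect_identical(rank_covariates(sim$table, base), character())
  expect_equal(nrow(stepwise_select(sim$table, base, character())$selected), 0)

  # constant covariate excluded with a warning
  tab <- sim$table
  tab$data$cv_const <- 1
  tab$covariates <- rbind(tab$covariates, bias_covariate("cv_const"))
  expect_warning(rk <- rank_covariates(tab, base), "constant")
  expect_identical(rk, character())
})

test_that("stepwise selection finds a planted shift with the right sign and respects the level", {
  sim <- sim_with_bias(c(cv_planted = 0.5, cv_noise = 0), n_studies = 30, seed = 12)
  base <- fit_base(sim$table, seed = 12)
  rk <- rank_covariates(sim$table, base)
  sel <- stepwise_select(sim$table, base, rk, level = 0.05)
  expect_true("cv_planted" %in% sel$selected$name)
  expect_equal(sel$selected$sign[sel$selected$name == "cv_planted"], 1)
  expect_false("cv_noise" %in% sel$selected$name)

  # level -> 0 empties the selection
  sel0 <- stepwise_select(sim$table, base, rk, level = 1e-12)
  expect_equal(nrow(sel0$selected), 0)

  # invariance to covariate column order given the same ranking
  tab2 <- sim$table
  perm <- c(setdiff(names(tab2$data), c("cv_planted", "cv_noise")),
            "cv_noise", "cv_planted")
  tab2$data <- tab2$data[, perm]
  tab2$covariates <- tab2$covariates[2:1, ]
  sel2 <- stepwise_select(tab2, base, rk, level = 0.05)
  expect_equal(sel2$selected$name, sel$selected$name)
  expect_equal(sel2$selected$beta, sel$selected$beta, tolerance = 1e-10)
})

test_that("bias adjustment removes the selected shift before the refit", {
  sim <- sim_with_bias(c(cv_planted = 0.5), n_studies = 25, seed = 21)
  base <- fit_base(sim$table, seed = 21)
  sel <- stepwise_select(sim$table, base, rank_covariates(sim$table, base))
  expect_true("cv_planted" %in% sel$selected$name)
  adj <- adjust_table(sim$table, base, sel)
  b <- sel$selected$beta[sel$selected$name == "cv_planted"]
  expect_equal(adj$data$log_effect,
               sim$table$data$log_effect - b * sim$table$data$cv_planted)
  # planted effect is estimated close to 0.5
  expect_lt(abs(b - 0.5), 0.15)
})
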