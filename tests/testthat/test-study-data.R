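test_that("study tables validate, round-trip through CSV, and close open categories", {
  d <- data.frame(study_id = c("a", "a", "b"), design = c("cohort", "cohort", "rct"),
                  ref_lower = c(NA, 100, 120.5), ref_upper = c(115, 115, 120.5),
                  alt_lower = c(115, 175, 141.25), alt_upper = c(125, NA, 141.25),
                  log_effect = c(0.123456789012, -0.2, 0.5),
                  se_log_effect = c(0.05, 0.1, 0.2),
                  events = c(10, 20, 30), cv_x = c(0, 1, 1))
  t <- study_table(d)
  expect_s3_class(t, "bop_table")
  expect_equal(n_rows(t), 3)
  expect_equal(n_studies(t), 2)
  expect_equal(covariate_names(t), "cv_x")
  # open-ended categories close to the plausible window
  expect_equal(t$data$ref_lower[1], 100)
  expect_equal(t$data$alt_upper[2], 200)

  path <- tempfile(fileext = ".csv")
  write_study_table(t, path)
  t2 <- load_study_table(path)
  expect_equal(t2$data$log_effect, t$data$log_effect, tolerance = 1e-12)
  expect_equal(t2$data, t$data, tolerance = 1e-12)
  expect_equal(t2$covariates$name, t$covariates$name)

  # validation failures name the offending rows
  bad <- d; bad$se_log_effect[2] <- 0
  expect_error(study_table(bad), "row 2")
  expect_error(study_table(d[, setdiff(names(d), "log_effect")]), "log_effect")
  swapped <- d; swapped$ref_lower[3] <- 130
  expect_error(study_table(swapped), "lower <= upper")
})

test_that("midpoints and exposure percentiles match the closed forms", {
  expect_equal(midpoint_exposure(100, 120), 110)
  expect_equal(midpoint_exposure(165, 165), 165)
  expect_equal(midpoint_exposure(107, 128), 117.5)

  t1 <- make_table(110, 110, 150, 150, log_effect = 0.5)
  expect_equal(exposure_percentiles(t1, c(0.15, 0.85)), c(116, 144))

  t2 <- make_table(rep(115, 3), rep(125, 3), rep(115, 3), rep(125, 3),
                   log_effect = c(0, 0, 0))
  expect_equal(exposure_percentiles(t2, c(0.15, 0.85)), c(120, 120))

  set.seed(11)
  for (i in 1:5) {
    tt <- make_table(runif(7, 100, 140), runif(7, 140, 160),
                     runif(7, 120, 160), runif(7, 160, 200),
                     log_effect = rnorm(7))
    mids <- pooled_midpoints(tt)
    for (p in c(0.15, 0.5, 0.85)) {
      expect_equal(exposure_percentiles(tt, c(p, 0.9))[1],
                   brute_percentile(mids, p))
    }
  }
  expect_error(exposure_percentiles(subset_table(t1, integer())), "empty")
})

test_that("percentile band is monotone and stable under interior insertion", {
  set.seed(3)
  tt <- make_table(runif(10, 100, 130), runif(10, 130, 150),
                   runif(10, 120, 150), runif(10, 150, 190),
                   log_effect = rnorm(10))
  band <- exposure_percentiles(tt)
  expect_lte(band[1], band[2])
  inside <- mean(band)
  d <- tt$data[1, ]
  d$ref_lower <- d$ref_upper <- d$alt_lower <- d$alt_upper <- inside
  tt2 <- study_table(rbind(tt$data, d), covariates = tt$covariates)
  band2 <- exposure_percentiles(tt2)
  expect_gte(band2[1], band[1] - 1e-12)
  expect_lte(band2[2], band[2] + 1e-12)
})
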