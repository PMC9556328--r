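#' Construct a ground-truth risk curve
#'
#' Defines the continuous log-relative-risk function that the synthetic
#' generator reports against and that recovery tests compare to. The curve is
#' anchored at 0 at the window minimum.
#'
#' Families: `"log_linear"` (`log_rr(x) = slope * (x - xmin)`), `"flat"`
#' (identically 0), and `"spline"` (a natural cubic interpolant through
#' supplied knot values, shifted so the value at the window minimum is 0).
#'
#' @param family One of `"log_linear"`, `"flat"`, `"spline"`.
#' @param window Exposure window `c(min, max)` in mm Hg (default 100-200,
#'   the modeled plausible range).
#' @param slope Log-RR per mm Hg (log-linear family; default 0.02).
#' @param knots,values Knot positions and log-RR values (spline family).
#' @return An object of class `bop_truth` with elements `grid`, `log_rr`,
#'   `family`, `window` and the continuous evaluator `fun`.
#' @export
make_true_curve <- function(family = c("log_linear", "flat", "spline"),
                            window = c(100, 200), slope = 0.02,
                            knots = NULL, values = NULL) {
  family <- match.arg(family)
  stopifnot(length(window) == 2, window[1] < window[2])
  fun <- switch(family,
    log_linear = {
      force(slope); xmin <- window[1]
      function(x) slope * (x - xmin)
    },
    flat = function(x) rep(0, length(x)),
    spline = {
      if (is.null(knots) || is.null(values) || length(knots) != length(values)) {
        stop("spline family needs matching 'knots' and 'values'")
      }
      sf <- stats::splinefun(knots, values, method = "natural")
      shift <- sf(window[1])
      function(x) sf(x) - shift
    })
  grid <- seq(window[1], window[2], by = 1)
  structure(list(grid = grid, log_rr = fun(grid), family = family,
                 window = window, fun = fun),
            class = "bop_truth")
}

#' Evaluate a true curve, pointwise or range-averaged
#'
#' Range averages use adaptive quadrature on the continuous evaluator
#' (relative tolerance 1e-12), so polynomial truths are exact to numerical
#' precision; a degenerate range evaluates pointwise.
#'
#' @param truth A `bop_truth`.
#' @param lower,upper Range bounds; equal values evaluate the curve at a point.
#' @return Average log RR over the range.
#' @export
true_range_average <- function(truth, lower, upper) {
  if (lower == upper) return(truth$fun(lower))
  stats::integrate(truth$fun, lower, upper, rel.tol = 1e-12,
                   abs.tol = 1e-12)$value / (upper - lower)
}

#' Simulation configuration
#'
#' Defaults mirror the structure of the extracted evidence base the pipeline
#' is designed for: 41 studies of which 39 are trials and 2 are cohorts,
#' exposures within 100-200 mm Hg, trial reference-arm means centered at
#' 121 mm Hg, cohort category edges with open-ended end categories closed to
#' the window, minor between-study heterogeneity and a 10% outlier fraction.
#'
#' @param n_studies Number of studies (default 41).
#' @param rct_fraction Fraction of studies that are trials (default 39/41).
#' @param gamma_true Between-study variance of the study-level log-RR shift
#'   (default 0.01).
#' @param se_range Range from which reported standard errors are drawn
#'   uniformly (default `c(0.05, 0.2)`).
#' @param outlier_fraction Fraction of rows planted as outliers (default 0.1).
#' @param outlier_shift Additive log-RR shift applied to planted outliers
#'   (default 1).
#' @param bias_effects Named numeric vector: log-RR measurement shift per
#'   dummy bias covariate (covariate values are drawn Bernoulli(0.5) per
#'   study). Default: two inert covariates with zero effect.
#' @param exposure_window Exposure window `c(min, max)` (default 100-200).
#' @param cohort_edges Category edges for cohort rows (default the
#'   115/.../175 grid with end categories closed to the window).
#' @param rct_ref_mean,rct_ref_sd Center/spread of trial reference-arm mean
#'   exposure (defaults 121 and 10 mm Hg).
#' @param rct_diff_range Range of the alternative-minus-reference arm
#'   difference, drawn uniformly (default `c(5, 30)` mm Hg).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `bop_sim_config`.
#' @export
sim_config <- function(n_studies = 41, rct_fraction = 39 / 41,
                       gamma_true = 0.01, se_range = c(0.05, 0.2),
                       outlier_fraction = 0.1, outlier_shift = 1,
                       bias_effects = c(cv_incidence = 0, cv_subpopulation = 0),
                       exposure_window = c(100, 200),
                       cohort_edges = c(100, 115, 125, 135, 145, 155, 165, 175, 200),
                       rct_ref_mean = 121, rct_ref_sd = 10,
                       rct_diff_range = c(5, 30), seed = 1L) {
  stopifnot(n_studies >= 1,
            rct_fraction >= 0, rct_fraction <= 1,
            gamma_true >= 0,
            length(se_range) == 2, all(se_range > 0), se_range[1] <= se_range[2],
            outlier_fraction >= 0, outlier_fraction <= 1,
            length(exposure_window) == 2, exposure_window[1] < exposure_window[2],
            length(rct_diff_range) == 2, rct_diff_range[1] <= rct_diff_range[2])
  cohort_edges <- sort(cohort_edges)
  cohort_edges <- cohort_edges[cohort_edges >= exposure_window[1] &
                               cohort_edges <= exposure_window[2]]
  if (length(cohort_edges) < 3) stop("need at least 3 cohort category edges in window")
  structure(list(n_studies = n_studies, rct_fraction = rct_fraction,
                 gamma_true = gamma_true, se_range = se_range,
                 outlier_fraction = outlier_fraction,
                 outlier_shift = outlier_shift, bias_effects = bias_effects,
                 exposure_window = exposure_window, cohort_edges = cohort_edges,
                 rct_ref_mean = rct_ref_mean, rct_ref_sd = rct_ref_sd,
                 rct_diff_range = rct_diff_range, seed = as.integer(seed)),
            class = "bop_sim_config")
}

#' Simulate a study table with known ground truth
#'
#' Each row's true signal is the average of the true log-RR curve over the
#' alternative range minus its average over the reference range (pointwise
#' for degenerate trial-arm ranges). The observed log effect adds a
#' study-level random shift `u_s ~ N(0, gamma_true)` (one draw per study, shared
#' across its rows), measurement-bias shifts for active covariates, a planted
#' outlier offset on a random `outlier_fraction` of rows, and sampling noise
#' `e ~ N(0, se^2)` with `se` drawn uniformly from `se_range`.
#'
#' Trial rows carry degenerate arm-mean ranges; cohort studies contribute one
#' row per non-reference category versus the lowest category, with edges from
#' `cfg$cohort_edges`.
#'
#' @param truth A `bop_truth` whose window covers `cfg$exposure_window`.
#' @param cfg A [sim_config()].
#' @return A list with elements `table` (a `bop_table`) and `ledger` (the
#'   truth ledger: per-row `data.frame` with `signal`, `u`, `outlier`, and
#'   attribute-free study-level shifts in `attr(ledger, "study_effects")`).
#' @export
simulate_table <- function(truth, cfg) {
  stopifnot(inherits(truth, "bop_truth"), inherits(cfg, "bop_sim_config"))
  if (truth$window[1] > cfg$exposure_window[1] ||
      truth$window[2] < cfg$exposure_window[2]) {
    stop("truth window does not cover the configured exposure window")
  }
  set.seed(cfg$seed)
  n_rct <- round(cfg$rct_fraction * cfg$n_studies)
  design <- sample(rep(c("rct", "cohort"),
                       c(n_rct, cfg$n_studies - n_rct)))
  cov_names <- names(cfg$bias_effects)

  rows <- list()
  study_u <- stats::rnorm(cfg$n_studies, 0, sqrt(cfg$gamma_true))
  names(study_u) <- sprintf("study_%02d", seq_len(cfg$n_studies))
  for (s in seq_len(cfg$n_studies)) {
    sid <- names(study_u)[s]
    cov_vals <- stats::rbinom(length(cov_names), 1, 0.5)
    if (design[s] == "rct") {
      lo <- cfg$exposure_window[1]
      hi <- cfg$exposure_window[2] - cfg$rct_diff_range[2]
      repeat {
        ref <- stats::rnorm(1, cfg$rct_ref_mean, cfg$rct_ref_sd)
        if (ref >= lo && ref <= hi) break
      }
      alt <- ref + stats::runif(1, cfg$rct_diff_range[1], cfg$rct_diff_range[2])
      arm <- data.frame(study_id = sid, design = "rct",
                        ref_lower = ref, ref_upper = ref,
                        alt_lower = alt, alt_upper = alt,
                        stringsAsFactors = FALSE)
    } else {
      e <- cfg$cohort_edges
      k <- length(e) - 1
      arm <- data.frame(study_id = sid, design = "cohort",
                        ref_lower = e[1], ref_upper = e[2],
                        alt_lower = e[2:k], alt_upper = e[3:(k + 1)],
                        stringsAsFactors = FALSE)
    }
    for (j in seq_along(cov_names)) arm[[cov_names[j]]] <- cov_vals[j]
    rows[[s]] <- arm
  }
  d <- do.call(rbind, rows)
  n <- nrow(d)

  signal <- mapply(function(rl, ru, al, au) {
    true_range_average(truth, al, au) - true_range_average(truth, rl, ru)
  }, d$ref_lower, d$ref_upper, d$alt_lower, d$alt_upper)
  u <- study_u[d$study_id]
  bias <- if (length(cov_names)) {
    as.matrix(d[, cov_names, drop = FALSE]) %*% cfg$bias_effects
  } else rep(0, n)
  se <- stats::runif(n, cfg$se_range[1], cfg$se_range[2])
  n_out <- round(cfg$outlier_fraction * n)
  outlier <- rep(FALSE, n)
  if (n_out > 0) outlier[sample.int(n, n_out)] <- TRUE
  e <- stats::rnorm(n, 0, se)

  d$log_effect <- signal + unname(u) + drop(bias) +
    ifelse(outlier, cfg$outlier_shift, 0) + e
  d$se_log_effect <- se
  d$events <- round(stats::runif(n, 50, 2000))

  schema <- if (length(cov_names)) {
    do.call(rbind, lapply(cov_names, bias_covariate))
  } else NULL
  tab <- study_table(d, covariates = schema,
                     floor = min(70, cfg$exposure_window[1]),
                     ceiling = max(250, cfg$exposure_window[2]))
  ledger <- data.frame(row = seq_len(n), study_id = d$study_id,
                       signal = unname(signal), u = unname(u),
                       outlier = outlier, noise = e,
                       stringsAsFactors = FALSE)
  attr(ledger, "study_effects") <- study_u
  list(table = tab, ledger = ledger)
}

#' Serialize a truth ledger to JSON
#' @param ledger Ledger from [simulate_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_ledger <- function(ledger, path) {
  jsonlite::write_json(
    list(rows = ledger,
         study_effects = as.list(attr(ledger, "study_effects"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
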