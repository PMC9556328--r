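# End-to-end orchestration: fit, bias selection, heterogeneity, BPRF,
# publication-bias diagnostics, exports.

#' Pipeline configuration
#'
#' Collects every tunable the analysis uses; all randomness flows from the
#' single `seed`. Defaults are the default pipeline: monotone quadratic
#' spline with two interior knots, linear tails, right-tail derivative prior
#' sd 0.001, 10% trimming, 50 ensemble members, reporting relative to
#' 100 mm Hg, the 15th-85th percentile band, harmful direction.
#'
#' @param reference_exposure Reference SBP for reported RRs (default 100).
#' @param rr_exposures Exposures at which the summary reports RRs.
#' @param trim_fraction Fraction of rows trimmed per member (default 0.10).
#' @param n_ensemble Ensemble size (default 50).
#' @param n_interior Interior knots per member (default 2).
#' @param percentile_band ROS averaging band (default `c(0.15, 0.85)`).
#' @param direction `"harmful"` or `"protective"` (default harmful).
#' @param significance_level Level for stepwise covariate selection.
#' @param seed Integer seed.
#' @param monotone,left_linear,right_linear Constraint flags.
#' @param right_tail_prior_sd Right-tail derivative prior sd (`Inf` disables).
#' @param extrapolate_low Allow the reference/queries below the fitted
#'   domain via linear extension (sensitivity mode).
#' @param gamma_inflation_k Heterogeneity-uncertainty inflation (default 2).
#' @return An object of class `bop_config` (a named list).
#' @export
pipeline_config <- function(reference_exposure = 100,
                            rr_exposures = c(110, 115, 120, 130, 140, 150, 165),
                            trim_fraction = 0.10, n_ensemble = 50,
                            n_interior = 2, percentile_band = c(0.15, 0.85),
                            direction = "harmful", significance_level = 0.05,
                            seed = 1L, monotone = TRUE, left_linear = TRUE,
                            right_linear = TRUE, right_tail_prior_sd = 0.001,
                            extrapolate_low = FALSE, gamma_inflation_k = 2) {
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5, n_ensemble >= 1,
            length(percentile_band) == 2,
            all(percentile_band > 0 & percentile_band < 1),
            percentile_band[1] < percentile_band[2],
            significance_level > 0, significance_level < 1,
            direction %in% c("harmful", "protective"))
  structure(list(reference_exposure = reference_exposure,
                 rr_exposures = rr_exposures,
                 trim_fraction = trim_fraction, n_ensemble = n_ensemble,
                 n_interior = n_interior, percentile_band = percentile_band,
                 direction = direction,
                 significance_level = significance_level,
                 seed = as.integer(seed), monotone = monotone,
                 left_linear = left_linear, right_linear = right_linear,
                 right_tail_prior_sd = right_tail_prior_sd,
                 extrapolate_low = extrapolate_low,
                 gamma_inflation_k = gamma_inflation_k),
            class = "bop_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys match [pipeline_config()] arguments.
#' @return A `bop_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full burden-of-proof analysis
#'
#' Executes the stages in order: (1) ensemble curve fit with trimming;
#' (2) Lasso ranking and stepwise selection of bias covariates, with one
#' adjusted refit if any are selected; (3) between-study heterogeneity with
#' Fisher-information uncertainty; (4) funnel residuals and Egger's test;
#' (5) BPRF, ROS and star rating over the percentile band. When `out_dir`
#' is given, writes `curve.csv`, `bprf.csv`, `funnel.csv`, `summary.json`,
#' `log.txt` and `figures/` there.
#'
#' @param table A `bop_table` or path to a study-table CSV.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return An object of class `bop_result`: list with `table`, `config`,
#'   `curve`, `selection`, `gamma`, `bprf`, `funnel`, `egger`, `summary`.
#' @export
run_pipeline <- function(table, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "bop_config"))
  if (is.character(table)) table <- load_study_table(table)
  stopifnot(inherits(table, "bop_table"))
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  fit_once <- function(tab) {
    ensemble_fit(tab, n_members = config$n_ensemble,
                 n_interior = config$n_interior,
                 left_linear = config$left_linear,
                 right_linear = config$right_linear,
                 right_tail_prior_sd = config$right_tail_prior_sd,
                 monotone = config$monotone,
                 trim_fraction = config$trim_fraction)
  }

  curve <- stage("curve_fit", fit_once(table))
  selection <- stage("bias_selection", {
    ranking <- rank_covariates(table, curve)
    stepwise_select(table, curve, ranking, config$significance_level)
  })
  adj_table <- table
  if (nrow(selection$selected) > 0) {
    adj_table <- adjust_table(table, curve, selection)
    curve <- stage("adjusted_refit", fit_once(adj_table))
  }
  gamma <- stage("heterogeneity", estimate_gamma(adj_table, curve))
  funnel <- stage("funnel", funnel_points(adj_table, curve, gamma))
  egger <- stage("eggers_test", eggers_test(funnel))
  bprf <- stage("bprf", bprf_result(curve, gamma, table,
                                    direction = config$direction,
                                    band = config$percentile_band,
                                    k = config$gamma_inflation_k))

  summary <- stage("summary", pipeline_summary(table, config, curve, selection,
                                               gamma, bprf, egger))
  result <- structure(list(table = table, config = config, curve = curve,
                           selection = selection, gamma = gamma, bprf = bprf,
                           funnel = funnel, egger = egger, summary = summary),
                      class = "bop_result")
  if (!is.null(out_dir)) write_result(result, out_dir)
  invisible(result)
}

pipeline_summary <- function(table, config, curve, selection, gamma, bprf,
                             egger) {
  ref <- config$reference_exposure
  extrap <- config$extrapolate_low
  ui <- ui_with_heterogeneity(curve, gamma, c(0.025, 0.975),
                              config$gamma_inflation_k)
  fe_sd <- sqrt(curve$fixed_var)
  at <- function(v, x) stats::approx(curve$grid, v, xout = x, rule = 2)$y
  ref_log <- curve_log_rr(curve, ref, extrap)
  xs <- config$rr_exposures
  xs <- xs[xs >= curve$domain[1] | extrap]
  xs <- xs[xs <= curve$domain[2] | extrap]
  rr_table <- data.frame(
    exposure = xs,
    rr_mean = exp(curve_log_rr(curve, xs, extrap) - ref_log),
    rr_lo_fe = exp(at(curve$mean_log_rr - 1.96 * fe_sd, xs) - ref_log),
    rr_hi_fe = exp(at(curve$mean_log_rr + 1.96 * fe_sd, xs) - ref_log),
    rr_lo_het = exp(at(ui[, 1], xs) - ref_log),
    rr_hi_het = exp(at(ui[, 2], xs) - ref_log),
    rr_bprf = exp(at(bprf$bprf_log, xs) - ref_log))
  list(n_rows = n_rows(table), n_studies = n_studies(table),
       n_trimmed = sum(1 - curve$members[[1]]$trim_weights),
       domain = curve$domain,
       reference_exposure = ref,
       p15 = bprf$p15, p85 = bprf$p85,
       gamma = gamma$gamma, se_gamma = gamma$se_gamma,
       selected_covariates = selection$selected$name,
       ros = bprf$ros, averaged_bprf = bprf$averaged_bprf,
       percent_increase = bprf$percent_increase, stars = bprf$stars,
       egger = egger, rr_table = rr_table)
}

#' @export
print.bop_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<bop_result> %d rows / %d studies; domain %g-%g mm Hg\n",
              s$n_rows, s$n_studies, s$domain[1], s$domain[2]))
  cat(sprintf("  gamma %.4f (se %.4f); Egger p %.3g\n",
              s$gamma, s$se_gamma, s$egger$p_value))
  cat(sprintf("  band %.1f-%.1f: averaged BPRF %.3f (+%.2f%%), ROS %.3f, %d star(s)\n",
              s$p15, s$p85, s$averaged_bprf, s$percent_increase, s$ros, s$stars))
  print(round_df(s$rr_table, 3), row.names = FALSE)
  invisible(x)
}

round_df <- function(d, digits) {
  for (nm in names(d)) if (is.numeric(d[[nm]])) d[[nm]] <- round(d[[nm]], digits)
  d
}

write_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cv <- result$curve
  utils::write.csv(data.frame(exposure = cv$grid,
                              mean_log_rr = cv$mean_log_rr,
                              fixed_var = cv$fixed_var),
                   file.path(out_dir, "curve.csv"), row.names = FALSE)
  utils::write.csv(data.frame(exposure = result$bprf$grid,
                              bprf_log_rr = result$bprf$bprf_log),
                   file.path(out_dir, "bprf.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$funnel),
                   file.path(out_dir, "funnel.csv"), row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  writeLines(config_log(result$config), file.path(out_dir, "log.txt"))
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  save_fig <- function(name, plot) {
    grDevices::pdf(file.path(fig_dir, name), width = 7, height = 5)
    on.exit(grDevices::dev.off())
    print(plot)
  }
  save_fig("log_rr_curve.pdf", plot_risk_curve(result, scale = "log"))
  save_fig("rr_curve.pdf", plot_risk_curve(result, scale = "rr"))
  save_fig("funnel.pdf", plot_funnel(result))
  invisible(out_dir)
}

config_log <- function(config) {
  c("pipeline configuration (every parameter in effect):",
    vapply(names(config), function(nm) {
      sprintf("  %s = %s", nm, paste(format(config[[nm]]), collapse = ", "))
    }, character(1)))
}

#' Sensitivity suite
#'
#' Reruns the pipeline under standard perturbations: constraints relaxed
#' (monotonicity, linear tails and the right-tail prior off), design subsets
#' (cohort-only and trial-only, skipped with a warning below 3 studies) and
#' alternative reference exposures, and reports per-variant ROS, stars and
#' the maximum absolute difference between the variant and base mean log-RR
#' curves on their common grid.
#'
#' @param table A `bop_table` or CSV path.
#' @param config Base [pipeline_config()].
#' @param references Alternative reference exposures (default
#'   `c(107.5, 110, 115)`).
#' @return List with `report` (a `data.frame`: variant, n_rows, n_studies,
#'   p15, p85, ros, stars, max_curve_delta) and `runs` (the `bop_result`s).
#' @export
sensitivity_suite <- function(table, config = pipeline_config(),
                              references = c(107.5, 110, 115)) {
  if (is.character(table)) table <- load_study_table(table)
  base <- run_pipeline(table, config)
  runs <- list(base = base)
  report <- sensitivity_row(base, "base", NA_real_)

  relaxed_cfg <- config
  relaxed_cfg$monotone <- FALSE
  relaxed_cfg$left_linear <- FALSE
  relaxed_cfg$right_linear <- FALSE
  relaxed_cfg$right_tail_prior_sd <- Inf
  runs$unconstrained <- run_pipeline(table, relaxed_cfg)
  report <- rbind(report, sensitivity_row(runs$unconstrained, "unconstrained",
                                          curve_delta(base, runs$unconstrained)))

  for (dsg in c("cohort", "rct")) {
    sub <- subset_table(table, table$data$design == dsg)
    if (n_studies(sub) < 3) {
      warning(dsg, "-only subset has fewer than 3 studies; skipped")
      next
    }
    nm <- paste0(dsg, "_only")
    sub_cfg <- config
    dom_lo <- min(sub$data$ref_lower, sub$data$alt_lower)
    if (config$reference_exposure < dom_lo && !config$extrapolate_low) {
      sub_cfg$reference_exposure <- dom_lo  # re-anchor inside the subset domain
    }
    runs[[nm]] <- run_pipeline(sub, sub_cfg)
    report <- rbind(report, sensitivity_row(runs[[nm]], nm,
                                            curve_delta(base, runs[[nm]])))
  }
  for (ref in references) {
    if (ref < base$curve$domain[1] && !config$extrapolate_low) next
    cfg <- config
    cfg$reference_exposure <- ref
    nm <- sprintf("reference_%g", ref)
    runs[[nm]] <- run_pipeline(table, cfg)
    report <- rbind(report, sensitivity_row(runs[[nm]], nm, 0))
  }
  rownames(report) <- NULL
  list(report = report, runs = runs)
}

sensitivity_row <- function(res, name, delta) {
  s <- res$summary
  data.frame(variant = name, n_rows = s$n_rows, n_studies = s$n_studies,
             p15 = s$p15, p85 = s$p85, ros = s$ros, stars = s$stars,
             max_curve_delta = delta, stringsAsFactors = FALSE)
}

curve_delta <- function(base, other) {
  lo <- max(base$curve$domain[1], other$curve$domain[1])
  hi <- min(base$curve$domain[2], other$curve$domain[2])
  xs <- seq(lo, hi, length.out = 201)
  max(abs(curve_log_rr(base$curve, xs) - curve_log_rr(other$curve, xs)))
}
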