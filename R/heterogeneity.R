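# Between-study heterogeneity, heterogeneity-inclusive uncertainty, and the
# conservative burden-of-proof summary (BPRF / ROS / stars).

#' Estimate between-study heterogeneity
#'
#' Profile maximum likelihood for the variance `gamma` of study-level random
#' effects on the log-RR scale, given the fitted mean curve (and any selected
#' bias covariates, whose effects are removed from the observations first).
#' Rows trimmed by the ensemble are excluded. Per study `s` with residual
#' vector `r_s` (observed minus curve-predicted signal), the marginal model
#' is `r_s ~ N(0, diag(se^2) + gamma * 11')`; the likelihood is evaluated in
#' closed form (Woodbury identity) and maximized over `gamma >= 0`. The
#' standard error of `gamma` comes from the observed Fisher information at
#' the optimum.
#'
#' @param t A `bop_table`.
#' @param c A `bop_ensemble` fitted to `t`.
#' @param selection Optional `bop_selection`; selected covariate effects are
#'   subtracted from the observations before computing residuals.
#' @param inliers Optional logical vector of rows to use; default excludes
#'   [ensemble_trimmed()] rows.
#' @return An object of class `bop_gamma`: list with `gamma`, `se_gamma`,
#'   `loglik`, `n_studies`.
#' @export
estimate_gamma <- function(t, c, selection = NULL, inliers = NULL) {
  stopifnot(inherits(t, "bop_table"), inherits(c, "bop_ensemble"))
  if (n_studies(t) < 3) {
    stop("need at least 3 studies to estimate between-study heterogeneity")
  }
  if (is.null(inliers)) inliers <- !ensemble_trimmed(c, t)
  d <- t$data[inliers, , drop = FALSE]
  ti <- subset_table(t, inliers)
  if (length(unique(d$study_id)) < 3) {
    stop("need at least 3 studies to estimate between-study heterogeneity")
  }
  y <- adjusted_log_effect(ti, c, selection)
  r <- y - predict_signal(c, ti)
  nll <- gamma_nll_factory(r, d$se_log_effect^2, d$study_id)
  ub <- max(1, 10 * stats::var(r))
  opt <- stats::optimize(nll, c(0, ub), tol = 1e-10)
  gamma <- if (nll(0) <= opt$objective) 0 else opt$minimum
  # observed Fisher information by central difference (one-sided at 0)
  h <- 1e-4 * (gamma + 1e-3)
  g0 <- max(gamma, h)
  info <- (nll(g0 + h) - 2 * nll(g0) + nll(g0 - h)) / h^2
  se_gamma <- if (is.finite(info) && info > 0) 1 / sqrt(info) else NA_real_
  structure(list(gamma = gamma, se_gamma = se_gamma,
                 loglik = -nll(gamma),
                 n_studies = length(unique(d$study_id))),
            class = "bop_gamma")
}

# Marginal negative log-likelihood of gamma given residuals, reported SEs
# and study grouping: per study, r_s ~ N(0, diag(se^2) + gamma 11'),
# evaluated in closed form via the Woodbury identity.
gamma_nll_factory <- function(r, se2, study_id) {
  groups <- split(seq_along(r), study_id)
  function(gamma) {
    val <- 0
    for (idx in groups) {
      s2 <- se2[idx]; ri <- r[idx]
      a <- sum(1 / s2)
      quad <- sum(ri^2 / s2) - gamma * sum(ri / s2)^2 / (1 + gamma * a)
      val <- val + 0.5 * (sum(log(s2)) + log1p(gamma * a) + quad)
    }
    val
  }
}

#' @export
print.bop_gamma <- function(x, ...) {
  cat(sprintf("<bop_gamma> gamma = %.5f (se %.5f), %d studies\n",
              x$gamma, x$se_gamma, x$n_studies))
  invisible(x)
}

# Total sd of the log-RR curve at each grid point: fixed-effects sd plus the
# heterogeneity contribution scaled along the curve (random-slope geometry:
# zero at the anchor, proportional to |mean| elsewhere). k inflates gamma by
# k standard errors to propagate heterogeneity-estimation uncertainty.
total_sd <- function(c, g, k = 2) {
  gamma_adj <- max(g$gamma + k * ifelse(is.finite(g$se_gamma), g$se_gamma, 0), 0)
  m <- max(abs(c$mean_log_rr))
  s <- if (m > 0) abs(c$mean_log_rr) / m else rep(0, length(c$grid))
  sqrt(c$fixed_var) + sqrt(gamma_adj) * s
}

#' Quantile curves inclusive of between-study heterogeneity
#'
#' For each requested quantile `q`, returns
#' `mean_log_rr(x) + z_q * sd_total(x)` where
#' `sd_total(x) = sqrt(fixed_var(x)) + sqrt(gamma + k * se_gamma) * s(x)` and
#' `s(x) = |mean_log_rr(x)| / max|mean_log_rr|`. The total sd is zero at the
#' anchored domain minimum, so all quantiles pass through log RR 0 there.
#'
#' @param c A `bop_ensemble`.
#' @param g A `bop_gamma`.
#' @param quantiles Fractions in (0, 1).
#' @param k Heterogeneity-uncertainty inflation in standard errors of gamma
#'   (default 2).
#' @return Matrix, one column per quantile, rows matching `c$grid`.
#' @export
ui_with_heterogeneity <- function(c, g, quantiles = c(0.05, 0.95), k = 2) {
  stopifnot(all(quantiles > 0 & quantiles < 1))
  sdt <- total_sd(c, g, k)
  out <- vapply(quantiles, function(q) c$mean_log_rr + stats::qnorm(q) * sdt,
                numeric(length(c$grid)))
  colnames(out) <- paste0("q", formatC(quantiles, format = "g"))
  out
}

#' Burden-of-proof risk function (conservative quantile curve)
#'
#' For a harmful risk the BPRF is the 5th-quantile curve of the
#' heterogeneity-inclusive band (the edge closest to the null RR of 1); for a
#' protective risk it is the 95th. The direction must be declared; it is
#' never auto-detected.
#'
#' @param c A `bop_ensemble`.
#' @param g A `bop_gamma`.
#' @param direction `"harmful"` or `"protective"`.
#' @param k Heterogeneity-uncertainty inflation (see
#'   [ui_with_heterogeneity()]).
#' @return An object of class `bop_bprf`: list with `grid`, `bprf_log`,
#'   `direction`.
#' @export
compute_bprf <- function(c, g, direction = c("harmful", "protective"), k = 2) {
  direction <- match.arg(direction)
  q <- if (direction == "harmful") 0.05 else 0.95
  bprf_log <- drop(ui_with_heterogeneity(c, g, q, k))
  structure(list(grid = c$grid, bprf_log = bprf_log, direction = direction),
            class = "bop_bprf")
}

#' Risk-outcome score from a BPRF curve
#'
#' The ROS is the average log BPRF over the data-dense exposure band
#' (by default the 15th-85th percentiles of pooled midpoints), computed on a
#' uniform 0.1-mm Hg grid interpolated from the curve. `averaged_bprf` is
#' `exp(ros)` (the exposure-averaged conservative RR) and `percent_increase`
#' is `100 * (exp(ros) - 1)`.
#'
#' @param b A `bop_bprf`, or any list with `grid` and `bprf_log`.
#' @param p15,p85 Band bounds (mm Hg), inside the curve grid, `p15 < p85`.
#' @return List with `ros`, `averaged_bprf`, `percent_increase`.
#' @export
compute_ros <- function(b, p15, p85) {
  stopifnot(p15 < p85)
  g <- b$grid
  if (p15 < g[1] || p85 > g[length(g)]) {
    stop(sprintf("band [%g, %g] outside curve grid [%g, %g]",
                 p15, p85, g[1], g[length(g)]))
  }
  xs <- seq(p15, p85, length.out = max(2L, ceiling((p85 - p15) / 0.1) + 1L))
  ros <- mean(stats::approx(g, b$bprf_log, xout = xs)$y)
  list(ros = ros, averaged_bprf = exp(ros),
       percent_increase = 100 * (exp(ros) - 1))
}

#' Star rating of a risk-outcome score
#'
#' Ordinal 1-5 evidence category: 1 for `ros < 0`, 2 for `0 <= ros <= 0.14`,
#' 3 for `0.14 < ros <= 0.41`, 4 for `0.41 < ros <= 0.62`, 5 for
#' `ros > 0.62` (upper bounds inclusive in the lower category).
#'
#' @param ros Finite numeric score.
#' @return Integer in 1..5.
#' @export
star_rating <- function(ros) {
  if (length(ros) != 1L || !is.finite(ros)) stop("ros must be a finite scalar")
  if (ros < 0) 1L
  else if (ros <= 0.14) 2L
  else if (ros <= 0.41) 3L
  else if (ros <= 0.62) 4L
  else 5L
}

#' Full conservative-evidence summary
#'
#' Convenience wrapper combining [compute_bprf()], the exposure percentile
#' band of the table, [compute_ros()] and [star_rating()].
#'
#' @param c A `bop_ensemble`.
#' @param g A `bop_gamma`.
#' @param t The `bop_table` (for the percentile band).
#' @param direction `"harmful"` or `"protective"`.
#' @param band Percentile pair (default `c(0.15, 0.85)`).
#' @param k Heterogeneity-uncertainty inflation.
#' @return An object of class `bop_bprf_result`: the `bop_bprf` fields plus
#'   `p15`, `p85`, `ros`, `averaged_bprf`, `percent_increase`, `stars`.
#' @export
bprf_result <- function(c, g, t, direction = "harmful",
                        band = c(0.15, 0.85), k = 2) {
  b <- compute_bprf(c, g, direction, k)
  pct <- exposure_percentiles(t, band)
  pct[1] <- max(pct[1], c$grid[1])
  pct[2] <- min(pct[2], c$grid[length(c$grid)])
  r <- compute_ros(b, pct[1], pct[2])
  structure(c(b, list(p15 = pct[1], p85 = pct[2], ros = r$ros,
                      averaged_bprf = r$averaged_bprf,
                      percent_increase = r$percent_increase,
                      stars = star_rating(r$ros))),
            class = "bop_bprf_result")
}

#' @export
print.bop_bprf_result <- function(x, ...) {
  cat(sprintf(paste0("<bop_bprf_result> %s risk; band %.1f-%.1f mm Hg; ",
                     "averaged BPRF %.2f (+%.1f%%); ROS %.2f; %d star(s)\n"),
              x$direction, x$p15, x$p85, x$averaged_bprf,
              x$percent_increase, x$ros, x$stars))
  invisible(x)
}
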