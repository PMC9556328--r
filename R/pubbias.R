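# Funnel diagnostics and Egger's regression on model residuals.

#' Funnel points from model residuals
#'
#' One point per table row: the residual (observed minus curve-predicted log
#' effect) and the total standard deviation combining the reported SE with
#' between-study heterogeneity, `sqrt(se^2 + gamma)`. Rows trimmed by the
#' ensemble are flagged but included.
#'
#' @param t A `bop_table`.
#' @param c A `bop_ensemble` fitted to `t`.
#' @param g A `bop_gamma`.
#' @param y Optional replacement observations (e.g. bias-adjusted log
#'   effects); defaults to the table's `log_effect`.
#' @return A `data.frame` of class `bop_funnel` with columns `residual`,
#'   `sd_total`, `trimmed`.
#' @export
funnel_points <- function(t, c, g, y = NULL) {
  stopifnot(inherits(t, "bop_table"), inherits(c, "bop_ensemble"),
            inherits(g, "bop_gamma"))
  if (is.null(y)) y <- t$data$log_effect
  res <- y - predict_signal(c, t)
  out <- data.frame(residual = res,
                    sd_total = sqrt(t$data$se_log_effect^2 + g$gamma),
                    trimmed = ensemble_trimmed(c, t))
  class(out) <- c("bop_funnel", "data.frame")
  out
}

#' Egger's regression test for funnel asymmetry
#'
#' Classic Egger formulation applied to model residuals: ordinary regression
#' of the standardized residual (`residual / sd_total`) on precision
#' (`1 / sd_total`); the intercept estimates small-study asymmetry and its
#' two-sided t test (df = n - 2) gives the p value. Trimmed rows are
#' excluded from the test (they remain on the funnel plot).
#'
#' @param points A `bop_funnel` (or data.frame with `residual`, `sd_total`,
#'   optionally `trimmed`).
#' @return List with `intercept`, `se_intercept`, `p_value`, `n_used`.
#' @export
eggers_test <- function(points) {
  stopifnot(all(c("residual", "sd_total") %in% names(points)))
  if (!"trimmed" %in% names(points)) points$trimmed <- FALSE
  pts <- points[!points$trimmed, , drop = FALSE]
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 untrimmed funnel points")
  if (any(pts$sd_total <= 0)) stop("sd_total must be positive")
  z <- pts$residual / pts$sd_total
  prec <- 1 / pts$sd_total
  if (stats::sd(prec) < 1e-12) {
    warning("degenerate precision spread (all sd_total equal); ",
            "Egger's test has no power against asymmetry here")
  }
  if (all(abs(z) < 1e-12)) {
    return(list(intercept = 0, se_intercept = 0, p_value = 1, n_used = n))
  }
  fit <- stats::lm(z ~ prec)
  est <- summary(fit)$coefficients
  tval <- est["(Intercept)", "t value"]
  list(intercept = unname(est["(Intercept)", "Estimate"]),
       se_intercept = unname(est["(Intercept)", "Std. Error"]),
       p_value = unname(2 * stats::pt(-abs(tval), df = n - 2)),
       n_used = n)
}
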