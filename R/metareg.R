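# Ensemble spline meta-regression with range integration and trimming.

# Per-row design: average of the curve over the alternative range minus the
# average over the reference range, as coefficient rows on the g nodes.
build_design <- function(t, knots, extrapolate = FALSE) {
  d <- t$data
  n <- nrow(d)
  V <- matrix(0, n, length(knots))
  for (i in seq_len(n)) {
    V[i, ] <- range_design_row(d$alt_lower[i], d$alt_upper[i], knots, extrapolate) -
      range_design_row(d$ref_lower[i], d$ref_upper[i], knots, extrapolate)
  }
  V
}

# Exact bound-constrained weighted least squares by active-set enumeration:
# minimize 0.5*(y - X b)' W (y - X b) + 0.5 * b' P b  s.t. b >= 0 (optional).
# With <= 5 free parameters, enumerating the 2^p active sets is exact and
# immune to the extreme weight scales that arise in noise-free fixtures.
solve_wls_nonneg <- function(X, y, w, pdiag, nonneg = TRUE) {
  p <- ncol(X)
  A <- crossprod(X, X * w) + diag(pdiag, p)
  b <- crossprod(X, y * w)
  ridge <- diag(max(diag(A)) * 1e-12 + 1e-300, p)
  unconstrained <- function(free) {
    bf <- rep(0, p)
    sol <- tryCatch(solve(A[free, free, drop = FALSE] + ridge[free, free, drop = FALSE],
                          b[free]),
                    error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    bf[free] <- sol
    bf
  }
  if (!nonneg) {
    out <- unconstrained(seq_len(p))
    if (is.null(out)) stop("singular design in spline fit")
    return(out)
  }
  scale <- max(abs(b), max(diag(A)), 1)
  tol <- 1e-9
  best <- NULL; best_obj <- Inf
  for (mask in 0:(2^p - 1)) {
    active <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    free <- setdiff(seq_len(p), active)
    if (length(free) == 0) {
      beta <- rep(0, p)
    } else {
      beta <- unconstrained(free)
      if (is.null(beta)) next
      if (any(beta[free] < -tol * max(1, max(abs(beta))))) next
    }
    grad <- drop(A %*% beta - b)
    if (length(active) && any(grad[active] < -tol * scale)) next
    obj <- 0.5 * sum(beta * drop(A %*% beta)) - sum(beta * b)
    if (obj < best_obj - 1e-300) {
      best <- pmax(beta, 0); best_obj <- obj
    }
  }
  if (is.null(best)) stop("constrained spline fit infeasible")
  best
}

#' Fit a single constrained spline meta-regression with trimming
#'
#' Maximizes the trimmed Gaussian likelihood of the observed log effects
#' against the range-integrated spline signal, with per-row variance
#' `se_log_effect^2`. Monotonicity (non-decreasing log RR) is imposed as
#' nonnegativity of the derivative nodes; the right-tail derivative carries
#' the zero-mean Gaussian shrinkage prior toward flatness. Trimming keeps the
#' `round((1 - trim_fraction) * n)` most coherent rows via concentration
#' steps: refit, re-rank standardized residuals, re-select, until the inlier
#' set is stable.
#'
#' @param t A `bop_table`.
#' @param spec A [spline_spec()].
#' @param monotone Impose the monotonicity constraint (default `TRUE`).
#' @param trim_fraction Fraction of rows to trim (default 0.10).
#' @return An object of class `bop_fit` with elements `gvec` (derivative
#'   node values), `trim_weights` (0/1 per row), `loglik`,
#'   `total_variation`, `vcov_free`, and bookkeeping fields.
#' @export
fit_single_model <- function(t, spec, monotone = TRUE, trim_fraction = 0.10) {
  stopifnot(inherits(t, "bop_table"), inherits(spec, "bop_spline_spec"),
            trim_fraction >= 0, trim_fraction < 0.5)
  d <- t$data
  n <- nrow(d)
  K <- length(spec$knots)
  Tm <- tie_matrix(K, spec$left_linear, spec$right_linear)
  p <- ncol(Tm)
  V <- build_design(t, spec$knots)
  X <- V %*% Tm
  y <- d$log_effect
  w <- 1 / d$se_log_effect^2
  pdiag <- rep(0, p)
  if (is.finite(spec$right_tail_prior_sd)) {
    pdiag[p] <- 1 / spec$right_tail_prior_sd^2  # right-tail derivative node
  }
  h <- round((1 - trim_fraction) * n)
  if (h < p + 1) {
    stop(sprintf("too few untrimmed rows (%d) for %d spline coefficients", h, p))
  }

  # concentration steps: start from the full-data fit, then alternate
  # "keep the h most coherent rows" with refitting, tracking the best
  # size-h inlier set by trimmed likelihood (comparable only at size h)
  beta <- solve_wls_nonneg(X, y, w, pdiag, nonneg = monotone)
  seen <- character()
  best <- NULL
  for (iter in seq_len(100)) {
    z <- (y - drop(X %*% beta)) / d$se_log_effect
    inliers <- sort(order(abs(z), seq_len(n))[seq_len(h)])
    key <- paste(inliers, collapse = ",")
    if (key %in% seen) break
    seen <- c(seen, key)
    beta <- solve_wls_nonneg(X[inliers, , drop = FALSE], y[inliers],
                             w[inliers], pdiag, nonneg = monotone)
    ll <- sum(stats::dnorm(y[inliers], drop(X[inliers, , drop = FALSE] %*% beta),
                           d$se_log_effect[inliers], log = TRUE))
    if (is.null(best) || ll > best$loglik) {
      best <- list(beta = beta, inliers = inliers, loglik = ll)
    }
  }
  beta <- best$beta; inliers <- best$inliers
  gvec <- drop(Tm %*% beta)
  trim_weights <- as.numeric(seq_len(n) %in% inliers)
  Xi <- X[inliers, , drop = FALSE]
  A <- crossprod(Xi, Xi * w[inliers]) + diag(pdiag, p)
  vcov_free <- tryCatch(solve(A), error = function(e) {
    solve(A + diag(max(diag(A)) * 1e-10, p))
  })
  tv <- max(abs(diff(gvec) / diff(spec$knots)))
  structure(list(spec = spec, knots = spec$knots, gvec = gvec,
                 beta_free = beta, tie = Tm, vcov_free = vcov_free,
                 trim_weights = trim_weights, loglik = best$loglik,
                 total_variation = tv, monotone = monotone,
                 n = n, h = h), class = "bop_fit")
}

#' Evaluate a fitted member curve
#' @param fit A `bop_fit`.
#' @param x Exposures (mm Hg).
#' @param extrapolate Allow linear extension outside the knot span.
#' @return Log RR at `x`, anchored at 0 at the domain minimum.
#' @export
member_curve <- function(fit, x, extrapolate = FALSE) {
  eval_spline(fit$gvec, fit$knots, x, extrapolate)
}

# Random interior-knot placement: uniform over the band, rejection-sampled to
# keep interior knots at least min_gap apart (gap relaxed if infeasible).
sample_knots <- function(n_interior, band, min_gap = 10, max_tries = 1000) {
  if (n_interior == 0) return(numeric())
  gap <- min_gap
  repeat {
    for (i in seq_len(max_tries)) {
      k <- sort(stats::runif(n_interior, band[1], band[2]))
      if (n_interior < 2 || all(diff(k) >= gap)) return(k)
    }
    gap <- gap / 2
    if (gap < 1e-3) stop("cannot place interior knots in band")
  }
}

fit_domain <- function(t) {
  d <- t$data
  c(min(d$ref_lower, d$alt_lower), max(d$ref_upper, d$alt_upper))
}

#' Ensemble spline meta-regression
#'
#' Fits `n_members` constrained spline meta-regressions with random interior
#' knot placement and combines them into a posterior mean curve. Interior
#' knots are drawn uniformly over the central band of pooled arm midpoints
#' (default 10th-90th percentiles), at least `min_knot_gap` mm Hg apart.
#' Member weights combine fit quality and smoothness:
#' `w ~ exp(-BIC/2) / (1 + total_variation)`, normalized; members that fail
#' to converge are dropped with a warning (an error if more than half fail).
#'
#' The returned curve is anchored at log RR 0 (with zero variance) at the
#' fit-domain minimum; `fixed_var` combines the within-member coefficient
#' covariance with the between-member dispersion and excludes between-study
#' heterogeneity.
#'
#' @param t A `bop_table` spanning at least 4 distinct midpoints.
#' @param n_members Number of ensemble members (default 50).
#' @param n_interior Interior knots per member (default 2).
#' @param left_linear,right_linear,right_tail_prior_sd Spline-family options,
#'   see [spline_spec()].
#' @param monotone Impose monotonicity (default `TRUE`).
#' @param trim_fraction Fraction trimmed per member (default 0.10).
#' @param seed Integer seed controlling knot placement; `NULL` uses the
#'   current RNG state.
#' @param grid_step Output grid spacing in mm Hg (default 1).
#' @param knot_band_probs Percentile band of pooled midpoints for knot
#'   placement (default `c(0.1, 0.9)`).
#' @param min_knot_gap Minimum spacing between interior knots (default 10).
#' @return An object of class `bop_ensemble` with elements `grid`,
#'   `mean_log_rr`, `fixed_var`, `model_weights`, `members`, `domain`.
#' @export
ensemble_fit <- function(t, n_members = 50, n_interior = 2,
                         left_linear = TRUE, right_linear = TRUE,
                         right_tail_prior_sd = 0.001, monotone = TRUE,
                         trim_fraction = 0.10, seed = NULL, grid_step = 1,
                         knot_band_probs = c(0.1, 0.9), min_knot_gap = 10) {
  stopifnot(inherits(t, "bop_table"), n_members >= 1)
  mids <- pooled_midpoints(t)
  if (length(unique(mids)) < 4) stop("data span fewer than 4 distinct midpoints")
  if (!is.null(seed)) set.seed(seed)
  dom <- fit_domain(t)
  band <- unname(stats::quantile(mids, knot_band_probs, type = 7))

  members <- vector("list", n_members)
  failures <- 0L
  for (m in seq_len(n_members)) {
    knots <- c(dom[1], sample_knots(n_interior, band, min_knot_gap), dom[2])
    fit <- tryCatch(
      fit_single_model(t, spline_spec(knots, left_linear, right_linear,
                                      right_tail_prior_sd),
                       monotone = monotone, trim_fraction = trim_fraction),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("ensemble member ", m, " failed: ", conditionMessage(fit))
      failures <- failures + 1L
    } else {
      members[[m]] <- fit
    }
  }
  members <- Filter(Negate(is.null), members)
  if (failures > n_members / 2) {
    stop("more than half of the ensemble members failed to converge")
  }

  p <- vapply(members, function(f) length(f$beta_free), integer(1))
  bic <- vapply(members, function(f) -2 * f$loglik, numeric(1)) + p * log(members[[1]]$h)
  tv <- vapply(members, function(f) f$total_variation, numeric(1))
  raw <- exp(-(bic - min(bic)) / 2) / (1 + tv)
  wts <- raw / sum(raw)

  grid <- seq(dom[1], dom[2], by = grid_step)
  if (grid[length(grid)] < dom[2]) grid <- c(grid, dom[2])
  curves <- vapply(members, function(f) member_curve(f, grid), numeric(length(grid)))
  mean_log_rr <- drop(curves %*% wts)
  mean_log_rr <- mean_log_rr - mean_log_rr[1]  # re-anchor (0 by construction)
  within_var <- vapply(members, function(f) {
    D <- point_design(grid, f$knots) %*% f$tie
    rowSums((D %*% f$vcov_free) * D)
  }, numeric(length(grid)))
  fixed_var <- drop(within_var %*% wts) +
    drop((curves - mean_log_rr)^2 %*% wts)
  fixed_var[1] <- 0

  structure(list(grid = grid, mean_log_rr = mean_log_rr,
                 fixed_var = fixed_var, model_weights = wts,
                 members = members, domain = dom, knot_band = band),
            class = "bop_ensemble")
}

#' @export
print.bop_ensemble <- function(x, ...) {
  cat(sprintf("<bop_ensemble> %d members on [%g, %g] mm Hg; max log RR %.3f\n",
              length(x$members), x$domain[1], x$domain[2], max(x$mean_log_rr)))
  invisible(x)
}

# Linear interpolation of the ensemble mean curve, with optional linear
# extension beyond the domain using the edge slopes.
curve_log_rr <- function(c, x, extrapolate = FALSE) {
  g <- c$grid; f <- c$mean_log_rr
  out <- stats::approx(g, f, xout = x, rule = 1)$y
  low <- x < g[1]; high <- x > g[length(g)]
  if (any(low) || any(high)) {
    if (!extrapolate) {
      stop(sprintf("exposure outside curve domain [%g, %g]; set extrapolate = TRUE",
                   g[1], g[length(g)]))
    }
    sl_lo <- (f[2] - f[1]) / (g[2] - g[1])
    nlast <- length(g)
    sl_hi <- (f[nlast] - f[nlast - 1]) / (g[nlast] - g[nlast - 1])
    out[low] <- f[1] + sl_lo * (x[low] - g[1])
    out[high] <- f[nlast] + sl_hi * (x[high] - g[nlast])
  }
  out
}

#' Relative risk between two exposures
#'
#' `exp(mean_log_rr(x) - mean_log_rr(reference))` from the ensemble mean
#' curve; satisfies `predict_rr(c, ref, ref) = 1` and transitivity across
#' reference changes exactly on the log scale.
#'
#' @param c A `bop_ensemble`.
#' @param x Exposures of interest (mm Hg).
#' @param reference Reference exposure (mm Hg).
#' @param extrapolate Allow queries outside the fitted domain (linear
#'   extension; sensitivity mode).
#' @return Relative risks.
#' @export
predict_rr <- function(c, x, reference, extrapolate = FALSE) {
  exp(curve_log_rr(c, x, extrapolate) - curve_log_rr(c, reference, extrapolate))
}

# Average of the (piecewise-linear) mean curve over a range: exact trapezoid
# on the grid segments; degenerate ranges evaluate pointwise.
curve_range_average <- function(c, lower, upper, extrapolate = FALSE) {
  if (lower == upper) return(curve_log_rr(c, lower, extrapolate))
  cuts <- sort(unique(c(lower, upper, c$grid[c$grid > lower & c$grid < upper])))
  f <- curve_log_rr(c, cuts, extrapolate)
  sum(diff(cuts) * (utils::head(f, -1) + utils::tail(f, -1)) / 2) / (upper - lower)
}

#' Curve-predicted signal for every table row
#'
#' The ensemble-mean analogue of the likelihood's range-integration: average
#' log RR over the alternative range minus the reference range, per row.
#'
#' @param c A `bop_ensemble`.
#' @param t A `bop_table`.
#' @param extrapolate Allow ranges outside the fitted domain.
#' @return Numeric vector of predicted log effects.
#' @export
predict_signal <- function(c, t, extrapolate = FALSE) {
  d <- t$data
  vapply(seq_len(nrow(d)), function(i) {
    curve_range_average(c, d$alt_lower[i], d$alt_upper[i], extrapolate) -
      curve_range_average(c, d$ref_lower[i], d$ref_upper[i], extrapolate)
  }, numeric(1))
}

#' Consensus trimmed rows of an ensemble
#'
#' Marks the `n - h` rows most often trimmed across members (weighted by the
#' member weights; ties broken by the standardized residual against the
#' ensemble mean, then row order), so the pipeline-level trimmed set has
#' exactly the per-member trimming count.
#'
#' @param ens A `bop_ensemble`.
#' @param t The `bop_table` the ensemble was fitted to.
#' @return Logical vector, `TRUE` for trimmed rows.
#' @export
ensemble_trimmed <- function(ens, t) {
  n <- n_rows(t)
  if (n != ens$members[[1]]$n) {
    stop("table does not match the table the ensemble was fitted to")
  }
  n_trim <- n - ens$members[[1]]$h
  if (n_trim == 0) return(rep(FALSE, n))
  freq <- rowSums(vapply(seq_along(ens$members), function(m) {
    ens$model_weights[m] * (1 - ens$members[[m]]$trim_weights)
  }, numeric(n)))
  z <- abs((t$data$log_effect - predict_signal(ens, t)) / t$data$se_log_effect)
  ord <- order(-freq, -z, seq_len(n))
  trimmed <- rep(FALSE, n)
  trimmed[ord[seq_len(n_trim)]] <- TRUE
  trimmed
}
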