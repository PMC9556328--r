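# Quadratic-spline machinery, parametrized through the derivative.
#
# The log-RR curve f is represented as the exact integral of a continuous
# piecewise-linear derivative g with node values at the knots:
#   f(x) = int_{k1}^{x} g(u) du,   g piecewise linear on [k1, ..., kK].
# f is then a C1 quadratic spline anchored at f(k1) = 0, linear in the node
# values of g.  Consequences exploited throughout:
#   * monotonicity of f  <=>  all g node values >= 0 (bound constraint);
#   * a linear tail segment  <=>  equal g values at its two end knots;
#   * the "maximum derivative of the right linear tail" is the last g node;
#   * range averages of f are exact (per-piece Simpson, exact for quadratics).
# Design rows below express f(x) (or its range average) as coefficient
# vectors on the g nodes.

# f(x) as a coefficient row on the g node values; x may lie outside the knot
# span only when extrapolate = TRUE (linear extension with the edge slope).
point_design_row <- function(x, knots, extrapolate = FALSE) {
  K <- length(knots)
  coef <- numeric(K)
  if (x < knots[1] || x > knots[K]) {
    if (!extrapolate) {
      stop(sprintf("exposure %g outside fit domain [%g, %g]",
                   x, knots[1], knots[K]))
    }
    if (x < knots[1]) {
      coef[1] <- x - knots[1]
      return(coef)
    }
  }
  for (j in seq_len(K - 1)) {
    a <- knots[j]; b <- knots[j + 1]
    if (x <= a) break
    h <- b - a
    tt <- min(x, b) - a
    coef[j] <- coef[j] + tt - tt^2 / (2 * h)
    coef[j + 1] <- coef[j + 1] + tt^2 / (2 * h)
  }
  if (x > knots[K]) coef[K] <- coef[K] + x - knots[K]
  coef
}

point_design <- function(x, knots, extrapolate = FALSE) {
  t(vapply(x, point_design_row, numeric(length(knots)),
           knots = knots, extrapolate = extrapolate))
}

# Average of f over [lower, upper] as a coefficient row: split at interior
# knots and apply Simpson's rule per piece (exact, f is piecewise quadratic).
range_design_row <- function(lower, upper, knots, extrapolate = FALSE) {
  if (lower > upper) stop("range must have lower <= upper")
  if (lower == upper) return(point_design_row(lower, knots, extrapolate))
  cuts <- sort(unique(c(lower, upper, knots[knots > lower & knots < upper])))
  total <- numeric(length(knots))
  for (i in seq_len(length(cuts) - 1)) {
    p <- cuts[i]; q <- cuts[i + 1]
    total <- total + (q - p) / 6 *
      (point_design_row(p, knots, extrapolate) +
       4 * point_design_row((p + q) / 2, knots, extrapolate) +
       point_design_row(q, knots, extrapolate))
  }
  total / (upper - lower)
}

#' Range-average design vector of the quadratic spline
#'
#' Returns the linear functional `v` such that `v %*% g` equals the average
#' of the fitted curve over `[lower, upper]`, where `g` holds the derivative
#' node values at the knots. A degenerate range (`lower == upper`) returns
#' the pointwise evaluation functional. Integration is exact (piecewise
#' Simpson on the quadratic pieces), matching the likelihood's
#' range-integration mechanism.
#'
#' @param spec A [spline_spec()].
#' @param lower,upper Range bounds (mm Hg) within the fit domain.
#' @param extrapolate Allow evaluation outside the knot span (linear
#'   extension with the tail slope).
#' @return Numeric vector, one coefficient per knot.
#' @export
range_average_design <- function(spec, lower, upper, extrapolate = FALSE) {
  range_design_row(lower, upper, spec$knots, extrapolate)
}

# Tie matrix mapping free parameters -> full g node vector.  Linear tails tie
# the two end nodes of the corresponding tail segment to a single parameter.
tie_matrix <- function(K, left_linear, right_linear) {
  group <- seq_len(K)
  if (left_linear) group[1] <- group[2]
  if (right_linear) group[K] <- group[K - 1]
  free <- unique(group)
  Tm <- matrix(0, K, length(free))
  for (j in seq_len(K)) Tm[j, match(group[j], free)] <- 1
  Tm
}

#' Quadratic-spline specification
#'
#' Defines the curve family used by the meta-regression: a quadratic spline
#' (degree 2) with interior knots, optional linear tail segments, and a
#' Gaussian prior (default mean 0, sd 0.001) on the derivative of the right
#' linear tail that shrinks the curve toward flatness where data run out.
#'
#' @param knots Full ascending knot vector including the domain bounds;
#'   interior knots must be strictly inside.
#' @param left_linear,right_linear Force the first/last knot segment to be
#'   linear (defaults `TRUE`, the default pipeline's tail constraints).
#' @param right_tail_prior_sd Standard deviation of the zero-mean Gaussian
#'   prior on the right-tail derivative; `Inf` disables it.
#' @return An object of class `bop_spline_spec`.
#' @export
spline_spec <- function(knots, left_linear = TRUE, right_linear = TRUE,
                        right_tail_prior_sd = 0.001) {
  knots <- as.numeric(knots)
  K <- length(knots)
  if (K < 2) stop("need at least the two domain-bound knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly ascending")
  stopifnot(right_tail_prior_sd > 0)
  structure(list(knots = knots, degree = 2L,
                 n_interior = K - 2L,
                 left_linear = isTRUE(left_linear),
                 right_linear = isTRUE(right_linear),
                 right_tail_prior_sd = right_tail_prior_sd),
            class = "bop_spline_spec")
}

#' @export
print.bop_spline_spec <- function(x, ...) {
  cat(sprintf("<bop_spline_spec> quadratic, knots: %s%s%s\n",
              paste(signif(x$knots, 6), collapse = ", "),
              if (x$left_linear) ", left tail linear" else "",
              if (x$right_linear) ", right tail linear" else ""))
  invisible(x)
}

# Evaluate a fitted g node vector as a curve.
eval_spline <- function(gvec, knots, x, extrapolate = FALSE) {
  drop(point_design(x, knots, extrapolate) %*% gvec)
}
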