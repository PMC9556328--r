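# Shared fixture builders and independent oracles.

# Hand-built table: ranges and effects given explicitly.
make_table <- function(ref_lower, ref_upper, alt_lower, alt_upper,
                       log_effect, se = 0.1, study_id = NULL,
                       design = "rct", covariates = NULL) {
  n <- length(log_effect)
  d <- data.frame(
    study_id = if (is.null(study_id)) sprintf("s%02d", seq_len(n)) else study_id,
    design = rep_len(design, n),
    ref_lower = ref_lower, ref_upper = ref_upper,
    alt_lower = alt_lower, alt_upper = alt_upper,
    log_effect = log_effect, se_log_effect = rep_len(se, n),
    stringsAsFactors = FALSE)
  if (!is.null(covariates)) d <- cbind(d, covariates)
  study_table(d)
}

# Noise-free rows from a curve defined by derivative node values on knots:
# a mix of degenerate and interval ranges spanning the domain.
noise_free_rows <- function(knots, gvec, n = 24, se = 0.01, seed = 42) {
  set.seed(seed)
  dom <- range(knots)
  ref_lo <- runif(n, dom[1], dom[1] + diff(dom) * 0.3)
  ref_up <- ref_lo + runif(n, 0, 15)
  alt_lo <- runif(n, dom[1] + diff(dom) * 0.35, dom[2] - 20)
  alt_up <- alt_lo + runif(n, 0, 20)
  avg <- function(l, u) {
    vapply(seq_along(l), function(i) {
      sum(bopmeta:::range_design_row(l[i], u[i], knots) * gvec)
    }, numeric(1))
  }
  make_table(ref_lo, ref_up, alt_lo, alt_up,
             log_effect = avg(alt_lo, alt_up) - avg(ref_lo, ref_up), se = se)
}

# Linear-interpolation percentile between order statistics, written out
# longhand (independent of stats::quantile).
brute_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Exhaustive trimmed-likelihood search: best inlier subset of size h under
# the same constrained fit, by enumeration.
brute_force_trim <- function(t, spec, monotone = TRUE, h = NULL) {
  n <- n_rows(t)
  if (is.null(h)) h <- round(0.9 * n)
  subsets <- utils::combn(n, h)
  best_ll <- -Inf
  best <- NULL
  for (j in seq_len(ncol(subsets))) {
    keep <- subsets[, j]
    fit <- fit_single_model(subset_table(t, keep), spec,
                            monotone = monotone, trim_fraction = 0)
    if (fit$loglik > best_ll) {
      best_ll <- fit$loglik
      best <- keep
    }
  }
  setdiff(seq_len(n), best)
}
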