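# Lasso ranking and stepwise significance testing of dummy bias covariates.

# Candidate covariates: dummies from the schema, excluding gamma-class
# (accepted in the schema but only logged) and constant columns.
candidate_covariates <- function(t) {
  sch <- t$covariates
  if (nrow(sch) == 0) return(character())
  gam <- sch$name[sch$klass == "gamma_class"]
  if (length(gam)) {
    message("gamma-class covariate(s) accepted but not modeled: ",
            paste(gam, collapse = ", "))
  }
  cand <- sch$name[sch$klass != "gamma_class"]
  const <- vapply(cand, function(nm) length(unique(t$data[[nm]])) < 2, logical(1))
  if (any(const)) {
    warning("constant covariate(s) excluded: ",
            paste(cand[const], collapse = ", "))
  }
  cand[!const]
}

# The regressor a covariate contributes: beta-class covariates shift the
# measurement additively; alpha-class covariates interact with the exposure
# signal.
covariate_regressor <- function(t, nm, signal) {
  klass <- t$covariates$klass[match(nm, t$covariates$name)]
  x <- t$data[[nm]]
  if (identical(klass, "alpha")) x * signal else x
}

#' Rank bias covariates along a Lasso path
#'
#' Orders the candidate dummy covariates from most to least impactful by the
#' penalty at which each enters a weighted Lasso regression of the observed
#' log effects on the covariates, with the curve-predicted signal as a fixed
#' offset, observation weights `1/se^2`, standardized covariates and no
#' intercept. Covariates that never enter the path are ranked last by their
#' least-penalized coefficient magnitude.
#'
#' @param t A `bop_table` with at least one candidate covariate.
#' @param base_curve A `bop_ensemble` fitted without covariates.
#' @return Character vector of covariate names, most impactful first
#'   (empty if there are no usable candidates).
#' @export
rank_covariates <- function(t, base_curve) {
  stopifnot(inherits(t, "bop_table"), inherits(base_curve, "bop_ensemble"))
  cand <- candidate_covariates(t)
  if (length(cand) == 0) return(character())
  signal <- predict_signal(base_curve, t)
  if (length(cand) == 1) return(cand)
  X <- vapply(cand, function(nm) covariate_regressor(t, nm, signal),
              numeric(n_rows(t)))
  fit <- glmnet::glmnet(X, t$data$log_effect, family = "gaussian",
                        weights = 1 / t$data$se_log_effect^2,
                        offset = signal, intercept = FALSE,
                        standardize = TRUE, nlambda = 200,
                        lambda.min.ratio = 1e-4)
  B <- as.matrix(fit$beta)
  entry <- apply(B, 1, function(row) {
    nz <- which(abs(row) > 0)
    if (length(nz)) nz[1] else Inf
  })
  final <- abs(B[, ncol(B)])
  cand[order(entry, -final, seq_along(cand))]
}

#' Stepwise significance selection of ranked covariates
#'
#' Adds ranked covariates one at a time to a weighted linear meta-regression
#' of the observed log effects on the curve-predicted signal, retaining each
#' covariate only if its coefficient is significant at `level` by a t test
#' whose degrees of freedom are corrected for the number of studies used
#' (`df = n_studies - n_parameters`).
#'
#' @param t A `bop_table`.
#' @param base_curve A `bop_ensemble` (provides the signal).
#' @param ranking Covariate order from [rank_covariates()].
#' @param level Significance level (default 0.05).
#' @return An object of class `bop_selection`: list with `ranking`,
#'   `selected` (data.frame: name, klass, beta, se, t, df, p, sign) and
#'   `level`. `selected` may be empty.
#' @export
stepwise_select <- function(t, base_curve, ranking, level = 0.05) {
  stopifnot(level > 0, level < 1)
  empty <- data.frame(name = character(), klass = character(),
                      beta = numeric(), se = numeric(), t = numeric(),
                      df = numeric(), p = numeric(), sign = numeric(),
                      stringsAsFactors = FALSE)
  sel <- structure(list(ranking = ranking, selected = empty, level = level),
                   class = "bop_selection")
  if (length(ranking) == 0) return(sel)
  signal <- predict_signal(base_curve, t)
  y <- t$data$log_effect
  w <- 1 / t$data$se_log_effect^2
  ns <- n_studies(t)
  accepted <- character()
  for (nm in ranking) {
    regs <- cbind(signal,
                  if (length(accepted)) {
                    vapply(accepted, function(a) covariate_regressor(t, a, signal),
                           numeric(length(y)))
                  },
                  covariate_regressor(t, nm, signal))
    colnames(regs) <- c("signal", accepted, nm)
    df <- ns - ncol(regs)
    if (df < 1) {
      warning("too few studies to test covariate '", nm, "'")
      next
    }
    fit <- stats::lm(y ~ 0 + regs, weights = w)
    est <- summary(fit)$coefficients
    row <- est[nrow(est), , drop = FALSE]
    tval <- row[1, "t value"]
    p <- 2 * stats::pt(-abs(tval), df)
    if (is.finite(p) && p < level) {
      accepted <- c(accepted, nm)
      klass <- t$covariates$klass[match(nm, t$covariates$name)]
      sel$selected <- rbind(sel$selected, data.frame(
        name = nm, klass = klass, beta = row[1, "Estimate"],
        se = row[1, "Std. Error"], t = tval, df = df, p = p,
        sign = sign(row[1, "Estimate"]), stringsAsFactors = FALSE))
    }
  }
  # refit jointly so reported effects condition on the full accepted set
  if (nrow(sel$selected) > 1) {
    regs <- cbind(signal, vapply(accepted, function(a)
      covariate_regressor(t, a, signal), numeric(length(y))))
    colnames(regs) <- c("signal", accepted)
    fit <- stats::lm(y ~ 0 + regs, weights = w)
    est <- summary(fit)$coefficients
    idx <- match(paste0("regs", accepted), rownames(est))
    sel$selected$beta <- est[idx, "Estimate"]
    sel$selected$se <- est[idx, "Std. Error"]
    sel$selected$sign <- sign(sel$selected$beta)
  }
  sel
}

#' @export
print.bop_selection <- function(x, ...) {
  if (nrow(x$selected) == 0) {
    cat(sprintf("<bop_selection> no covariates significant at level %g (of %d ranked)\n",
                x$level, length(x$ranking)))
  } else {
    cat(sprintf("<bop_selection> %d covariate(s) selected at level %g:\n",
                nrow(x$selected), x$level))
    print(x$selected[, c("name", "klass", "beta", "se", "p")], row.names = FALSE)
  }
  invisible(x)
}

# Observed log effects corrected for selected measurement-bias covariates
# (beta-class: subtract beta*x; alpha-class: subtract beta*x*signal).
adjusted_log_effect <- function(t, c, selection = NULL) {
  y <- t$data$log_effect
  if (is.null(selection) || nrow(selection$selected) == 0) return(y)
  signal <- predict_signal(c, t)
  for (i in seq_len(nrow(selection$selected))) {
    nm <- selection$selected$name[i]
    y <- y - selection$selected$beta[i] * covariate_regressor(t, nm, signal)
  }
  y
}

#' Study table with bias-adjusted observations
#'
#' Returns a copy of `t` whose `log_effect` column has the selected
#' covariate effects removed, for the final adjusted curve fit.
#'
#' @param t A `bop_table`.
#' @param c The `bop_ensemble` providing the signal.
#' @param selection A `bop_selection`.
#' @return A `bop_table`.
#' @export
adjust_table <- function(t, c, selection) {
  out <- t
  out$data$log_effect <- adjusted_log_effect(t, c, selection)
  out
}
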