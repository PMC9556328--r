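# Publication-style figures: risk curve with uncertainty bands and BPRF,
# and the modified funnel plot.

#' Risk-curve figure
#'
#' Mean log-RR (or RR) curve with the fixed-effects 95% band, the
#' heterogeneity-inclusive 95% band, the conservative BPRF curve, and the
#' observed comparisons drawn as points at the alternative-arm midpoint
#' (hollow where trimmed), sized by precision.
#'
#' @param result A `bop_result`.
#' @param scale `"log"` (log RR) or `"rr"`.
#' @return A ggplot object.
#' @export
plot_risk_curve <- function(result, scale = c("log", "rr")) {
  scale <- match.arg(scale)
  cv <- result$curve
  trans <- if (scale == "rr") exp else identity
  ui <- ui_with_heterogeneity(cv, result$gamma, c(0.025, 0.975),
                              result$config$gamma_inflation_k)
  fe_sd <- sqrt(cv$fixed_var)
  band <- data.frame(
    exposure = cv$grid,
    mean = trans(cv$mean_log_rr),
    fe_lo = trans(cv$mean_log_rr - 1.96 * fe_sd),
    fe_hi = trans(cv$mean_log_rr + 1.96 * fe_sd),
    het_lo = trans(ui[, 1]), het_hi = trans(ui[, 2]),
    bprf = trans(result$bprf$bprf_log))
  d <- result$table$data
  ref_anchor <- curve_log_rr(cv, cv$domain[1])
  pts <- data.frame(
    exposure = midpoint_exposure(d$alt_lower, d$alt_upper),
    value = trans(vapply(seq_len(nrow(d)), function(i) {
      curve_range_average(cv, d$ref_lower[i], d$ref_upper[i])
    }, numeric(1)) + d$log_effect - ref_anchor),
    precision = 1 / d$se_log_effect,
    trimmed = result$funnel$trimmed)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$exposure)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$het_lo, ymax = .data$het_hi),
                         fill = "darkseagreen2", alpha = 0.6) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fe_lo, ymax = .data$fe_hi),
                         fill = "darkseagreen3", alpha = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.9) +
    ggplot2::geom_line(ggplot2::aes(y = .data$bprf), colour = "red",
                       linewidth = 0.8) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(y = .data$value, size = .data$precision,
                                     shape = .data$trimmed),
                        colour = "grey30", alpha = 0.7) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::scale_size_continuous(range = c(0.8, 3)) +
    ggplot2::labs(x = "Systolic blood pressure (mm Hg)",
                  y = if (scale == "rr") "Relative risk" else "log(relative risk)",
                  size = "1 / SE", shape = "Trimmed") +
    ggplot2::theme_minimal()
}

#' Modified funnel plot
#'
#' Residuals (relative to 0) against total standard deviation (reported SE
#' combined with between-study heterogeneity), y axis reversed so precise
#' observations sit at the top; trimmed rows are hollow.
#'
#' @param result A `bop_result`.
#' @return A ggplot object.
#' @export
plot_funnel <- function(result) {
  f <- as.data.frame(result$funnel)
  ggplot2::ggplot(f, ggplot2::aes(x = .data$residual, y = .data$sd_total,
                                  shape = .data$trimmed)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue4", size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Residual (log RR)", y = "Total s.d.",
                  shape = "Trimmed") +
    ggplot2::theme_minimal()
}
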