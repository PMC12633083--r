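# ggplot2 displays for result objects ----------------------------------

#' Plot a power curve
#' @param object A [power_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_curve <- function(object, ...) {
  varying <- attr(object, "varying")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid, y = .data$power)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = attr(object, "alpha"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = switch(varying,
        sigma2_I = "Variance explained by G×T interaction",
        rho = "Correlation between true and estimated PES",
        r_GI = "Correlation between true PES and PRS"),
      y = "Power (two-sided)",
      title = sprintf("Analytic power, %s strategy", attr(object, "strategy"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot subgroup ATEs by predicted-CATE quantile
#' @param object A [subgroup_ate()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.subgroup_ate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$bin), y = .data$ate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.15) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "Predicted-CATE quantile bin",
                  y = "Subgroup ATE (95% CI)",
                  title = "Treatment effect by predicted-response stratum") +
    ggplot2::theme_minimal()
}

#' Plot PRS importance scores
#' @param object An importance table from [prs_importance()].
#' @param top Show at most this many PRS (default 25).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_table <- function(object, top = 25, ...) {
  df <- utils::head(object, top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$label, .data$importance))) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "Importance (|t| of tau_hat ~ PRS)", y = NULL,
                  title = "PRS importance for treatment-effect heterogeneity") +
    ggplot2::theme_minimal()
}

#' Plot a method comparison (rejection rates with binomial error bars)
#' @param object A [run_method_comparison()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.method_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$method,
                                       y = .data$rejection_rate)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(0, .data$rejection_rate - 2 * .data$se),
      ymax = pmin(1, .data$rejection_rate + 2 * .data$se)), width = 0.2) +
    ggplot2::geom_hline(yintercept = object$alpha[1], linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = NULL, y = "Rejection rate",
                  title = sprintf("HTE detection, %s scenario (n = %d)",
                                  object$scenario[1], object$n_rct[1])) +
    ggplot2::theme_minimal()
}
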