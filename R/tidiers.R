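# broom-style tidiers ---------------------------------------------------

#' Tidy a best-linear-projection result
#' @param x A `blp_result`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.blp_result <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "tau_hat"),
    estimate = c(x$alpha_hat, x$beta_hat),
    std.error = c(NA_real_, x$se_beta),
    statistic = c(NA_real_, x$statistic),
    p.value = c(NA_real_, x$p_value)
  )
}

#' One-row summary of a best-linear-projection result
#' @param x A `blp_result`.
#' @param ... Unused.
#' @export
glance.blp_result <- function(x, ...) {
  tibble::tibble(beta_hat = x$beta_hat, se_beta = x$se_beta,
                 statistic = x$statistic, p.value = x$p_value,
                 n_used = x$n_used, degenerate = x$degenerate)
}

#' Tidy an individual-level HTE report (per-learner tests)
#' @param x An `hte_report`.
#' @param ... Unused.
#' @export
tidy.hte_report <- function(x, ...) x$global

#' One-row summary of an HTE report
#' @param x An `hte_report`.
#' @param ... Unused.
#' @export
glance.hte_report <- function(x, ...) {
  tibble::tibble(p_combined = x$p_combined, best_learner = x$best_learner,
                 n = x$config$n, k_folds = x$config$k_folds,
                 n_learners = length(x$config$learners),
                 seed = x$config$seed)
}

#' Tidy a summary-statistic scan result (per-PRS tests)
#' @param x A `cauchy_result`.
#' @param ... Unused.
#' @export
tidy.cauchy_result <- function(x, ...) x$per_prs

#' One-row summary of a summary-statistic scan
#' @param x A `cauchy_result`.
#' @param ... Unused.
#' @export
glance.cauchy_result <- function(x, ...) {
  tibble::tibble(t_stat = x$t_stat, p_combined = x$p_combined,
                 n_prs = nrow(x$per_prs))
}
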