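#' Best-linear-projection heterogeneity test
#'
#' Regresses pseudo-outcomes on the out-of-fold CATE predictions,
#' `Y_H = alpha + beta * tau_hat + eps`. A well-calibrated CATE model gives
#' `beta` near 1; pure-noise predictions give `beta` near 0, so rejecting
#' `H0: beta = 0` is evidence of detectable treatment-effect heterogeneity.
#' Standard errors are heteroskedasticity-robust (HC3 sandwich; pseudo-
#' outcomes are heavy-tailed) with a two-sided normal reference.
#'
#' @param y_h Pseudo-outcome vector (or [pseudo_outcome()] result) aligned
#'   with the rows of `tau`.
#' @param tau A `cate_estimate` from [sequential_crossfit()], or a numeric
#'   vector of predictions.
#' @return A `blp_result`: list with `alpha_hat`, `beta_hat`, `se_beta`,
#'   `statistic`, `p_value`, `n_used`, `degenerate`.
#' @export
blp_test <- function(y_h, tau) {
  y_h <- as.numeric(y_h)
  if (inherits(tau, "cate_estimate")) {
    keep <- !is.na(tau$tau_hat)
    t_vec <- tau$tau_hat[keep]
    y_vec <- y_h[keep]
  } else {
    t_vec <- as.numeric(tau)
    y_vec <- y_h
  }
  if (length(t_vec) < 10) {
    abort("blp_test needs at least 10 individuals with out-of-fold predictions.")
  }
  if (stats::var(t_vec) < 1e-12) {
    res <- list(alpha_hat = mean(y_vec), beta_hat = 0, se_beta = NA_real_,
                statistic = 0, p_value = 1, n_used = length(t_vec),
                degenerate = TRUE)
    return(structure(res, class = "blp_result"))
  }
  fit <- stats::lm(y_vec ~ t_vec)
  vc <- sandwich::vcovHC(fit, type = "HC3")
  beta <- unname(coef(fit)[2])
  se <- sqrt(vc[2, 2])
  z <- beta / se
  structure(list(
    alpha_hat = unname(coef(fit)[1]), beta_hat = beta, se_beta = se,
    statistic = z, p_value = two_sided_p(z), n_used = length(t_vec),
    degenerate = FALSE
  ), class = "blp_result")
}

#' @exportS3Method base::print
print.blp_result <- function(x, ...) {
  cat("Best linear projection of pseudo-outcomes on predicted CATE\n")
  cat(sprintf("  n = %d, alpha = %.4f, beta = %.4f (HC3 SE %.4f)\n",
              x$n_used, x$alpha_hat, x$beta_hat, x$se_beta))
  cat(sprintf("  z = %.3f, two-sided p = %.4g%s\n", x$statistic, x$p_value,
              if (x$degenerate) " [degenerate: constant predictions]" else ""))
  invisible(x)
}

#' Subgroup average treatment effects by predicted-CATE quantile
#'
#' Sorts individuals with out-of-fold predictions by `tau_hat` (ties broken
#' by a stable sort on id, for determinism), splits them into `q`
#' near-equal quantile bins, and estimates a difference-in-means ATE with
#' unpooled SE, normal confidence interval and two-sided p in each bin.
#'
#' @param data The [trial_dataset()] the predictions refer to.
#' @param tau A `cate_estimate` from [sequential_crossfit()].
#' @param q Number of quantile bins (default 4).
#' @param conf_level Confidence level for the per-bin intervals.
#' @return A `subgroup_ate` tibble: one row per bin with `bin`, `n`,
#'   `tau_hat_min`, `tau_hat_max`, `ate`, `se`, `ci_low`, `ci_high`, `p`.
#' @export
subgroup_ate <- function(data, tau, q = 4L, conf_level = 0.95) {
  stopifnot(inherits(data, "trial_dataset"), inherits(tau, "cate_estimate"))
  q <- as.integer(q)
  if (q < 1) abort("q must be at least 1.")
  keep <- which(!is.na(tau$tau_hat))
  ord <- keep[order(tau$tau_hat[keep], data$id[keep], method = "radix")]
  sizes <- balanced_sizes(length(ord), q)
  bin_of <- rep(seq_len(q), times = sizes)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- purrr::map(seq_len(q), function(b) {
    idx <- ord[bin_of == b]
    Y <- data$outcome[idx]
    T <- data$treatment[idx]
    if (length(unique(T)) < 2) {
      abort(sprintf("Subgroup bin %d contains only one treatment arm.", b))
    }
    est <- ate_difference_in_means(Y, T)
    tibble::tibble(
      bin = b, n = length(idx),
      tau_hat_min = min(tau$tau_hat[idx]), tau_hat_max = max(tau$tau_hat[idx]),
      ate = est$estimate, se = est$se,
      ci_low = est$estimate - zq * est$se,
      ci_high = est$estimate + zq * est$se,
      p = two_sided_p(est$estimate / est$se)
    )
  })
  structure(dplyr::bind_rows(rows),
            q = q, class = c("subgroup_ate", class(tibble::tibble())))
}

#' PRS importance for treatment-effect heterogeneity
#'
#' For each PRS feature, fits the single-variable regression
#' `tau_hat = a_0 + a_k * PRS_k` on the individuals with out-of-fold
#' predictions and scores importance as the absolute t-statistic
#' `|a_k / SE(a_k)|`. Large scores flag traits whose genetic liability
#' tracks the predicted treatment effect.
#'
#' @param tau A `cate_estimate` from [sequential_crossfit()].
#' @param data The [trial_dataset()] providing the PRS columns.
#' @return An `importance_table` tibble sorted by descending importance:
#'   `label`, `a_k`, `se_ak`, `importance`, `rank`, `zero_variance`.
#' @export
prs_importance <- function(tau, data) {
  stopifnot(inherits(tau, "cate_estimate"), inherits(data, "trial_dataset"))
  keep <- !is.na(tau$tau_hat)
  if (sum(keep) < 10) abort("prs_importance needs at least 10 predicted individuals.")
  t_vec <- tau$tau_hat[keep]
  X <- prs_matrix(data)[keep, , drop = FALSE]
  labels <- attr(data, "prs_labels")
  tau_constant <- stats::var(t_vec) < 1e-12
  rows <- purrr::map(seq_along(labels), function(k) {
    x <- X[, k]
    if (stats::var(x) < 1e-12 || tau_constant) {
      return(tibble::tibble(label = labels[k], a_k = 0, se_ak = NA_real_,
                            importance = 0, zero_variance = stats::var(x) < 1e-12))
    }
    fit <- stats::lm(t_vec ~ x)
    sm <- summary(fit)$coefficients
    tibble::tibble(label = labels[k], a_k = sm[2, 1], se_ak = sm[2, 2],
                   importance = abs(sm[2, 1] / sm[2, 2]), zero_variance = FALSE)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$importance))
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("importance_table", class(tibble::tibble())))
}
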