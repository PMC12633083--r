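#' Individual-level heterogeneous-treatment-effect pipeline
#'
#' Runs the full individual-level pipeline for each requested learner:
#' pseudo-outcomes, sequential cross-fitting of a CATE model on the PRS
#' features, the best-linear-projection heterogeneity test, quantile
#' subgroup ATEs, and PRS importance ranking. When several learners are
#' supplied, every per-learner p-value is reported and the headline
#' combined p-value applies a Bonferroni correction across learners
#' (taking the minimum without correction would overstate significance).
#'
#' @param data A [trial_dataset()].
#' @param learners A [learner_spec()] or list of them (default: penalized
#'   linear).
#' @param k_folds Number of sequential folds (default 5).
#' @param q Number of subgroup quantile bins (default 4).
#' @param seed Integer seed; the run is fully reproducible given it.
#' @return An `hte_report`: list with `global` (per-learner tibble of BLP
#'   results), `p_combined` (Bonferroni across learners), `subgroups`,
#'   `importance`, `cate`, `fits` (per-learner component objects), and
#'   `config`.
#' @export
run_mlearner_i <- function(data, learners = learner_spec("penalized_linear"),
                           k_folds = 5L, q = 4L, seed = 1L) {
  stopifnot(inherits(data, "trial_dataset"))
  if (inherits(learners, "learner_spec")) learners <- list(learners)
  stopifnot(length(learners) >= 1,
            all(vapply(learners, inherits, logical(1), "learner_spec")))

  e <- trial_propensity(data)
  y_h <- as.numeric(pseudo_outcome(data$outcome, data$treatment, e))

  fits <- purrr::map(learners, function(sp) {
    cate <- sequential_crossfit(data, sp, k_folds = k_folds, seed = seed)
    blp <- blp_test(y_h, cate)
    list(
      learner = sp$name,
      cate = cate,
      blp = blp,
      subgroups = subgroup_ate(data, cate, q = q),
      importance = prs_importance(cate, data)
    )
  })
  names(fits) <- vapply(fits, `[[`, character(1), "learner")

  global <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(learner = f$learner, beta_hat = f$blp$beta_hat,
                   se_beta = f$blp$se_beta, statistic = f$blp$statistic,
                   p_value = f$blp$p_value, degenerate = f$blp$degenerate,
                   n_used = f$blp$n_used)
  })
  p_combined <- min(1, length(fits) * min(global$p_value))
  best <- global$learner[which.min(global$p_value)]

  structure(list(
    global = global,
    p_combined = p_combined,
    best_learner = best,
    subgroups = fits[[best]]$subgroups,
    importance = fits[[best]]$importance,
    cate = fits[[best]]$cate,
    fits = fits,
    config = list(k_folds = k_folds, q = q, seed = seed, propensity = e,
                  n = nrow(data), learners = names(fits))
  ), class = "hte_report")
}

#' @exportS3Method base::print
print.hte_report <- function(x, ...) {
  cat("Heterogeneous treatment effect report (individual-level pipeline)\n")
  cat(sprintf("  n = %d, K = %d folds, seed = %d\n",
              x$config$n, x$config$k_folds, x$config$seed))
  cat("  Per-learner best-linear-projection tests:\n")
  for (i in seq_len(nrow(x$global))) {
    cat(sprintf("    %-18s beta = %7.4f  p = %.4g\n",
                x$global$learner[i], x$global$beta_hat[i], x$global$p_value[i]))
  }
  cat(sprintf("  Combined p (Bonferroni over %d learner%s): %.4g\n",
              nrow(x$global), if (nrow(x$global) > 1) "s" else "",
              x$p_combined))
  cat(sprintf("  Subgroup ATEs (best learner: %s):\n", x$best_learner))
  print(tibble::as_tibble(x$subgroups), n = nrow(x$subgroups))
  invisible(x)
}

#' Write an HTE report to disk
#'
#' Serializes the report as JSON (global p-values, subgroup and importance
#' tables, configuration incl. seed) plus tab-separated tables.
#'
#' @param report An `hte_report`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_hte_report <- function(report, dir) {
  stopifnot(inherits(report, "hte_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    json = file.path(dir, "hte_report.json"),
    global = file.path(dir, "global_tests.tsv"),
    subgroups = file.path(dir, "subgroup_ate.tsv"),
    importance = file.path(dir, "prs_importance.tsv")
  )
  jsonlite::write_json(list(
    global = report$global, p_combined = report$p_combined,
    best_learner = report$best_learner,
    subgroups = tibble::as_tibble(report$subgroups),
    importance = tibble::as_tibble(report$importance),
    config = report$config
  ), paths["json"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(report$global, paths["global"])
  readr::write_tsv(tibble::as_tibble(report$subgroups), paths["subgroups"])
  readr::write_tsv(tibble::as_tibble(report$importance), paths["importance"])
  invisible(paths)
}
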