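#' Per-PRS treatment-interaction z test from summary statistics
#'
#' Tests whether the trait tracked by one GWAS modifies treatment response,
#' using only summary statistics: the GWAS marginal z-scores act as PRS
#' weights `w_j`, and the statistic aggregates the SNP-by-treatment
#' interaction z-scores as `z = sum_j w_j Z_Ij / sqrt(sum_j w_j^2)` over
#' harmonized shared variants. Under the null of no PRS-by-treatment
#' interaction, and with (approximately) LD-independent variants, `z` is
#' standard normal. LD pruning is the caller's responsibility.
#'
#' @param gwis A `sumstats` of kind `gwis_interaction`.
#' @param gwas A `sumstats` of kind `gwas_marginal` for one trait, or a
#'   harmonized pair table from [harmonize_variants()].
#' @return A one-row tibble: `trait_label`, `z`, `p_value`,
#'   `n_variants_used`.
#' @export
prs_treatment_interaction_z <- function(gwis, gwas) {
  if (inherits(gwas, "sumstats")) {
    label <- attr(gwas, "trait_label")
    pairs <- harmonize_variants(gwis, gwas)
  } else {
    label <- attr(gwas, "trait_label") %||% "trait"
    pairs <- gwas
  }
  w <- pairs$z_other
  z_i <- pairs$z_ref
  denom <- sqrt(sum(w^2))
  if (denom == 0) abort("All PRS weights are zero; the statistic is undefined.")
  z <- sum(w * z_i) / denom
  tibble::tibble(trait_label = label, z = z, p_value = two_sided_p(z),
                 n_variants_used = length(w))
}

#' Cauchy combination of p-values
#'
#' Aggregates K p-values through the Cauchy combination statistic
#' `T_K = mean(tan((1/2 - p_k) * pi))`; the combined p-value is
#' `1/2 - arctan(T_K) / pi`, i.e. the upper tail of a standard Cauchy
#' variable at `T_K`. The test keeps its size under arbitrary dependence
#' among the component tests, which is what makes it suitable for scans
#' over many correlated PRS. Inputs are clipped into
#' `[1e-15, 1 - 1e-15]` before the tangent transform to avoid overflow.
#'
#' @param pvals Vector of p-values in (0, 1).
#' @return A list with `t_stat` (`T_K`) and `p_combined`.
#' @export
cauchy_combine <- function(pvals) {
  if (length(pvals) == 0) abort("Need at least one p-value to combine.")
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p <- pmin(pmax(pvals, 1e-15), 1 - 1e-15)
  t_stat <- mean(tan((0.5 - p) * pi))
  list(t_stat = t_stat, p_combined = 0.5 - atan(t_stat) / pi)
}

#' Summary-statistic heterogeneous-treatment-effect scan
#'
#' Runs the per-PRS treatment-interaction z test for every supplied GWAS
#' against one genome-wide interaction study, combines the per-PRS
#' p-values with the Cauchy combination test into a single global p-value
#' for treatment-effect heterogeneity, and ranks the PRS by ascending
#' p-value. Per-PRS Bonferroni-adjusted p-values are included for
#' follow-up of individual traits.
#'
#' @param gwis A `sumstats` of kind `gwis_interaction`.
#' @param gwas_list List of `sumstats` of kind `gwas_marginal` (one per
#'   trait). A GWAS with no harmonizable variants is excluded with a
#'   warning; if all are excluded, an error is raised.
#' @return A `cauchy_result`: list with `per_prs` (tibble ranked by
#'   ascending p, with `rank` and `p_bonferroni`), `t_stat`, `p_combined`.
#' @export
run_mlearner_s <- function(gwis, gwas_list) {
  stopifnot(inherits(gwis, "sumstats"), length(gwas_list) >= 1)
  if (inherits(gwas_list, "sumstats")) gwas_list <- list(gwas_list)
  rows <- purrr::map(gwas_list, function(g) {
    tryCatch(prs_treatment_interaction_z(gwis, g), error = function(err) {
      warn(sprintf("Excluding trait `%s`: %s",
                   attr(g, "trait_label"), conditionMessage(err)))
      NULL
    })
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) abort("No GWAS could be harmonized against the GWIS.")
  per_prs <- dplyr::bind_rows(rows)
  cc <- cauchy_combine(per_prs$p_value)
  per_prs <- dplyr::arrange(per_prs, .data$p_value)
  per_prs$rank <- seq_len(nrow(per_prs))
  per_prs$p_bonferroni <- pmin(1, per_prs$p_value * nrow(per_prs))
  structure(list(per_prs = per_prs, t_stat = cc$t_stat,
                 p_combined = cc$p_combined),
            class = "cauchy_result")
}

#' @exportS3Method base::print
print.cauchy_result <- function(x, ...) {
  cat("Summary-statistic HTE scan (Cauchy combination over PRS)\n")
  cat(sprintf("  %d PRS tested; T = %.4f; combined p = %.4g\n",
              nrow(x$per_prs), x$t_stat, x$p_combined))
  print(utils::head(tibble::as_tibble(x$per_prs), 10))
  invisible(x)
}
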