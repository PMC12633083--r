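#' Monte Carlo comparison of HTE detection methods
#'
#' Replicates the simulation study harness: for each replicate `r`, a trial
#' is simulated with seed `seed + r`, each requested method is run, and a
#' rejection at level `alpha` is recorded. Power (or, under
#' `pes_mode = "null"`, the type-I error rate) is the fraction of
#' replicates rejecting the null of no heterogeneity.
#'
#' @param config A [sim_config()]; `config$pes_mode` defines the scenario.
#' @param methods Character vector drawn from `"mlearner_i"`,
#'   `"single_prs"`, `"within_gwis"`, `"prspgx"`, `"mlearner_snp"`,
#'   `"mlearner_s"`.
#' @param replicates Number of replicates (default `config$replicates`).
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param alpha Significance level (default 0.05).
#' @param learner Learner for the CATE pipelines (default penalized
#'   linear).
#' @param k_folds Folds for the CATE pipelines.
#' @param exclude_failures Log and drop failing replicates from a method's
#'   denominator instead of erroring (default `FALSE`).
#' @return A `method_comparison` tibble: `method`, `scenario`, `n_rct`,
#'   `replicates`, `n_reject`, `rejection_rate`, `se` (binomial), `alpha`,
#'   `seed`.
#' @export
run_method_comparison <- function(config = sim_config(),
                                  methods = c("mlearner_i", "single_prs"),
                                  replicates = config$replicates,
                                  seed = config$seed, alpha = 0.05,
                                  learner = learner_spec("penalized_linear"),
                                  k_folds = 5L,
                                  exclude_failures = FALSE) {
  known <- c("mlearner_i", "single_prs", "within_gwis", "prspgx",
             "mlearner_snp", "mlearner_s")
  stopifnot(all(methods %in% known))
  needs_geno <- any(methods %in% c("within_gwis", "prspgx", "mlearner_snp",
                                   "mlearner_s"))
  pvals <- matrix(NA_real_, nrow = replicates, ncol = length(methods),
                  dimnames = list(NULL, methods))
  for (r in seq_len(replicates)) {
    seed_r <- seed + r
    dat <- simulate_trial(config, seed = seed_r,
                          include_genotypes = needs_geno)
    for (m in methods) {
      p <- tryCatch(
        method_p_value(m, dat, seed = seed_r, learner = learner,
                       k_folds = k_folds),
        error = function(err) {
          if (!exclude_failures) {
            abort(sprintf("Method %s failed on replicate %d: %s",
                          m, r, conditionMessage(err)))
          }
          warn(sprintf("Dropping replicate %d for %s: %s", r, m,
                       conditionMessage(err)))
          NA_real_
        })
      pvals[r, m] <- p
    }
  }
  rows <- purrr::map(methods, function(m) {
    p <- pvals[, m]
    ok <- !is.na(p)
    rate <- mean(p[ok] <= alpha)
    tibble::tibble(
      method = m, scenario = config$pes_mode, n_rct = config$n_rct,
      replicates = sum(ok), n_reject = sum(p[ok] <= alpha),
      rejection_rate = rate,
      se = sqrt(rate * (1 - rate) / sum(ok)),
      alpha = alpha, seed = seed
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "p_values") <- pvals
  class(out) <- c("method_comparison", class(tibble::tibble()))
  out
}

# dispatch one method on one simulated trial, returning its p-value
method_p_value <- function(method, dat, seed, learner, k_folds) {
  switch(method,
    mlearner_i = run_mlearner_i(dat, learner, k_folds = k_folds,
                                seed = seed)$p_combined,
    single_prs = single_prs_interaction(dat, prs = "prs_outcome")$p_value,
    within_gwis = within_gwis_pes(dat, seed = seed)$p_value,
    prspgx = prspgx(dat, seed = seed)$p_value,
    mlearner_snp = mlearner_snp(dat, learner, k_folds = k_folds,
                                seed = seed)$p_combined,
    mlearner_s = mlearner_s_from_trial(dat, seed = seed)$p_combined
  )
}

#' Summary-statistic pipeline applied to a simulated trial
#'
#' Emulates the summary-level workflow on simulated data: the
#' genome-wide interaction scan is computed from the trial itself
#' ([gwis_scan()]), and per-trait GWAS z-scores for each auxiliary PRS are
#' synthesized from the generator's SNP weight matrix with sampling noise
#' for a GWAS of `config$n_gwas` individuals. The scan and the Cauchy
#' combination then run exactly as on real summary statistics.
#'
#' @param dat A [simulate_trial()] dataset with genotypes.
#' @param seed Integer seed for the synthesized GWAS noise.
#' @return A `cauchy_result` from [run_mlearner_s()].
#' @export
mlearner_s_from_trial <- function(dat, seed = 1L) {
  gm <- attr(dat, "genotypes")
  truth <- trial_truth(dat)
  if (is.null(gm) || is.null(truth$prs_weights)) {
    abort("mlearner_s_from_trial needs a genotype-backed simulated trial.")
  }
  G <- std_dosages(gm)
  scan <- gwis_scan(dat$outcome, dat$treatment, G)
  J <- nrow(scan)
  alleles <- tibble::tibble(variant_id = scan$variant_id,
                            allele_effect = "A", allele_other = "G")
  gwis <- sumstats(dplyr::mutate(alleles,
                                 z = ifelse(is.na(scan$z_I), 0, scan$z_I),
                                 n = nrow(dat)),
                   kind = "gwis_interaction", trait_label = "trial_gwis")
  cfg <- truth$config
  set.seed(derive_seed(seed, 61L))
  gwas_list <- purrr::map(seq_len(ncol(truth$prs_weights)), function(k) {
    z_k <- sqrt(cfg$n_gwas) * sqrt(truth$h2[k]) * truth$prs_weights[, k] +
      rnorm(J)
    sumstats(dplyr::mutate(alleles, z = z_k, n = cfg$n_gwas),
             kind = "gwas_marginal", trait_label = paste0("trait_", k))
  })
  run_mlearner_s(gwis, gwas_list)
}
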