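#' Simulation configuration for the synthetic RCT engine
#'
#' Defaults reproduce the generative model used throughout the package's
#' calibration and power studies: a unit-variance quantitative outcome
#' `Y = sqrt(0.1) * PRS_baseline + S * T_std + 0.01 * T_std + eps`, where
#' the polygenic efficacy score `S` explains 10% of outcome variance, a
#' panel of 25 auxiliary true PRS with heritabilities drawn from
#' `N(0.5, 0.05)` and pairwise correlation targets spanning
#' `[-0.8, 0.8]`, and estimated PRS obtained by adding GWAS estimation
#' noise of variance `Me / n_gwas` (effective SNP number 60,000, GWAS
#' sample 200,000). The linear PES weights the 25 PRS with coefficients
#' equally spaced in `[-0.6, 0.6]`.
#'
#' @param n_rct RCT sample size (500 / 1000 / 2000 in the study scenarios).
#' @param n_snps Number of SNPs for genotype-level runs (scaled-down
#'   default 2000).
#' @param n_aux_prs Number of auxiliary PRS (default 25).
#' @param h2_mean,h2_sd Mean and SD of per-trait heritability draws.
#' @param corr_low,corr_high Range spanned by the PRS correlation targets.
#' @param var_baseline Outcome variance explained by the baseline PRS.
#' @param var_pes Outcome variance explained by the G-by-T interaction.
#' @param t_coef Treatment main-effect coefficient on the standardized
#'   treatment indicator.
#' @param n_gwas External GWAS sample size for PRS estimation noise.
#' @param Me Effective number of independent SNPs.
#' @param p_treat Randomization probability.
#' @param pes_mode `"linear"`, `"nonlinear"` or `"null"` (no G-by-T
#'   component).
#' @param weights Linear PES weights over the auxiliary PRS.
#' @param maf_range Minor-allele-frequency range for simulated genotypes.
#' @param seed Base seed.
#' @param replicates Default replicate count for Monte Carlo studies.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_rct = 1000, n_snps = 2000, n_aux_prs = 25,
                       h2_mean = 0.5, h2_sd = 0.05,
                       corr_low = -0.8, corr_high = 0.8,
                       var_baseline = 0.1, var_pes = 0.1, t_coef = 0.01,
                       n_gwas = 200000, Me = 60000, p_treat = 0.5,
                       pes_mode = c("linear", "nonlinear", "null"),
                       weights = seq(-0.6, 0.6, length.out = n_aux_prs),
                       maf_range = c(0.05, 0.5),
                       seed = 1L, replicates = 500L) {
  pes_mode <- match.arg(pes_mode)
  check_prob(p_treat, "p_treat")
  if (var_baseline + var_pes + t_coef^2 >= 1) {
    abort("Variance budget var_baseline + var_pes + t_coef^2 must stay below 1.")
  }
  stopifnot(length(weights) == n_aux_prs, Me > 0, n_gwas > 0,
            corr_low >= -1, corr_high <= 1, corr_low <= corr_high)
  structure(list(
    n_rct = n_rct, n_snps = n_snps, n_aux_prs = n_aux_prs,
    h2_mean = h2_mean, h2_sd = h2_sd,
    corr_low = corr_low, corr_high = corr_high,
    var_baseline = var_baseline, var_pes = var_pes, t_coef = t_coef,
    n_gwas = n_gwas, Me = Me, p_treat = p_treat, pes_mode = pes_mode,
    weights = weights, maf_range = maf_range,
    seed = as.integer(seed), replicates = as.integer(replicates)
  ), class = "sim_config")
}

#' Simulate a genotype dosage matrix
#'
#' Per-variant minor allele frequencies are drawn uniformly over
#' `maf_range` and dosages as `Binomial(2, MAF_j)`.
#'
#' @param n Number of individuals.
#' @param J Number of variants.
#' @param maf_range MAF range (default `c(0.05, 0.5)`).
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with per-variant `mafs` recorded.
#' @export
simulate_genotypes <- function(n, J, maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  set.seed(derive_seed(seed, 11L))
  mafs <- runif(J, maf_range[1], maf_range[2])
  dos <- matrix(rbinom(n * J, 2L, rep(mafs, each = n)), nrow = n, ncol = J)
  genotype_matrix(dos, variant_ids = paste0("snp_", seq_len(J)), mafs = mafs)
}

# deterministic correlation target for the auxiliary PRS panel.
#
# One-factor construction: trait k loads lambda_k on a shared factor, with
# loadings equally spaced in [-sqrt(|low|), sqrt(high)], so the pairwise
# correlations lambda_k * lambda_l range over [low, ~high] and the matrix
# I + Lambda Lambda' - diag(lambda^2) is positive semidefinite by
# construction (no ad hoc repair step, which would distort the intended
# range). Cached per (K, low, high).
corr_cache <- new.env(parent = emptyenv())

prs_correlation_target <- function(K, low = -0.8, high = 0.8) {
  key <- sprintf("%d_%g_%g", K, low, high)
  if (!is.null(corr_cache[[key]])) return(corr_cache[[key]])
  lam <- seq(-sqrt(abs(low)), sqrt(high), length.out = K)
  # interleave the loadings from both ends of the range so that the
  # loading sequence is not aligned with any monotone trait ordering
  # (e.g. the linear PES weights); a perfectly aligned panel would
  # collapse to a single common factor, which is not the architecture a
  # multi-trait PRS panel is meant to emulate
  idx <- as.vector(rbind(seq_len(ceiling(K / 2)),
                         K + 1 - seq_len(ceiling(K / 2))))[seq_len(K)]
  lam <- lam[idx]
  R <- tcrossprod(lam)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("PRS correlation target is not positive semidefinite.")
  corr_cache[[key]] <- R
  R
}

#' Simulate a correlated panel of true and estimated PRS
#'
#' True PRS are drawn from a multivariate normal with unit variances and
#' the deterministic correlation target described in [sim_config()].
#' Estimated PRS add independent GWAS estimation noise of variance
#' `Me / n_gwas` and are re-standardized, so the true-estimated
#' correlation per trait is about `1 / sqrt(1 + Me / n_gwas)`. A baseline
#' (outcome-trait) PRS pair is generated the same way, independently of
#' the auxiliary panel. Per-trait heritability draws are recorded as
#' metadata.
#'
#' @param n Number of individuals.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param genotypes Optional [genotype_matrix()]; when supplied, true PRS
#'   are built as linear combinations of the standardized dosages (weight
#'   rows drawn to match the correlation target), so that SNP-level
#'   methods see a consistent genetic architecture. The weight matrices
#'   are returned for summary-statistic synthesis.
#' @return List with `true_prs`, `est_prs` (n x K matrices),
#'   `baseline_true`, `baseline_est` (vectors), `h2` (length-K draws),
#'   `corr_target`, and for genotype-backed panels `prs_weights`
#'   (J x K) and `baseline_weights` (J).
#' @export
simulate_prs_panel <- function(n, config = sim_config(), seed = 1L,
                               genotypes = NULL) {
  K <- config$n_aux_prs
  R <- prs_correlation_target(K, config$corr_low, config$corr_high)
  set.seed(derive_seed(seed, 21L))
  h2 <- pmin(pmax(rnorm(K, config$h2_mean, config$h2_sd), 0.01), 0.99)
  prs_weights <- NULL
  baseline_weights <- NULL
  if (is.null(genotypes)) {
    true_prs <- MASS::mvrnorm(n, mu = rep(0, K), Sigma = R)
    baseline_true <- rnorm(n)
  } else {
    G_std <- std_dosages(genotypes)
    J <- ncol(G_std)
    prs_weights <- MASS::mvrnorm(J, mu = rep(0, K), Sigma = R / J)
    true_prs <- G_std %*% prs_weights
    baseline_weights <- rnorm(J) / sqrt(J)
    baseline_true <- drop(G_std %*% baseline_weights)
    # rescale weights so the recorded linear maps reproduce the
    # standardized scores exactly
    sds <- apply(true_prs, 2, stats::sd)
    true_prs <- scale(true_prs, scale = sds)[, , drop = TRUE]
    prs_weights <- sweep(prs_weights, 2, sds, "/")
    b_sd <- stats::sd(baseline_true)
    baseline_true <- scale(baseline_true, scale = b_sd)[, 1]
    baseline_weights <- baseline_weights / b_sd
  }
  noise_var <- config$Me / config$n_gwas
  est_prs <- true_prs + matrix(rnorm(n * K, sd = sqrt(noise_var)), n, K)
  est_prs <- standardize_cols(est_prs)
  baseline_est <- standardize(baseline_true + rnorm(n, sd = sqrt(noise_var)))
  colnames(true_prs) <- colnames(est_prs) <- paste0("prs_", seq_len(K))
  list(true_prs = true_prs, est_prs = est_prs,
       baseline_true = baseline_true, baseline_est = baseline_est,
       h2 = h2, corr_target = R,
       prs_weights = prs_weights, baseline_weights = baseline_weights)
}

#' Linear polygenic efficacy score
#'
#' `S = sqrt(var_pes) * standardize(0.1 * baseline + aux %*% weights)`:
#' a weighted combination of the baseline and auxiliary true PRS, scaled
#' so the G-by-T component contributes exactly `var_pes` of outcome
#' variance.
#'
#' @param baseline_prs Standardized baseline PRS vector.
#' @param aux_prs n x K matrix of auxiliary true PRS.
#' @param weights Length-K weight vector.
#' @param var_pes Target variance of the PES.
#' @return PES vector `S` with sample variance `var_pes`.
#' @export
pes_linear <- function(baseline_prs, aux_prs, weights, var_pes = 0.1) {
  aux_prs <- as.matrix(aux_prs)
  stopifnot(length(weights) == ncol(aux_prs),
            length(baseline_prs) == nrow(aux_prs))
  raw <- 0.1 * baseline_prs + drop(aux_prs %*% weights)
  sqrt(var_pes) * standardize(raw)
}

# the fixed nonlinear transform of the auxiliary PRS panel
nonlinear_f <- function(aux_prs) {
  P <- as.matrix(aux_prs)
  if (ncol(P) < 25) abort("The nonlinear PES needs at least 25 auxiliary PRS.")
  5 * P[, 1] + P[, 2] * P[, 3] + sin(P[, 4]) + cos(P[, 5]) + exp(P[, 6]) +
    log(abs(P[, 7]) + 1) + P[, 8] * P[, 9] - P[, 10]^3 +
    0.1 * rowSums(P[, 11:25, drop = FALSE]^2)
}

#' Nonlinear polygenic efficacy score
#'
#' Replaces the linear combination with a fixed nonlinear transform of the
#' first 25 auxiliary PRS (`f = 5 P1 + P2 P3 + sin P4 + cos P5 + exp P6 +
#' log(|P7| + 1) + P8 P9 - P10^3 + 0.1 * sum_{j=11..25} Pj^2`), then
#' `S = sqrt(var_pes) * standardize(0.1 * baseline + standardize(f))`.
#' The absolute value inside the logarithm keeps the transform defined on
#' the whole real line.
#'
#' @inheritParams pes_linear
#' @return PES vector `S` with sample variance `var_pes`.
#' @export
pes_nonlinear <- function(baseline_prs, aux_prs, var_pes = 0.1) {
  f <- nonlinear_f(aux_prs)
  raw <- 0.1 * baseline_prs + standardize(f)
  sqrt(var_pes) * standardize(raw)
}

#' Simulate one randomized trial under the polygenic G-by-T model
#'
#' Generates the full study: PRS panel (optionally genotype-backed),
#' polygenic efficacy score according to `pes_mode`, Bernoulli treatment,
#' and the unit-variance outcome
#' `Y = sqrt(var_baseline) * baseline + S * T_std + t_coef * T_std + eps`,
#' with Gaussian noise scaled so that `Var(Y) = 1`. The returned dataset
#' carries the estimated PRS as analysis features (what a practitioner
#' would actually have), the estimated outcome PRS as the extra column
#' `prs_outcome`, and a `truth` attribute with the true `S`, the true
#' CATE (`A + C * S`), and the generator internals for oracle checks.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param include_genotypes Also simulate SNP dosages and tie the PRS panel
#'   to them (required by the SNP-level baselines).
#' @return A [trial_dataset()].
#' @export
simulate_trial <- function(config = sim_config(), seed = config$seed,
                           include_genotypes = FALSE) {
  n <- config$n_rct
  genotypes <- NULL
  if (include_genotypes) {
    genotypes <- simulate_genotypes(n, config$n_snps, config$maf_range,
                                    seed = derive_seed(seed, 31L))
  }
  panel <- simulate_prs_panel(n, config, seed = seed, genotypes = genotypes)

  S <- switch(config$pes_mode,
    linear = pes_linear(panel$baseline_true, panel$true_prs,
                        config$weights, config$var_pes),
    nonlinear = pes_nonlinear(panel$baseline_true, panel$true_prs,
                              config$var_pes),
    null = rep(0, n)
  )
  var_s <- if (config$pes_mode == "null") 0 else config$var_pes
  p <- config$p_treat
  set.seed(derive_seed(seed, 41L))
  T <- rbinom(n, 1L, p)
  T_std <- standardize_treatment(T, p)
  noise_sd <- sqrt(1 - config$var_baseline - var_s - config$t_coef^2)
  Y <- sqrt(config$var_baseline) * panel$baseline_true +
    S * T_std + config$t_coef * T_std + rnorm(n, sd = noise_sd)

  C <- 1 / sqrt(p * (1 - p))
  truth <- list(
    S = S, cate = C * config$t_coef + C * S, A = C * config$t_coef, C = C,
    baseline_true = panel$baseline_true, h2 = panel$h2,
    corr_target = panel$corr_target, prs_weights = panel$prs_weights,
    baseline_weights = panel$baseline_weights, config = config, seed = seed
  )
  df <- tibble::tibble(id = sprintf("id_%05d", seq_len(n)),
                       treatment = T, outcome = Y,
                       prs_outcome = panel$baseline_est)
  out <- trial_dataset(df, prs = panel$est_prs, design_p = p,
                       genotypes = genotypes)
  attr(out, "truth") <- truth
  out
}

#' Ground truth attached to a simulated trial
#' @param data A [simulate_trial()] dataset.
#' @return List with the true PES `S`, true CATE, and generator internals.
#' @export
trial_truth <- function(data) attr(data, "truth")
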