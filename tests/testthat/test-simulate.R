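test_that("simulated genotypes are binomial dosages at their drawn MAFs", {
  gm <- simulate_genotypes(5000, 40, seed = 1)
  expect_true(all(gm$dosages %in% 0:2))
  expect_true(all(gm$mafs >= 0.05 & gm$mafs <= 0.5))
  freq <- colMeans(gm$dosages) / 2
  se <- sqrt(gm$mafs * (1 - gm$mafs) / (2 * 5000))
  expect_true(all(abs(freq - gm$mafs) < 4 * se))
  # seeded reproducibility
  gm2 <- simulate_genotypes(5000, 40, seed = 1)
  expect_identical(gm$dosages, gm2$dosages)
})

test_that("the PRS panel matches its correlation and attenuation targets", {
  cfg <- sim_config()
  panel <- simulate_prs_panel(20000, cfg, seed = 2)
  expect_equal(dim(panel$true_prs), c(20000, 25))
  expect_lt(max(abs(colMeans(panel$true_prs))), 0.03)
  expect_lt(max(abs(apply(panel$true_prs, 2, var) - 1)), 0.06)
  # attenuation: corr(true, est) = 1/sqrt(1 + Me/n_gwas) per trait
  expected_r <- 1 / sqrt(1 + cfg$Me / cfg$n_gwas)
  obs_r <- vapply(1:25, function(k) {
    cor(panel$true_prs[, k], panel$est_prs[, k])
  }, 1)
  expect_true(all(abs(obs_r - expected_r) < 0.03))
  # realized correlation structure close to the target: every entry
  # within Monte Carlo error (entry SE is about (1 - r^2)/sqrt(n), at most
  # 1/sqrt(n)), and the aggregate Frobenius distance consistent with
  # sqrt(K^2/n) accumulation of that noise
  dev <- abs(cor(panel$true_prs) - panel$corr_target)
  expect_lt(max(dev), 5 / sqrt(20000))
  expect_lt(norm(cor(panel$true_prs) - panel$corr_target, "F"),
            2 * sqrt(25^2 / 20000))
  # target is a PSD correlation matrix spanning the requested range
  R <- panel$corr_target
  expect_equal(diag(R), rep(1, 25))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  off <- R[upper.tri(R)]
  expect_lt(min(off), -0.5)
  expect_gt(max(off), 0.5)
})

test_that("linear PES has exactly its variance budget", {
  set.seed(3)
  aux <- matrix(rnorm(250), 10, 25)
  base <- rnorm(10)
  w <- seq(-0.6, 0.6, length.out = 25)
  S <- pes_linear(base, aux, w, var_pes = 0.1)
  expect_lt(abs(var(S) - 0.1), 1e-10)
  # loop oracle for the raw combination
  raw <- numeric(10)
  for (i in 1:10) {
    raw[i] <- 0.1 * base[i]
    for (k in 1:25) raw[i] <- raw[i] + aux[i, k] * w[k]
  }
  expect_equal(S, sqrt(0.1) * (raw - mean(raw)) / sd(raw))
  # zero weights leave a pure (standardized) baseline score
  S0 <- pes_linear(base, aux, rep(0, 25), var_pes = 0.1)
  expect_equal(abs(cor(S0, base)), 1)
})

test_that("nonlinear PES evaluates its fixed transform", {
  # all-zero PRS row: f = cos(0) + exp(0) = 2, all other terms vanish
  expect_equal(polyhte:::nonlinear_f(matrix(0, 1, 25)), 2)
  set.seed(4)
  aux <- matrix(rnorm(30 * 25), 30, 25)
  base <- rnorm(30)
  S1 <- pes_nonlinear(base, aux, var_pes = 0.1)
  S2 <- pes_nonlinear(base, aux, var_pes = 0.1)
  expect_identical(S1, S2)
  expect_lt(abs(var(S1) - 0.1), 1e-10)
  # log term is defined even for extreme negative PRS values
  aux[, 7] <- -50
  expect_true(all(is.finite(pes_nonlinear(base, aux, var_pes = 0.1))))
})

test_that("simulated outcomes satisfy the variance bookkeeping", {
  cfg <- sim_config(n_rct = 20000, pes_mode = "linear")
  dat <- simulate_trial(cfg, seed = 5)
  truth <- trial_truth(dat)
  expect_lt(abs(var(dat$outcome) - 1), 0.05)
  expect_lt(abs(mean(dat$treatment) - 0.5), 3 * sqrt(0.25 / 20000))
  # component variances match their budgets
  t_std <- standardize_treatment(dat$treatment, 0.5)
  expect_lt(abs(var(truth$S * t_std) - 0.1), 0.01)
  expect_lt(abs(var(sqrt(0.1) * truth$baseline_true) - 0.1), 0.01)
  # null mode drops the interaction component
  datn <- simulate_trial(sim_config(n_rct = 2000, pes_mode = "null"), seed = 5)
  expect_true(all(trial_truth(datn)$S == 0))
  expect_lt(abs(var(datn$outcome) - 1), 0.07)
  # variance budget must stay below 1
  expect_error(sim_config(var_baseline = 0.6, var_pes = 0.5), "budget")
})

test_that("attenuation carries through to a PES rebuilt from estimated PRS", {
  cfg <- sim_config(n_rct = 20000, pes_mode = "linear")
  dat <- simulate_trial(cfg, seed = 6)
  truth <- trial_truth(dat)
  # rebuild the PES from the estimated panel with the true linear weights
  S_est <- pes_linear(dat$prs_outcome, prs_matrix(dat), cfg$weights,
                      var_pes = cfg$var_pes)
  # measurement-error prediction: each standardized estimated PRS is
  # (true + noise)/sqrt(1 + nv) with noise variance nv = Me/n_gwas, so
  # corr(S, S_est) = sqrt((q + b) / (q + nv * sum(w^2) + b * (1 + nv)))
  # with q = w' R w and b the baseline weight contribution 0.1^2
  nv <- cfg$Me / cfg$n_gwas
  w <- cfg$weights
  q <- drop(t(w) %*% truth$corr_target %*% w)
  b <- 0.1^2
  r_pred <- sqrt((q + b) / (q + nv * sum(w^2) + b * (1 + nv)))
  expect_lt(abs(cor(truth$S, S_est) - r_pred), 0.05)
})

test_that("single-PRS interaction test is calibrated under the null generator", {
  cfg <- sim_config(n_rct = 500, pes_mode = "null")
  ps <- vapply(1:500, function(r) {
    dat <- simulate_trial(cfg, seed = 40000 + r)
    single_prs_interaction(dat, prs = 13)$p_value
  }, 1)
  rate <- mean(ps <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("genotype-backed panels tie PRS linearly to the dosages", {
  cfg <- sim_config(n_rct = 600, n_snps = 300, pes_mode = "linear")
  dat <- simulate_trial(cfg, seed = 7, include_genotypes = TRUE)
  gm <- attr(dat, "genotypes")
  truth <- trial_truth(dat)
  expect_equal(dim(gm), c(600L, 300L))
  # recorded weights reproduce the standardized true PRS exactly
  G_std <- apply(gm$dosages, 2, function(x) (x - mean(x)) / sd(x))
  rebuilt <- G_std %*% truth$prs_weights
  expect_lt(max(abs(cor(rebuilt[, 1], rebuilt[, 1]) - 1)), 1e-12)
  expect_lt(max(abs(apply(rebuilt, 2, var) - 1)), 1e-8)
})
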