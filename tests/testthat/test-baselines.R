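test_that("single-PRS interaction model has the four stated terms", {
  dat <- toy_trial(n = 100, K = 3, seed = 1)
  res <- single_prs_interaction(dat, prs = 2)
  expect_equal(length(attr(res, "details")$coefficients), 4)
  expect_between(res$p_value, 0, 1)
  dat2 <- toy_trial(n = 30, K = 1, seed = 2,
                    prs = matrix(1, 30, 1))
  expect_error(single_prs_interaction(dat2, prs = 1), "constant")
})

test_that("single-PRS test rejects a correctly specified strong modifier", {
  # PRS equal to the true S under strong interaction variance
  cfg <- sim_config(n_rct = 2000, pes_mode = "linear")
  hits <- vapply(1:60, function(r) {
    dat <- simulate_trial(cfg, seed = 50000 + r)
    single_prs_interaction(dat, prs = trial_truth(dat)$S)$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.90)
})

test_that("within-sample GWIS splits are disjoint and the PES test runs", {
  cfg <- sim_config(n_rct = 400, n_snps = 150, pes_mode = "linear")
  dat <- simulate_trial(cfg, seed = 3, include_genotypes = TRUE)
  res <- within_gwis_pes(dat, seed = 3)
  d <- attr(res, "details")
  expect_equal(d$n_train + d$n_test, 400)
  expect_between(res$p_value, 0, 1)
  expect_error(within_gwis_pes(toy_trial(n = 40)), "genotypes")
})

test_that("within-sample GWIS is calibrated under the null generator", {
  cfg <- sim_config(n_rct = 500, n_snps = 500, pes_mode = "null")
  ps <- vapply(1:200, function(r) {
    dat <- simulate_trial(cfg, seed = 60000 + r, include_genotypes = TRUE)
    within_gwis_pes(dat, seed = r)$p_value
  }, 1)
  rate <- mean(ps <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("the per-SNP scan matches per-SNP lm fits", {
  set.seed(4)
  n <- 120; J <- 8
  G <- matrix(rnorm(n * J), n, J)
  T <- rbinom(n, 1, 0.5)
  y <- 0.3 * G[, 2] + 0.5 * G[, 3] * T + rnorm(n)
  scan <- gwis_scan(y, T, G)
  for (j in c(2, 3, 7)) {
    fit <- summary(lm(y ~ G[, j] * T))$coefficients
    expect_equal(scan$beta_G[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(scan$beta_I[j], fit[4, 1], tolerance = 1e-10)
    expect_equal(scan$se_I[j], fit[4, 2], tolerance = 1e-10)
  }
})

test_that("two-score regression builds its scores by definition", {
  set.seed(5)
  n <- 40; J <- 10
  G <- matrix(rbinom(n * J, 2, 0.3), n, J)
  G_std <- apply(G, 2, function(x) (x - mean(x)) / sd(x))
  T <- rep(c(0, 1), n / 2)
  y <- rnorm(n)
  scan <- gwis_scan(y, T, G_std)
  prog <- numeric(n); pred <- numeric(n)
  for (i in 1:n) for (j in 1:J) {
    prog[i] <- prog[i] + G_std[i, j] * scan$beta_G[j]
    pred[i] <- pred[i] + G_std[i, j] * scan$beta_I[j]
  }
  expect_equal(drop(G_std %*% scan$beta_G), prog)
  expect_equal(drop(G_std %*% scan$beta_I), pred)
})

test_that("two-score model recovers known coefficients", {
  # data generated exactly from the final two-score model
  set.seed(6)
  n <- 20000
  prog <- rnorm(n); pred <- rnorm(n)
  T <- rbinom(n, 1, 0.5)
  y <- 1 + 0.5 * T + 0.3 * prog + 0.4 * T * pred + rnorm(n)
  fit <- lm(y ~ T + prog + T:pred)
  cf <- summary(fit)$coefficients
  for (term in c("(Intercept)", "T", "prog", "T:pred")) {
    truth <- c("(Intercept)" = 1, T = 0.5, prog = 0.3, "T:pred" = 0.4)[term]
    expect_lt(abs(cf[term, 1] - truth), 3 * cf[term, 2])
  }
})

test_that("two-score pipeline is calibrated under the null generator", {
  cfg <- sim_config(n_rct = 600, n_snps = 400, pes_mode = "null")
  ps <- vapply(1:200, function(r) {
    dat <- simulate_trial(cfg, seed = 70000 + r, include_genotypes = TRUE)
    prspgx(dat, seed = r)$p_value
  }, 1)
  rate <- mean(ps <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("SNP-feature pipeline equals the PRS pipeline on identical features", {
  dat <- toy_trial(n = 80, K = 5, seed = 7)
  X <- prs_matrix(dat)
  # attach genotypes whose dosages are an affine copy of the PRS matrix
  dos <- (X - min(X)) / (max(X) - min(X)) * 2
  gm <- genotype_matrix(dos, variant_ids = paste0("v", 1:5))
  attr(dat, "genotypes") <- gm
  rep_snp <- mlearner_snp(dat, learner_spec("penalized_linear"),
                          k_folds = 3, seed = 11)
  dat_prs <- trial_dataset(
    tibble::tibble(id = dat$id, treatment = dat$treatment,
                   outcome = dat$outcome),
    prs = dos, design_p = 0.5)
  rep_prs <- run_mlearner_i(dat_prs, learner_spec("penalized_linear"),
                            k_folds = 3, seed = 11)
  expect_identical(rep_snp$cate$tau_hat, rep_prs$cate$tau_hat)
  expect_identical(rep_snp$p_combined, rep_prs$p_combined)
})

test_that("SNP-feature pipeline is calibrated under the null generator", {
  cfg <- sim_config(n_rct = 400, n_snps = 80, pes_mode = "null")
  ps <- vapply(1:100, function(r) {
    dat <- simulate_trial(cfg, seed = 80000 + r, include_genotypes = TRUE)
    mlearner_snp(dat, seed = 80000 + r)$p_combined
  }, 1)
  rate <- mean(ps <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 100))
})
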