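test_that("expected interaction coefficients follow the random-effects forms", {
  pp <- power_params(sigma2_I = 0.01, Me = 60000, n_rct = 5000)
  # 0.01 / (0.01 + 12) = 8.326e-4
  expect_equal(expected_interaction_coef("within_gwis", pp), 0.01 / 12.01)
  # perfect-estimation limit: Me/N -> 0 gives 1
  pp2 <- power_params(sigma2_I = 0.01, Me = 1e-9, n_rct = 5000)
  expect_equal(expected_interaction_coef("within_gwis", pp2), 1,
               tolerance = 1e-6)
  # uncorrelated single PRS carries no signal
  pp3 <- power_params(r_GI = 0)
  expect_equal(expected_interaction_coef("single_prs", pp3), 0)
})

test_that("multi-PRS coefficient reduces consistently and grows with K", {
  s2I <- 0.03; s2G <- 0.3; r <- 0.4; noise <- 0.15
  cov_wx <- r * sqrt(s2I * s2G)
  cov_xx <- matrix(s2G + noise)
  multi <- expected_interaction_coef("multi_prs", sigma2_W = s2I,
                                     cov_WX = cov_wx, cov_XX = cov_xx)
  # algebraic identity: multi * sigma2_W * cov_XX = single * cov_WX, where
  # single is the single-PRS expected coefficient with the same blocks
  single <- cov_wx / (s2G + noise)
  expect_equal(multi * s2I * cov_xx[1, 1], single * cov_wx * cov_xx[1, 1] /
                 (s2G + noise) * (s2G + noise))
  expect_equal(multi, cov_wx^2 / ((s2G + noise) * s2I))

  # adding an orthogonal informative PRS never decreases the coefficient
  set.seed(1)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    d <- runif(k, 0.2, 1)
    w <- runif(k, -0.3, 0.3)
    base <- expected_interaction_coef("multi_prs", sigma2_W = s2I,
                                      cov_WX = w[-k],
                                      cov_XX = diag(d[-k], nrow = k - 1))
    full <- expected_interaction_coef("multi_prs", sigma2_W = s2I,
                                      cov_WX = w, cov_XX = diag(d, nrow = k))
    expect_gte(full, base)
  }
  expect_error(
    expected_interaction_coef("multi_prs", sigma2_W = 1,
                              cov_WX = c(1, 1),
                              cov_XX = matrix(1, 2, 2)), "singular")
})

test_that("noncentrality closed forms", {
  pp <- power_params(n_test = 2500, sigma2_I = 0.03, rho = 0.5)
  expect_equal(noncentrality("transfer_rho", pp), sqrt(2500 * 0.25 * 0.03))
  expect_equal(noncentrality("transfer_rho", pp), 4.330127, tolerance = 1e-6)
  pp0 <- power_params(rho = 0)
  expect_equal(noncentrality("transfer_rho", pp0), 0)
  pp_w <- power_params(n_test = 2500, sigma2_I = 0.03, Me = 60000,
                       n_rct = 200000)
  expect_equal(noncentrality("within_gwis", pp_w),
               50 * 0.03 / sqrt(0.03 + 0.3))
})

test_that("analytic noncentrality matches a Monte Carlo regression study", {
  # interaction z-statistics from the test regression Y ~ S_hat*T, with
  # S_hat = S + estimation noise of variance Me/N_RCT
  pp <- power_params(n_test = 2500, sigma2_I = 0.03, Me = 60000,
                     n_rct = 200000)
  lam <- noncentrality("within_gwis", pp)
  set.seed(11)
  zs <- vapply(1:500, function(r) {
    n <- 2500
    S <- rnorm(n, sd = sqrt(0.03))
    S_hat <- S + rnorm(n, sd = sqrt(60000 / 200000))
    T <- rbinom(n, 1, 0.5)
    t_std <- standardize_treatment(T, 0.5)
    y <- S * t_std + 0.01 * t_std + rnorm(n, sd = sqrt(1 - 0.03 - 1e-4))
    fit <- summary(lm(y ~ scale(S_hat) * t_std))
    fit$coefficients["scale(S_hat):t_std", "t value"]
  }, 1)
  expect_lt(abs(mean(zs) - lam) / lam, 0.10)
})

test_that("two-sided power is exact at the null, monotone, and symmetric", {
  expect_equal(power_two_sided(0, 0.05), 0.05)
  expect_equal(power_two_sided(0, 0.17), 0.17)
  expect_equal(power_two_sided(4.330127, 0.05), 0.9911, tolerance = 1e-4)
  expect_equal(power_two_sided(50, 0.05), 1)
  expect_equal(power_two_sided(-3, 0.05), power_two_sided(3, 0.05))
  lams <- seq(0, 6, by = 0.25)
  expect_false(is.unsorted(power_two_sided(lams, 0.05)))
  expect_true(all(power_two_sided(lams, 0.05) < 1 + 1e-12))
})

test_that("power curves reproduce the transfer-learning contrast", {
  # with transfer learning: > 90% power once the true-estimated PES
  # correlation reaches 0.5 (N_test = 2500, sigma2_I = 0.03)
  pp <- power_params(n_test = 2500, sigma2_I = 0.03, alpha = 0.05)
  curve_b <- power_curve("transfer_rho", pp, grid = seq(0, 1, 0.05))
  expect_gt(curve_b$power[curve_b$grid == 0.5], 0.90)
  expect_false(is.unsorted(curve_b$power))

  # without transfer learning: negligible power over the realistic
  # 0-5% G-by-T variance range (N_RCT = 2500, Me = 60000)
  pp_a <- power_params(n_rct = 2500, n_test = 2500, Me = 60000)
  curve_a <- power_curve("within_gwis", pp_a, grid = seq(0, 0.05, 0.005))
  expect_lt(max(curve_a$power), 0.10)
  expect_false(is.unsorted(curve_a$power))
})
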