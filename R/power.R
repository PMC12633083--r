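#' Parameters for the analytic power scaling laws
#'
#' Collects the quantities entering the scaling laws for detecting a
#' PES-by-treatment interaction: `sigma2_I`, the proportion of
#' treatment-response variance explained by gene-by-treatment interaction;
#' `sigma2_G`, the outcome heritability; `r_GI`, the correlation between
#' the true polygenic efficacy score and a single PRS; `Me`, the effective
#' number of independent SNPs (controls the estimation noise `Me / N`);
#' `n_rct` and `n_gwas`, the training sample sizes for the within-sample
#' interaction scan and the external GWAS; `n_test`, the evaluation sample
#' size; `alpha`, the test size; and `rho`, the correlation between the
#' true and the estimated PES for the transfer-learning curve.
#'
#' @param sigma2_I,sigma2_G,r_GI,Me,n_rct,n_gwas,n_test,alpha,rho See
#'   description.
#' @return A `power_params` list.
#' @export
power_params <- function(sigma2_I = 0.03, sigma2_G = 0.3, r_GI = 0.5,
                         Me = 60000, n_rct = 2500, n_gwas = 400000,
                         n_test = 2500, alpha = 0.05, rho = 0.5) {
  stopifnot(sigma2_I >= 0, sigma2_I <= 1, sigma2_G >= 0, sigma2_G <= 1,
            abs(r_GI) <= 1, Me > 0, n_rct > 0, n_gwas > 0, n_test > 0,
            alpha > 0, alpha < 1, rho >= 0, rho <= 1)
  structure(list(sigma2_I = sigma2_I, sigma2_G = sigma2_G, r_GI = r_GI,
                 Me = Me, n_rct = n_rct, n_gwas = n_gwas, n_test = n_test,
                 alpha = alpha, rho = rho),
            class = "power_params")
}

#' Expected PES-by-treatment interaction coefficient
#'
#' Expected slope of the interaction term when the test regression
#' `Y ~ S_hat + T + S_hat:T` is run with a PES estimated by one of three
#' strategies, under a random-effects genetic architecture:
#' \describe{
#'   \item{within_gwis}{PES built from within-trial SNP-by-treatment
#'     interaction estimates: `sigma2_I / (sigma2_I + Me / n_rct)`.}
#'   \item{single_prs}{a single external PRS as PES proxy:
#'     `r_GI * sqrt(sigma2_I * sigma2_G) / (sigma2_G + Me / n_gwas)`.}
#'   \item{multi_prs}{the multi-PRS projection
#'     `t(cov_WX) %*% solve(cov_XX) %*% cov_WX / sigma2_W`, from the joint
#'     covariance of the true PES (variance `sigma2_W`) and the PRS panel;
#'     never below the single-PRS value.}
#' }
#'
#' @param strategy `"within_gwis"`, `"single_prs"` or `"multi_prs"`.
#' @param params A [power_params()] (first two strategies).
#' @param sigma2_W,cov_WX,cov_XX Multi-PRS covariance blocks: variance of
#'   the true PES, its covariance vector with the K PRS, and the K x K PRS
#'   covariance matrix (symmetric positive definite).
#' @return The expected interaction coefficient (scalar).
#' @export
expected_interaction_coef <- function(strategy = c("within_gwis", "single_prs",
                                                   "multi_prs"),
                                      params = power_params(),
                                      sigma2_W = NULL, cov_WX = NULL,
                                      cov_XX = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "within_gwis") {
    return(params$sigma2_I / (params$sigma2_I + params$Me / params$n_rct))
  }
  if (strategy == "single_prs") {
    return(params$r_GI * sqrt(params$sigma2_I * params$sigma2_G) /
             (params$sigma2_G + params$Me / params$n_gwas))
  }
  stopifnot(!is.null(sigma2_W), !is.null(cov_WX), !is.null(cov_XX))
  cov_XX <- as.matrix(cov_XX)
  if (!isSymmetric(unname(cov_XX), tol = 1e-8)) abort("cov_XX must be symmetric.")
  ev <- eigen(cov_XX, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) abort("cov_XX is (numerically) singular.")
  as.numeric(t(cov_WX) %*% solve(cov_XX, cov_WX)) / sigma2_W
}

#' Noncentrality parameter of the PES-by-treatment interaction test
#'
#' The mean of the interaction z-statistic under the alternative, for a
#' test sample of size `n_test` with a unit-variance outcome:
#' `lambda = sqrt(n_test) * Cov(S, S_hat) / sqrt(Var(S_hat))`. Closed forms:
#' \describe{
#'   \item{within_gwis}{`sqrt(n_test) * sigma2_I / sqrt(sigma2_I + Me/n_rct)`.}
#'   \item{single_prs}{`sqrt(n_test) * r_GI * sqrt(sigma2_I * sigma2_G) /
#'     sqrt(sigma2_G + Me/n_gwas)`.}
#'   \item{transfer_rho}{for a standardized estimated PES with correlation
#'     `rho` to the truth: `sqrt(n_test) * rho * sqrt(sigma2_I)`.}
#' }
#'
#' @param strategy `"within_gwis"`, `"single_prs"` or `"transfer_rho"`.
#' @param params A [power_params()].
#' @return Noncentrality `lambda` (scalar).
#' @export
noncentrality <- function(strategy = c("within_gwis", "single_prs",
                                       "transfer_rho"),
                          params = power_params()) {
  strategy <- match.arg(strategy)
  with(params, switch(strategy,
    within_gwis = sqrt(n_test) * sigma2_I / sqrt(sigma2_I + Me / n_rct),
    single_prs = sqrt(n_test) * r_GI * sqrt(sigma2_I * sigma2_G) /
      sqrt(sigma2_G + Me / n_gwas),
    transfer_rho = sqrt(n_test) * rho * sqrt(sigma2_I)
  ))
}

#' Two-sided power at a given noncentrality
#'
#' `Power = 1 - Phi(z_{1-alpha/2} - lambda) + Phi(-z_{1-alpha/2} - lambda)`,
#' the normal-approximation power of a two-sided z test; symmetric in the
#' sign of `lambda`, equal to `alpha` at `lambda = 0`.
#'
#' @param lambda Noncentrality parameter (vectorized).
#' @param alpha Two-sided test size in (0, 1).
#' @return Power value(s) in (0, 1).
#' @export
power_two_sided <- function(lambda, alpha = 0.05) {
  check_prob(alpha, "alpha")
  zq <- stats::qnorm(1 - alpha / 2)
  1 - stats::pnorm(zq - lambda) + stats::pnorm(-zq - lambda)
}

#' Power curve over a parameter grid
#'
#' Evaluates the noncentrality and two-sided power along a grid: for
#' `strategy = "within_gwis"` the grid is over `sigma2_I` (power without
#' transfer learning, as a function of the G-by-T-explained variance); for
#' `"transfer_rho"` it is over `rho` (power as a function of how well the
#' estimated PES correlates with the truth); for `"single_prs"` over
#' `r_GI`.
#'
#' @param strategy As in [noncentrality()].
#' @param params A [power_params()].
#' @param grid Numeric grid of the varying parameter.
#' @return A `power_curve` tibble: `grid`, `lambda`, `power`, with the
#'   varying parameter's name in attribute `varying`.
#' @export
power_curve <- function(strategy = c("within_gwis", "single_prs",
                                     "transfer_rho"),
                        params = power_params(),
                        grid = seq(0, 1, by = 0.01)) {
  strategy <- match.arg(strategy)
  varying <- switch(strategy, within_gwis = "sigma2_I",
                    single_prs = "r_GI", transfer_rho = "rho")
  lam <- vapply(grid, function(g) {
    p <- params
    p[[varying]] <- g
    noncentrality(strategy, p)
  }, numeric(1))
  structure(
    tibble::tibble(grid = grid, lambda = lam,
                   power = power_two_sided(lam, params$alpha)),
    strategy = strategy, varying = varying, alpha = params$alpha,
    class = c("power_curve", class(tibble::tibble()))
  )
}
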