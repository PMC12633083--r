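#' Polygenic efficacy score from standardized genotypes
#'
#' The polygenic efficacy score (PES) is the weighted sum of standardized
#' allele counts with SNP-by-treatment interaction effects as weights:
#' `S_i = sum_j G_ij * beta_I[j]`. Under the polygenic gene-by-treatment
#' model the conditional average treatment effect is linear in the PES.
#'
#' @param G_std Standardized genotype matrix (individuals x variants).
#' @param beta_I Interaction effect sizes, one per variant.
#' @return Numeric PES vector, one value per individual.
#' @export
compute_pes <- function(G_std, beta_I) {
  G_std <- as.matrix(G_std)
  if (ncol(G_std) != length(beta_I)) {
    abort("`beta_I` must have one entry per genotype column.")
  }
  as.numeric(G_std %*% beta_I)
}

#' Conditional average treatment effect implied by a PES
#'
#' Under the polygenic gene-by-treatment model with standardized treatment
#' coding, `CATE_i = A + C * S_i` where `A` is the average treatment effect
#' and `C = sqrt((1 - p)/p) + sqrt(p/(1 - p)) = 1 / sqrt(p (1 - p))` is the
#' span of the standardized treatment indicator. `C` is minimized at
#' `p = 0.5` (where `C = 2`) and symmetric in `p` vs `1 - p`.
#'
#' @param S PES vector.
#' @param ate_A Average treatment effect `A`.
#' @param p Treatment probability in (0, 1).
#' @return Numeric CATE vector with attribute `C` (the multiplier).
#' @export
cate_from_pes <- function(S, ate_A, p) {
  check_prob(p, "p")
  C <- 1 / sqrt(p * (1 - p))
  out <- ate_A + C * S
  attr(out, "C") <- C
  out
}

#' Inverse-propensity pseudo-outcome
#'
#' Computes `Y_H = T * Y / e - (1 - T) * Y / (1 - e)`, whose conditional
#' expectation given the covariates equals the conditional average
#' treatment effect, making it an unbiased proxy for the CATE that machine
#' learning models can be trained against.
#'
#' @param Y Outcome vector.
#' @param T 0/1 treatment vector.
#' @param e Propensity score: scalar or per-individual vector, required to
#'   lie in \[1e-3, 1 - 1e-3\] (positivity; in a randomized trial the
#'   design probability is known and well inside this band).
#' @return A `pseudo_outcome` object: numeric vector of `Y_H` values with
#'   attribute `propensity_used`.
#' @export
pseudo_outcome <- function(Y, T, e) {
  if (!all(T %in% c(0, 1))) abort("`T` must be coded 0/1.")
  if (any(e < 1e-3 | e > 1 - 1e-3)) {
    abort(paste("Propensity outside [1e-3, 1 - 1e-3] violates the positivity",
                "requirement; check the randomization probability."))
  }
  e <- rep(e, length.out = length(Y))
  values <- T * Y / e - (1 - T) * Y / (1 - e)
  structure(values, propensity_used = if (length(unique(e)) == 1) e[1] else NA_real_,
            class = "pseudo_outcome")
}

#' Difference-in-means average treatment effect
#'
#' Mean outcome difference between treated and control arms with the
#' unpooled (Welch) standard error `sqrt(s1^2/n1 + s0^2/n0)`.
#'
#' @param Y Outcome vector.
#' @param T 0/1 treatment vector.
#' @return A one-row tibble: `estimate`, `se`, `n1`, `n0`.
#' @export
ate_difference_in_means <- function(Y, T) {
  if (!all(T %in% c(0, 1))) abort("`T` must be coded 0/1.")
  y1 <- Y[T == 1]
  y0 <- Y[T == 0]
  if (length(y1) == 0 || length(y0) == 0) {
    abort("Both treatment arms must be nonempty.")
  }
  v1 <- if (length(y1) > 1) stats::var(y1) else 0
  v0 <- if (length(y0) > 1) stats::var(y0) else 0
  tibble::tibble(
    estimate = mean(y1) - mean(y0),
    se = sqrt(v1 / length(y1) + v0 / length(y0)),
    n1 = length(y1), n0 = length(y0)
  )
}
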