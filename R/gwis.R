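#' Per-SNP gene-by-treatment interaction scan
#'
#' Fits, for every SNP `j`, the ordinary least squares regression
#' `Y ~ 1 + T + G_j + G_j:T` and returns the genotype main-effect and
#' interaction coefficients with classical standard errors. The scan is
#' computed in closed form (Frisch-Waugh residualization on `[1, T]`
#' followed by per-SNP 2x2 solves), so it vectorizes over thousands of
#' SNPs; this is the summary-statistics generator used by the
#' within-sample-GWIS and two-score baselines.
#'
#' @param Y Outcome vector.
#' @param T 0/1 treatment vector.
#' @param G Genotype matrix (individuals x SNPs), any consistent coding;
#'   standardize beforehand if standardized effects are wanted.
#' @return Tibble with one row per SNP: `variant_id`, `beta_G`, `se_G`,
#'   `z_G`, `beta_I`, `se_I`, `z_I`, `n`.
#' @export
gwis_scan <- function(Y, T, G) {
  G <- as.matrix(G)
  n <- length(Y)
  stopifnot(length(T) == n, nrow(G) == n)
  X0 <- cbind(1, T)
  H <- solve(crossprod(X0))
  proj <- function(m) m - X0 %*% (H %*% crossprod(X0, m))
  y_r <- drop(proj(matrix(Y)))
  G_r <- proj(G)
  W_r <- proj(G * T)
  a <- colSums(G_r^2)
  b <- colSums(G_r * W_r)
  cc <- colSums(W_r^2)
  gy <- drop(crossprod(G_r, y_r))
  wy <- drop(crossprod(W_r, y_r))
  det <- a * cc - b^2
  bad <- det <= .Machine$double.eps * a * cc
  det[bad] <- NA_real_
  beta_G <- (cc * gy - b * wy) / det
  beta_I <- (a * wy - b * gy) / det
  rss <- sum(y_r^2) - beta_G * gy - beta_I * wy
  sigma2 <- pmax(rss, 0) / (n - 4)
  se_G <- sqrt(sigma2 * cc / det)
  se_I <- sqrt(sigma2 * a / det)
  tibble::tibble(
    variant_id = colnames(G) %||% paste0("snp_", seq_len(ncol(G))),
    beta_G = beta_G, se_G = se_G, z_G = beta_G / se_G,
    beta_I = beta_I, se_I = se_I, z_I = beta_I / se_I,
    n = n
  )
}
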