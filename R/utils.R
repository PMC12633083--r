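# internal helpers shared across the package

#' Standardize a numeric vector to mean 0, variance 1
#'
#' Uses the sample standard deviation (denominator n - 1). A zero-variance
#' input raises an error unless `allow_constant` is set, in which case a
#' zero vector is returned.
#' @noRd
standardize <- function(x, allow_constant = FALSE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) {
    if (allow_constant) return(rep(0, length(x)))
    abort("Cannot standardize a (near-)constant vector.")
  }
  (x - mean(x)) / s
}

# column-wise standardization of a matrix (vectorized: runs on matrices
# with tens of thousands of columns)
standardize_cols <- function(m, allow_constant = FALSE) {
  m <- as.matrix(m)
  n <- nrow(m)
  mu <- colMeans(m)
  sds <- sqrt(pmax(colSums(m^2) - n * mu^2, 0) / (n - 1))
  bad <- !is.finite(sds) | sds < 1e-12
  if (any(bad)) {
    if (!allow_constant) abort("Cannot standardize a (near-)constant column.")
    sds[bad] <- Inf  # constant columns map to zero
  }
  out <- sweep(sweep(m, 2, mu, "-"), 2, sds, "/")
  out[, bad] <- 0
  out
}

# derive a stream-specific 32-bit seed from a user seed; keeps all
# randomness traceable to one integer without reusing the same stream
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  # double arithmetic keeps exact integers well past 2^31, so no overflow
  as.integer((as.numeric(seed) * 1000003 + as.numeric(stream)) %% 2147483629)
}

check_prob <- function(p, name = "p") {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort(sprintf("`%s` must lie strictly inside (0, 1).", name))
  }
  invisible(p)
}

# balanced fold sizes: n split into k parts differing by at most one,
# larger parts first
balanced_sizes <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
}

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))
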