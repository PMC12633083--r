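# shared fixture builders (all data generated in code)

`%||%` <- function(x, y) if (is.null(x)) y else x

toy_sumstats <- function(z = c(1.2, -0.4, 2.1), kind = "gwis_interaction",
                         label = "toy") {
  sumstats(tibble::tibble(
    variant_id = paste0("rs", seq_along(z)),
    allele_effect = rep(c("A", "C", "G"), length.out = length(z)),
    allele_other = rep(c("G", "T", "C"), length.out = length(z)),
    z = z, n = 5000
  ), kind = kind, trait_label = label)
}

# minimal hand-built trial: pure-noise outcome, K PRS features
toy_trial <- function(n = 60, K = 3, seed = 42, p = 0.5,
                      outcome = NULL, treatment = NULL, prs = NULL) {
  set.seed(seed)
  treatment <- treatment %||% rbinom(n, 1, p)
  outcome <- outcome %||% rnorm(n)
  prs <- prs %||% matrix(rnorm(n * K), n, K,
                         dimnames = list(NULL, paste0("prs_", seq_len(K))))
  trial_dataset(
    tibble::tibble(id = sprintf("i%03d", seq_len(n)),
                   treatment = treatment, outcome = outcome),
    prs = prs, design_p = p
  )
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
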