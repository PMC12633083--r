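#' Sequential cross-fitting of a CATE model on PRS features
#'
#' Partitions the trial into `k_folds` ordered folds (random, seeded,
#' balanced sizes), then for each fold `k = 2, ..., K` fits the learner on
#' the pseudo-outcomes of folds `1..k-1` and predicts the conditional
#' average treatment effect on fold `k`. Every prediction is therefore
#' strictly out-of-sample: an individual's own outcome never enters the
#' model that predicts it. Fold 1 receives no prediction and is excluded
#' from downstream inference.
#'
#' @param data A [trial_dataset()].
#' @param learner A [learner_spec()].
#' @param k_folds Number of ordered folds `K >= 2` (default 5).
#' @param seed Integer seed governing the fold partition and learner fits.
#' @return A `cate_estimate`: tibble with columns `id`, `fold`, `tau_hat`
#'   (`NA` for fold 1), carrying attributes `k_folds`, `learner_used`,
#'   `seed`, `propensity_used`.
#' @export
sequential_crossfit <- function(data, learner, k_folds = 5L, seed = 1L) {
  stopifnot(inherits(data, "trial_dataset"), inherits(learner, "learner_spec"))
  n <- nrow(data)
  k_folds <- as.integer(k_folds)
  if (k_folds < 2) abort("k_folds must be at least 2.")
  if (k_folds > n / 2) abort("k_folds must not exceed n / 2.")

  e <- trial_propensity(data)
  y_h <- as.numeric(pseudo_outcome(data$outcome, data$treatment, e))
  X <- prs_matrix(data)

  set.seed(derive_seed(seed, 1L))
  fold <- sample(rep(seq_len(k_folds), times = balanced_sizes(n, k_folds)))

  tau_hat <- rep(NA_real_, n)
  for (k in 2:k_folds) {
    tr <- fold < k
    te <- fold == k
    spec_k <- learner
    spec_k$seed <- derive_seed(seed, 100L + k)
    model <- tryCatch(
      fit_learner(spec_k, X[tr, , drop = FALSE], y_h[tr]),
      error = function(err) {
        abort(sprintf("Learner `%s` failed on fold %d: %s",
                      learner$name, k, conditionMessage(err)))
      }
    )
    tau_hat[te] <- model$predict(X[te, , drop = FALSE])
  }

  structure(
    tibble::tibble(id = data$id, fold = fold, tau_hat = tau_hat),
    k_folds = k_folds, learner_used = learner$name, seed = seed,
    propensity_used = e,
    class = c("cate_estimate", class(tibble::tibble()))
  )
}
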