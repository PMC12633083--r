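# Comparison baselines sharing the trial_dataset interface --------------

baseline_result <- function(method, coef, se, p, details = list()) {
  structure(
    tibble::tibble(method = method, interaction_coef = coef, se = se,
                   p_value = p),
    details = details,
    class = c("baseline_result", class(tibble::tibble()))
  )
}

# HC3 z-test for one coefficient of a fitted lm
hc3_coef_test <- function(fit, term) {
  est <- coef(fit)[term]
  if (is.na(est)) abort(sprintf("Term `%s` could not be estimated.", term))
  vc <- sandwich::vcovHC(fit, type = "HC3")
  se <- sqrt(vc[term, term])
  z <- unname(est / se)
  list(coef = unname(est), se = unname(se), z = z, p = two_sided_p(z))
}

check_condition_number <- function(X) {
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > 1e8) {
    abort("Design matrix is (near-)collinear (condition number > 1e8).")
  }
}

#' Single-PRS treatment-interaction baseline
#'
#' The conventional candidate-score analysis: ordinary least squares of
#' `Y ~ treatment + PRS + treatment:PRS` with an HC3-robust two-sided test
#' of the interaction coefficient. With the trial outcome's own PRS this
#' asks whether genetic liability to the outcome modifies treatment
#' response.
#'
#' @param data A [trial_dataset()].
#' @param prs Column index/name into the PRS feature matrix, the name of a
#'   regular dataset column (e.g. `"prs_outcome"`), or a numeric vector.
#' @return A `baseline_result` row (method `"single_prs"`).
#' @export
single_prs_interaction <- function(data, prs = 1L) {
  stopifnot(inherits(data, "trial_dataset"))
  x <- if (is.numeric(prs) && length(prs) == nrow(data)) {
    prs
  } else if (is.character(prs) && prs %in% names(data) &&
             !prs %in% attr(data, "prs_labels")) {
    data[[prs]]
  } else {
    prs_matrix(data)[, prs]
  }
  if (stats::var(x) < 1e-12) abort("The chosen PRS column is constant.")
  df <- data.frame(y = data$outcome, t = data$treatment, g = x)
  check_condition_number(stats::model.matrix(~ t * g, df))
  fit <- stats::lm(y ~ t * g, data = df)
  res <- hc3_coef_test(fit, "t:g")
  baseline_result("single_prs", res$coef, res$se, res$p,
                  details = list(n = nrow(df), coefficients = coef(fit)))
}

# seeded disjoint split helper
split_indices <- function(n, fractions, seed) {
  set.seed(derive_seed(seed, 51L))
  idx <- sample(n)
  sizes <- round(fractions * n)
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  split(idx, rep(seq_along(sizes), times = sizes))
}

#' Within-sample GWIS baseline
#'
#' Estimates the polygenic efficacy score from the trial itself: a seeded
#' split into training and test halves; per-SNP `Y ~ G + T + G:T`
#' regressions on the training half provide interaction weights; the PES
#' is scored on the test half and its interaction with treatment tested
#' there (HC3). Power is limited by the `Me / N` estimation noise of the
#' within-trial interaction scan.
#'
#' @param data A [trial_dataset()] with genotypes attached.
#' @param split_fraction Fraction assigned to training (default 0.5).
#' @param seed Integer seed for the split.
#' @return A `baseline_result` row (method `"within_gwis"`).
#' @export
within_gwis_pes <- function(data, split_fraction = 0.5, seed = 1L) {
  gm <- attr(data, "genotypes")
  if (is.null(gm)) abort("within_gwis_pes requires genotypes in the dataset.")
  G <- std_dosages(gm)
  n <- nrow(data)
  parts <- split_indices(n, c(split_fraction, 1 - split_fraction), seed)
  train <- parts[[1]]; test <- parts[[2]]
  for (part in list(train, test)) {
    if (length(unique(data$treatment[part])) < 2) {
      abort("A split half contains only one treatment arm.")
    }
  }
  scan <- gwis_scan(data$outcome[train], data$treatment[train],
                    G[train, , drop = FALSE])
  pes <- drop(G[test, , drop = FALSE] %*% ifelse(is.na(scan$beta_I), 0,
                                                 scan$beta_I))
  if (stats::var(pes) < 1e-12) abort("Estimated PES is degenerate on the test half.")
  df <- data.frame(y = data$outcome[test], t = data$treatment[test],
                   s = standardize(pes))
  fit <- stats::lm(y ~ t * s, data = df)
  res <- hc3_coef_test(fit, "t:s")
  baseline_result("within_gwis", res$coef, res$se, res$p,
                  details = list(n_train = length(train), n_test = length(test),
                                 seed = seed))
}

#' Two-score pharmacogenomic regression baseline
#'
#' Builds a prognostic score (genotypes weighted by per-SNP main effects)
#' and a predictive score (weighted by per-SNP interaction effects) from a
#' within-trial interaction scan on a training split, tunes a small grid
#' of top-|z| inclusion proportions for each weight vector on a holdout
#' split (objective: R-squared of the two-score model for the outcome),
#' and tests the treatment-by-predictive-score coefficient in
#' `Y ~ T + prog + T:pred` on the disjoint test split (HC3).
#'
#' @param data A [trial_dataset()] with genotypes attached.
#' @param split_fraction Fraction of the sample used for training plus
#'   holdout (default 0.5); the remainder is the test split.
#' @param holdout_fraction Fraction of the training half held out for
#'   tuning (default 0.25).
#' @param keep_grid Candidate top-|z| proportions for each score.
#' @param seed Integer seed for the splits.
#' @return A `baseline_result` row (method `"prspgx"`).
#' @export
prspgx <- function(data, split_fraction = 0.5, holdout_fraction = 0.25,
                   keep_grid = c(1, 0.5, 0.2), seed = 1L) {
  gm <- attr(data, "genotypes")
  if (is.null(gm)) abort("prspgx requires genotypes in the dataset.")
  G <- std_dosages(gm)
  n <- nrow(data)
  half <- split_fraction
  parts <- split_indices(
    n, c(half * (1 - holdout_fraction), half * holdout_fraction, 1 - half),
    seed)
  train <- parts[[1]]; holdout <- parts[[2]]; test <- parts[[3]]

  scan <- gwis_scan(data$outcome[train], data$treatment[train],
                    G[train, , drop = FALSE])
  w_G <- ifelse(is.na(scan$beta_G), 0, scan$beta_G)
  w_I <- ifelse(is.na(scan$beta_I), 0, scan$beta_I)
  z_G <- abs(ifelse(is.na(scan$z_G), 0, scan$z_G))
  z_I <- abs(ifelse(is.na(scan$z_I), 0, scan$z_I))

  threshold <- function(w, z, keep) {
    if (keep >= 1) return(w)
    cut <- stats::quantile(z, 1 - keep)
    ifelse(z >= cut, w, 0)
  }
  build <- function(idx, kg, ki) {
    list(prog = drop(G[idx, , drop = FALSE] %*% threshold(w_G, z_G, kg)),
         pred = drop(G[idx, , drop = FALSE] %*% threshold(w_I, z_I, ki)))
  }
  combos <- expand.grid(kg = keep_grid, ki = keep_grid)
  r2 <- vapply(seq_len(nrow(combos)), function(i) {
    sc <- build(holdout, combos$kg[i], combos$ki[i])
    if (stats::var(sc$prog) < 1e-12 || stats::var(sc$pred) < 1e-12) return(-Inf)
    df <- data.frame(y = data$outcome[holdout], t = data$treatment[holdout],
                     prog = sc$prog, pred = sc$pred)
    summary(stats::lm(y ~ t + prog + t:pred, data = df))$r.squared
  }, numeric(1))
  best <- which.max(r2)

  sc <- build(test, combos$kg[best], combos$ki[best])
  if (stats::var(sc$prog) < 1e-12 || stats::var(sc$pred) < 1e-12) {
    abort("Degenerate (zero-variance) score on the test split.")
  }
  df <- data.frame(y = data$outcome[test], t = data$treatment[test],
                   prog = standardize(sc$prog), pred = standardize(sc$pred))
  fit <- stats::lm(y ~ t + prog + t:pred, data = df)
  res <- hc3_coef_test(fit, "t:pred")
  baseline_result("prspgx", res$coef, res$se, res$p,
                  details = list(n_train = length(train),
                                 n_holdout = length(holdout),
                                 n_test = length(test),
                                 keep_prog = combos$kg[best],
                                 keep_pred = combos$ki[best], seed = seed))
}

#' SNP-feature CATE pipeline baseline
#'
#' Runs the identical individual-level pipeline as [run_mlearner_i()] but
#' with standardized SNP dosages as features instead of the PRS panel,
#' i.e. no transfer learning from external GWAS.
#'
#' @param data A [trial_dataset()] with genotypes attached.
#' @param learner A [learner_spec()].
#' @param k_folds,q,seed As in [run_mlearner_i()].
#' @return An `hte_report` (its `p_combined` is the method's p-value).
#' @export
mlearner_snp <- function(data, learner = learner_spec("penalized_linear"),
                         k_folds = 5L, q = 4L, seed = 1L) {
  gm <- attr(data, "genotypes")
  if (is.null(gm)) abort("mlearner_snp requires genotypes in the dataset.")
  df <- tibble::tibble(id = data$id, treatment = data$treatment,
                       outcome = data$outcome)
  snp_data <- trial_dataset(df, prs = gm$dosages,
                            design_p = attr(data, "design_p"),
                            prs_labels = gm$variant_ids)
  run_mlearner_i(snp_data, learner, k_folds = k_folds, q = q, seed = seed)
}
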