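#' Assemble a randomized-trial dataset with PRS features
#'
#' Bundles outcomes, binary treatment, the design randomization probability
#' and an individuals-by-PRS feature matrix into the tabular container the
#' individual-level pipeline consumes. PRS columns are standardized to mean
#' 0, variance 1 within the analysis sample.
#'
#' @param data Data frame with columns `id`, `treatment` (0/1) and `outcome`
#'   (plus any extra covariate columns, which are carried along untouched).
#' @param prs Numeric matrix or data frame of PRS features, one row per
#'   individual, or a character vector naming PRS columns already in `data`.
#' @param design_p Design probability of assignment to treatment, strictly
#'   inside (0, 1). Defaults to the empirical treated fraction (with a
#'   message), since in a randomized trial the propensity is known.
#' @param prs_labels Optional labels for the PRS columns.
#' @param genotypes Optional [genotype_matrix()] for SNP-level baselines.
#' @param standardize_prs Standardize PRS columns (default `TRUE`).
#' @return A `trial_dataset`: a tibble with columns `id`, `treatment`,
#'   `outcome` and one standardized column per PRS, carrying `design_p`,
#'   `prs_labels`, `genotypes` and (for simulated data) `truth` attributes.
#' @export
trial_dataset <- function(data, prs, design_p = NULL, prs_labels = NULL,
                          genotypes = NULL, standardize_prs = TRUE) {
  data <- tibble::as_tibble(data)
  required <- c("id", "treatment", "outcome")
  if (!all(required %in% names(data))) {
    abort("`data` must contain columns id, treatment and outcome.")
  }
  if (!all(data$treatment %in% c(0, 1))) {
    abort("`treatment` must be coded 0/1.")
  }
  if (any(!is.finite(data$outcome))) abort("`outcome` must be finite.")
  if (is.character(prs)) {
    prs_mat <- as.matrix(data[, prs, drop = FALSE])
    data <- data[, setdiff(names(data), prs), drop = FALSE]
  } else {
    prs_mat <- as.matrix(prs)
  }
  if (nrow(prs_mat) != nrow(data)) {
    abort("PRS matrix must have one row per individual.")
  }
  if (is.null(prs_labels)) {
    prs_labels <- colnames(prs_mat) %||% paste0("prs_", seq_len(ncol(prs_mat)))
  }
  if (is.null(design_p)) {
    design_p <- mean(data$treatment)
    message(sprintf(
      "design_p not supplied; using the empirical treated fraction %.4f.",
      design_p))
  }
  check_prob(design_p, "design_p")
  if (standardize_prs) prs_mat <- standardize_cols(prs_mat, allow_constant = TRUE)
  colnames(prs_mat) <- prs_labels
  out <- dplyr::bind_cols(data, tibble::as_tibble(prs_mat))
  structure(out,
    design_p = design_p, prs_labels = prs_labels,
    genotypes = genotypes, truth = attr(data, "truth"),
    class = c("trial_dataset", class(tibble::tibble())))
}

# accessors ------------------------------------------------------------

#' Extract the PRS feature matrix from a trial dataset
#' @param data A `trial_dataset`.
#' @return Numeric matrix (individuals x PRS).
#' @export
prs_matrix <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  as.matrix(tibble::as_tibble(data)[, attr(data, "prs_labels"), drop = FALSE])
}

#' Propensity used for a trial dataset
#'
#' Returns the design randomization probability when recorded, otherwise
#' the empirical treated fraction.
#' @param data A `trial_dataset`.
#' @return Scalar in (0, 1).
#' @export
trial_propensity <- function(data) {
  attr(data, "design_p") %||% mean(data$treatment)
}

#' Standardize a binary treatment indicator
#'
#' Maps treatment 1 to `sqrt((1 - p) / p)` and 0 to `-sqrt(p / (1 - p))`,
#' the coding under which the polygenic gene-by-treatment model's
#' interaction column is orthogonal to the genotype main effect and the
#' indicator has mean 0 and variance 1 when the treated fraction equals `p`.
#'
#' @param treatment 0/1 vector.
#' @param p Treatment probability in (0, 1).
#' @return Numeric vector of standardized treatment codes.
#' @export
standardize_treatment <- function(treatment, p) {
  check_prob(p, "p")
  if (!all(treatment %in% c(0, 1))) abort("`treatment` must be coded 0/1.")
  ifelse(treatment == 1, sqrt((1 - p) / p), -sqrt(p / (1 - p)))
}
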