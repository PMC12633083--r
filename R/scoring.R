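#' Construct a genotype dosage matrix
#'
#' Dosages are coded 0-2 copies of a designated allele per variant, with
#' individuals in rows and variants in columns. Residual missing entries are
#' mean-imputed per variant (a deterministic rule; variants with high
#' missingness should already have been removed by QC).
#'
#' @param dosages Numeric matrix (individuals x variants), entries in
#'   \[0, 2\] or NA.
#' @param variant_ids Character vector of variant ids (one per column).
#' @param effect_alleles Optional character vector naming the allele counted
#'   by each column's dosage.
#' @param mafs Optional per-variant minor allele frequencies in (0, 0.5\].
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, variant_ids,
                            effect_alleles = NULL, mafs = NULL) {
  dosages <- as.matrix(dosages)
  if (length(variant_ids) != ncol(dosages)) {
    abort("`variant_ids` must have one entry per dosage column.")
  }
  if (anyDuplicated(variant_ids)) abort("variant_ids must be unique.")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) abort("Dosages must lie in [0, 2].")
  n_imputed <- 0L
  if (anyNA(dosages)) {
    for (j in seq_len(ncol(dosages))) {
      miss <- is.na(dosages[, j])
      if (any(miss)) {
        if (all(miss)) abort(sprintf("Variant %s has no observed dosages.",
                                     variant_ids[j]))
        dosages[miss, j] <- mean(dosages[!miss, j])
        n_imputed <- n_imputed + sum(miss)
      }
    }
    message(sprintf("Mean-imputed %d missing dosage entries.", n_imputed))
  }
  if (!is.null(mafs) && (length(mafs) != ncol(dosages) ||
                         any(mafs <= 0 | mafs > 0.5))) {
    abort("`mafs` must be per-variant values in (0, 0.5].")
  }
  colnames(dosages) <- variant_ids
  structure(
    list(dosages = dosages, variant_ids = as.character(variant_ids),
         effect_alleles = effect_alleles, mafs = mafs,
         n_imputed = n_imputed, cache = new.env(parent = emptyenv())),
    class = "genotype_matrix"
  )
}

# column-standardized dosages, computed once per matrix (large genotype
# matrices are standardized repeatedly across the pipeline otherwise)
std_dosages <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$cache$std)) {
    gm$cache$std <- standardize_cols(gm$dosages, allow_constant = TRUE)
  }
  gm$cache$std
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Read a PRS scoring file
#'
#' Parses PGS-Catalog-style scoring files: delimited text with a header,
#' lines starting with `#` ignored, columns for the variant id
#' (`rsID`/`variant_id`/`SNP`), `effect_allele` (or `A1`) and
#' `effect_weight` (or `weight`/`beta`).
#'
#' @param path Path to the scoring file.
#' @return A tibble with columns `variant_id`, `effect_allele`, `weight`.
#' @export
read_scoring_file <- function(path) {
  raw <- readr::read_table(path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) == 1) {
    raw <- readr::read_delim(path, delim = "\t", comment = "#",
                             show_col_types = FALSE,
                             col_types = readr::cols(.default = readr::col_character()))
  }
  aliases <- c(rsid = "variant_id", snp = "variant_id", id = "variant_id",
               variant_id = "variant_id",
               effect_allele = "effect_allele", a1 = "effect_allele",
               effect_weight = "weight", weight = "weight", beta = "weight")
  lowered <- tolower(names(raw))
  mapped <- unname(aliases[lowered])
  keep <- !is.na(mapped)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- mapped[keep]
  needed <- c("variant_id", "effect_allele", "weight")
  if (!all(needed %in% names(raw))) {
    abort("Scoring file must provide variant id, effect allele and effect weight columns.")
  }
  raw$weight <- as.numeric(raw$weight)
  raw$effect_allele <- toupper(raw$effect_allele)
  if (any(!is.finite(raw$weight))) abort("Scoring weights must be finite.")
  if (anyDuplicated(raw$variant_id)) abort("Scoring file variant ids must be unique.")
  tibble::as_tibble(raw[, needed])
}

#' Compute a polygenic score from dosages and a scoring file
#'
#' For each individual, sums dosage times weight over the scoring variants
#' present in the genotype matrix. When the genotype matrix records which
#' allele its dosages count, weights are sign-flipped for variants whose
#' scoring effect allele is the opposite allele. Optionally standardizes the
#' result to mean 0, variance 1 in the analysis sample (the within-trial
#' convention used by the individual-level pipeline).
#'
#' @param genotypes A `genotype_matrix`.
#' @param scoring A scoring tibble from [read_scoring_file()] (columns
#'   `variant_id`, `effect_allele`, `weight`).
#' @param standardize Standardize the score (default `FALSE`).
#' @return Numeric vector of length `nrow(genotypes)`; attribute
#'   `n_matched` carries the number of scoring variants used.
#' @export
score_prs <- function(genotypes, scoring, standardize = FALSE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  scoring <- tibble::as_tibble(scoring)
  idx <- match(scoring$variant_id, genotypes$variant_ids)
  matched <- !is.na(idx)
  if (!any(matched)) {
    abort(sprintf(
      "No scoring variants found in the genotype matrix (0 of %d matched).",
      nrow(scoring)))
  }
  sc <- scoring[matched, , drop = FALSE]
  cols <- idx[matched]
  w <- sc$weight
  if (!is.null(genotypes$effect_alleles)) {
    geno_ea <- genotypes$effect_alleles[cols]
    flip <- !is.na(geno_ea) & geno_ea != sc$effect_allele
    w[flip] <- -w[flip]
  }
  score <- as.numeric(genotypes$dosages[, cols, drop = FALSE] %*% w)
  if (standardize) score <- standardize(score)
  attr(score, "n_matched") <- sum(matched)
  score
}

#' Read a genotype dosage matrix from delimited text or VCF
#'
#' The delimited format expects a header of variant ids, a first column of
#' individual ids, and one dosage column per variant. VCF reading (behind
#' `format = "vcf"`, requires the vcfR package) uses the DS field when
#' present and otherwise counts alternate alleles from GT.
#'
#' @param path Input path.
#' @param format `"delim"` (default) or `"vcf"`.
#' @return A `genotype_matrix`; individual ids are kept as row names.
#' @export
read_dosages <- function(path, format = c("delim", "vcf")) {
  format <- match.arg(format)
  if (format == "delim") {
    raw <- readr::read_table(path, show_col_types = FALSE)
    ids <- as.character(raw[[1]])
    m <- as.matrix(raw[, -1, drop = FALSE])
    gm <- genotype_matrix(m, variant_ids = colnames(m))
    rownames(gm$dosages) <- ids
    return(gm)
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF reading requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(v)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(strsplit(gsub("\\|", "/", col), "/"), function(a) {
        sum(suppressWarnings(as.numeric(a)) > 0)
      }, numeric(1))
    })
  }
  m <- t(ds)  # vcfR is variants x samples
  gm <- genotype_matrix(m, variant_ids = ids,
                        effect_alleles = vcfR::getALT(v))
  gm
}
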