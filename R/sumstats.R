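#' Column aliases recognised in summary-statistic files
#'
#' Delimited GWAS/GWIS exports name the same columns differently across
#' tools. This table maps common aliases onto the canonical names used
#' throughout the package. Matching is case-insensitive.
#'
#' @return A named character vector: names are lower-case aliases, values the
#'   canonical column names.
#' @export
sumstats_aliases <- function() {
  c(
    snp = "variant_id", id = "variant_id", rsid = "variant_id",
    variant_id = "variant_id", marker = "variant_id", markername = "variant_id",
    a1 = "allele_effect", allele1 = "allele_effect", ea = "allele_effect",
    effect_allele = "allele_effect", allele_effect = "allele_effect",
    a2 = "allele_other", allele2 = "allele_other", oa = "allele_other",
    other_allele = "allele_other", allele_other = "allele_other",
    ref = "allele_other",
    z = "z", zscore = "z", z_score = "z", stat = "z",
    beta = "beta", b = "beta", effect = "beta",
    se = "se", stderr = "se", standard_error = "se",
    n = "n", nobs = "n", sample_size = "n",
    maf = "maf", eaf = "maf", freq = "maf",
    info = "info", imputation_quality = "info", r2 = "info",
    missing_rate = "missing_rate", f_miss = "missing_rate",
    hwe_p = "hwe_p", p_hwe = "hwe_p", hwe = "hwe_p"
  )
}

valid_alleles <- c("A", "C", "G", "T")

new_sumstats <- function(records, kind, trait_label) {
  structure(records,
    kind = kind, trait_label = trait_label,
    class = c("sumstats", class(tibble::tibble())))
}

#' Construct a summary-statistics object from a data frame
#'
#' Validates per-variant association records (alleles, z or beta/se
#' consistency, unique variant ids) and attaches the record kind
#' (`gwis_interaction` for SNP-by-treatment interaction z-scores,
#' `gwas_marginal` for ordinary GWAS z-scores).
#'
#' @param records Data frame with columns `variant_id`, `allele_effect`,
#'   `allele_other`, `z` (or `beta` and `se`), `n`, and optionally `maf`,
#'   `info`, `missing_rate`, `hwe_p`.
#' @param kind `"gwis_interaction"` or `"gwas_marginal"`.
#' @param trait_label Label for the trait the statistics refer to.
#' @return A `sumstats` tibble (one row per variant).
#' @export
sumstats <- function(records, kind = c("gwis_interaction", "gwas_marginal"),
                     trait_label = "trait") {
  kind <- match.arg(kind)
  records <- tibble::as_tibble(records)
  required <- c("variant_id", "allele_effect", "allele_other", "n")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"z" %in% names(records)) {
    if (!all(c("beta", "se") %in% names(records))) {
      abort("Need either a `z` column or both `beta` and `se`.")
    }
    records$z <- records$beta / records$se
  }
  bad_allele <- !(records$allele_effect %in% valid_alleles) |
    !(records$allele_other %in% valid_alleles)
  if (any(bad_allele)) {
    abort(sprintf("Invalid allele code on row(s): %s (alleles must be one of A/C/G/T)",
                  paste(which(bad_allele), collapse = ", ")))
  }
  if (any(records$allele_effect == records$allele_other)) {
    abort("Effect and other allele must differ.")
  }
  if (anyDuplicated(records$variant_id)) {
    abort("Duplicated variant_id values are not allowed within one sumstats object.")
  }
  if (any(!is.finite(records$z))) {
    abort(sprintf("Non-finite z on row(s): %s",
                  paste(which(!is.finite(records$z)), collapse = ", ")))
  }
  if (all(c("beta", "se") %in% names(records))) {
    ok <- is.na(records$beta) | is.na(records$se) |
      abs(records$z - records$beta / records$se) < 1e-8
    if (!all(ok)) abort("z inconsistent with beta/se (|z - beta/se| >= 1e-8).")
  }
  if ("maf" %in% names(records) && any(records$maf > 0.5, na.rm = TRUE)) {
    abort("maf must not exceed 0.5 (code the minor allele frequency).")
  }
  canonical <- c("variant_id", "allele_effect", "allele_other", "z", "n",
                 "beta", "se", "maf", "info", "missing_rate", "hwe_p")
  records <- records[, intersect(canonical, names(records))]
  new_sumstats(records, kind, trait_label)
}

#' Read summary statistics from delimited text
#'
#' Reads tab- or whitespace-separated files with a header row. Column names
#' are resolved through [sumstats_aliases()] (case-insensitive), so e.g.
#' `SNP,A1,A2,Z,N` and `variant_id,effect_allele,other_allele,beta,se,n`
#' both parse. When no `z` column is present it is derived as `beta / se`.
#' Row order is preserved.
#'
#' @param path Path to the file.
#' @param kind `"gwis_interaction"` or `"gwas_marginal"`.
#' @param trait_label Trait label; defaults to the file name.
#' @return A `sumstats` tibble.
#' @export
read_sumstats <- function(path, kind = c("gwis_interaction", "gwas_marginal"),
                          trait_label = NULL) {
  kind <- match.arg(kind)
  trait_label <- trait_label %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_table(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) == 1) {
    raw <- readr::read_delim(path, delim = "\t", show_col_types = FALSE,
                             col_types = readr::cols(.default = readr::col_character()))
  }
  aliases <- sumstats_aliases()
  lowered <- tolower(names(raw))
  mapped <- unname(aliases[lowered])
  keep <- !is.na(mapped)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- mapped[keep]
  raw <- raw[, !duplicated(names(raw)), drop = FALSE]
  for (col in intersect(c("z", "beta", "se", "n", "maf", "info",
                          "missing_rate", "hwe_p"), names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value in column `%s` on data line(s): %s",
                    col, paste(bad, collapse = ", ")))
    }
    raw[[col]] <- parsed
  }
  for (col in intersect(c("allele_effect", "allele_other"), names(raw))) {
    raw[[col]] <- toupper(raw[[col]])
  }
  sumstats(raw, kind = kind, trait_label = trait_label)
}

#' Write summary statistics to delimited text
#'
#' Writes a tab-separated file with canonical column names that
#' [read_sumstats()] parses back bit-exactly (full double precision).
#'
#' @param x A `sumstats` object.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  out <- tibble::as_tibble(x)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  readr::write_tsv(out, path)
  invisible(x)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize two sets of summary statistics onto shared variants
#'
#' Joins two summary-statistic sets on `variant_id` and aligns the second
#' (`other`) to the first (`reference`): when the effect/other alleles are
#' swapped relative to the reference, the sign of `other`'s z-score is
#' flipped; strand-ambiguous palindromic variants (A/T, C/G) are dropped by
#' default; variants whose alleles neither match nor swap are dropped.
#'
#' @param reference,other `sumstats` objects.
#' @param drop_palindromic Drop A/T and C/G variants (default `TRUE`).
#' @return A tibble with one row per harmonized variant: `variant_id`,
#'   `allele_effect`, `allele_other`, `z_ref`, `n_ref`, `z_other`, `n_other`,
#'   `flipped`. Attributes `n_dropped_palindromic` and `n_dropped_mismatch`
#'   carry drop counts.
#' @export
harmonize_variants <- function(reference, other, drop_palindromic = TRUE) {
  stopifnot(inherits(reference, "sumstats"), inherits(other, "sumstats"))
  ref <- tibble::as_tibble(reference)[, c("variant_id", "allele_effect",
                                          "allele_other", "z", "n")]
  oth <- tibble::as_tibble(other)[, c("variant_id", "allele_effect",
                                      "allele_other", "z", "n")]
  names(ref)[2:5] <- c("allele_effect", "allele_other", "z_ref", "n_ref")
  names(oth) <- c("variant_id", "ea_other", "oa_other", "z_other", "n_other")
  joined <- dplyr::inner_join(ref, oth, by = "variant_id")
  if (nrow(joined) == 0) abort("No shared variants between the two inputs.")

  pal <- is_palindromic(joined$allele_effect, joined$allele_other)
  n_pal <- 0L
  if (drop_palindromic) {
    n_pal <- sum(pal)
    joined <- joined[!pal, , drop = FALSE]
  }
  same <- joined$ea_other == joined$allele_effect &
    joined$oa_other == joined$allele_other
  swapped <- joined$ea_other == joined$allele_other &
    joined$oa_other == joined$allele_effect
  n_mismatch <- sum(!same & !swapped)
  keep <- same | swapped
  joined <- joined[keep, , drop = FALSE]
  flipped <- swapped[keep]
  joined$z_other <- ifelse(flipped, -joined$z_other, joined$z_other)
  if (nrow(joined) == 0) abort("No harmonizable variants remain after allele checks.")
  out <- joined[, c("variant_id", "allele_effect", "allele_other",
                    "z_ref", "n_ref", "z_other", "n_other")]
  out$flipped <- flipped
  attr(out, "n_dropped_palindromic") <- n_pal
  attr(out, "n_dropped_mismatch") <- n_mismatch
  out
}

#' Filter variants on standard GWAS quality-control thresholds
#'
#' Keeps records with imputation quality `info > info_min`, minor allele
#' frequency `maf >= maf_min`, missing call rate `missing_rate <=
#' missing_max`, and Hardy-Weinberg p-value `hwe_p >= hwe_p_min`. A record
#' lacking one of these fields fails that filter unless `permissive = TRUE`,
#' in which case the missing field is exempt.
#'
#' @param records A `sumstats` object or variant data frame.
#' @param info_min,maf_min,missing_max,hwe_p_min QC thresholds.
#' @param permissive Exempt records from filters whose field is absent/NA.
#' @return The filtered records, with an attribute `qc_counts` (named integer
#'   vector: input, kept, and per-filter drop counts).
#' @export
qc_filter_variants <- function(records, info_min = 0.9, maf_min = 0.05,
                               missing_max = 0.01, hwe_p_min = 1e-6,
                               permissive = FALSE) {
  stopifnot(info_min >= 0, info_min <= 1, maf_min >= 0, maf_min <= 0.5,
            missing_max >= 0, missing_max <= 1, hwe_p_min >= 0, hwe_p_min <= 1)
  df <- tibble::as_tibble(records)
  n_in <- nrow(df)
  field_pass <- function(field, test) {
    if (!field %in% names(df)) {
      return(rep(permissive, n_in))
    }
    v <- df[[field]]
    ifelse(is.na(v), permissive, test(v))
  }
  pass_info <- field_pass("info", function(v) v > info_min)
  pass_maf <- field_pass("maf", function(v) v >= maf_min)
  pass_miss <- field_pass("missing_rate", function(v) v <= missing_max)
  pass_hwe <- field_pass("hwe_p", function(v) v >= hwe_p_min)
  keep <- pass_info & pass_maf & pass_miss & pass_hwe
  out <- records[keep, , drop = FALSE]
  attr(out, "qc_counts") <- c(
    n_input = n_in, n_kept = sum(keep),
    n_fail_info = sum(!pass_info), n_fail_maf = sum(!pass_maf),
    n_fail_missing = sum(!pass_miss), n_fail_hwe = sum(!pass_hwe)
  )
  out
}
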