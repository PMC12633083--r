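test_that("delimited summary statistics parse with alias resolution", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "SNP A1 A2 Z N",
    "rs1 A G 1.20 5000",
    "rs2 C T -0.40 5000",
    "rs3 G C 2.10 5000"
  ), path)
  ss <- read_sumstats(path, kind = "gwis_interaction")
  expect_s3_class(ss, "sumstats")
  expect_equal(nrow(ss), 3)
  expect_equal(ss$z, c(1.2, -0.4, 2.1))
  expect_equal(ss$variant_id, paste0("rs", 1:3))  # row order preserved
})

test_that("z is derived as beta/se when absent", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP A1 A2 BETA SE N", "rs1 A G 0.2 0.1 1000"), path)
  ss <- read_sumstats(path, kind = "gwas_marginal")
  expect_equal(ss$z, 2.0)
})

test_that("malformed inputs raise informative errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP A1 A2 Z N", "rs1 AT G 1.0 100"), path)
  expect_error(read_sumstats(path), "allele")

  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP A1 A2 Z N", "rs1 A G xx 100"), path2)
  expect_error(read_sumstats(path2), "line")

  path3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP A1 Z N", "rs1 A 1.0 100"), path3)
  expect_error(read_sumstats(path3), "column")

  expect_error(
    sumstats(tibble::tibble(variant_id = c("rs1", "rs1"),
                            allele_effect = "A", allele_other = "G",
                            z = 1, n = 10)),
    "Duplicated")
})

test_that("write/read round-trip is bit-exact", {
  ss <- toy_sumstats(z = c(1.234567890123456, -2e-7, 0.1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, path)
  back <- read_sumstats(path, kind = "gwis_interaction")
  expect_identical(back$z, ss$z)
  expect_identical(back$n, ss$n)
  expect_identical(back$variant_id, ss$variant_id)
  expect_identical(back$allele_effect, ss$allele_effect)
})

test_that("harmonization matches, flips, and drops correctly", {
  ref <- sumstats(tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    allele_effect = c("A", "C", "A"), allele_other = c("G", "T", "T"),
    z = c(1, 2, 3), n = 100), kind = "gwis_interaction")
  # rs1 identical, rs2 swapped alleles, rs3 palindromic (A/T)
  oth <- sumstats(tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    allele_effect = c("A", "T", "A"), allele_other = c("G", "C", "T"),
    z = c(0.5, 1.5, 9), n = 200), kind = "gwas_marginal")
  h <- harmonize_variants(ref, oth)
  expect_equal(nrow(h), 2)
  expect_equal(h$z_other[h$variant_id == "rs1"], 0.5)   # unchanged
  expect_equal(h$z_other[h$variant_id == "rs2"], -1.5)  # sign flipped
  expect_equal(attr(h, "n_dropped_palindromic"), 1)

  # allele mismatch (neither match nor swap) dropped with a count
  oth2 <- sumstats(tibble::tibble(
    variant_id = c("rs1", "rs2"), allele_effect = c("C", "C"),
    allele_other = c("G", "T"), z = c(1, 1), n = 50),
    kind = "gwas_marginal")
  h2 <- harmonize_variants(ref, oth2)
  expect_equal(attr(h2, "n_dropped_mismatch"), 1)
  expect_equal(h2$variant_id, "rs2")

  far <- sumstats(tibble::tibble(variant_id = "zz9", allele_effect = "A",
                                 allele_other = "G", z = 1, n = 10),
                  kind = "gwas_marginal")
  expect_error(harmonize_variants(ref, far), "shared")
})

test_that("harmonization is idempotent", {
  ref <- toy_sumstats(z = c(1, -2, 3))
  oth <- sumstats(tibble::tibble(
    variant_id = paste0("rs", 1:3),
    allele_effect = c("G", "C", "C"),  # rs1 swapped, rs2 same, rs3 swapped
    allele_other = c("A", "T", "G"),
    z = c(0.7, -0.2, 1.1), n = 100), kind = "gwas_marginal")
  h1 <- harmonize_variants(ref, oth)
  # rebuild the aligned other and harmonize again: nothing changes
  oth_aligned <- sumstats(tibble::tibble(
    variant_id = h1$variant_id, allele_effect = h1$allele_effect,
    allele_other = h1$allele_other, z = h1$z_other, n = h1$n_other),
    kind = "gwas_marginal")
  h2 <- harmonize_variants(ref, oth_aligned)
  expect_equal(h2$z_other, h1$z_other)
  expect_false(any(h2$flipped))
})

test_that("QC filter applies the four thresholds", {
  rec <- tibble::tibble(
    variant_id = paste0("rs", 1:5),
    allele_effect = "A", allele_other = "G", z = 0, n = 100,
    info = c(0.95, 0.85, 0.99, 0.99, 0.99),
    maf = c(0.20, 0.20, 0.01, 0.30, 0.30),
    missing_rate = c(0.000, 0.000, 0.000, 0.050, 0.000),
    hwe_p = c(0.5, 0.5, 0.5, 0.5, 1e-8)
  )
  # rs1 passes; rs2 fails info; rs3 fails maf; rs4 fails missing; rs5 fails hwe
  ss <- sumstats(rec, kind = "gwas_marginal")
  out <- qc_filter_variants(ss)
  expect_equal(out$variant_id, "rs1")
  counts <- attr(out, "qc_counts")
  expect_equal(unname(counts["n_kept"]), 1)
  expect_equal(unname(counts["n_fail_info"]), 1)

  # 5-record list with exactly 2 single-filter violations -> 3 survivors
  rec2 <- rec[c(1, 1, 1, 2, 3), ]
  rec2$variant_id <- paste0("v", 1:5)
  out2 <- qc_filter_variants(sumstats(rec2, kind = "gwas_marginal"))
  expect_equal(nrow(out2), 3)
})

test_that("records lacking a QC field are dropped unless permissive", {
  rec <- tibble::tibble(variant_id = "rs1", allele_effect = "A",
                        allele_other = "G", z = 0, n = 100, maf = 0.3)
  ss <- sumstats(rec, kind = "gwas_marginal")
  expect_equal(nrow(qc_filter_variants(ss)), 0)
  expect_equal(nrow(qc_filter_variants(ss, permissive = TRUE)), 1)
})
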