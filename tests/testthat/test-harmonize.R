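rec <- function(snp = "rs1", ea, oa, beta = 0.1, se = 0.01, eaf = NA,
                p = 1e-9) {
  data.frame(SNP = snp, EA = ea, OA = oa, EAF = eaf, BETA = beta, SE = se,
             P = p, stringsAsFactors = FALSE)
}

test_that("allele complementation and palindrome detection", {
  expect_identical(complement_alleles(c("A", "AG")), c("T", "TC"))
  expect_error(complement_alleles("N"), "A/C/G/T")
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
  expect_identical(is_palindromic(c("A", "G"), c("T", "C")), c(TRUE, TRUE))
})

test_that("harmonize_pair resolves swaps, strand flips and palindromes", {
  # swapped alleles: outcome beta is negated
  h <- harmonize_pair(rec(ea = "A", oa = "G", beta = 0.10),
                      rec(ea = "G", oa = "A", beta = -0.05))
  expect_identical(h$STATUS, "allele_flipped")
  expect_equal(h$BETA_OUT, 0.05)

  # strand flip, complemented effect allele aligns: sign preserved
  h <- harmonize_pair(rec(ea = "C", oa = "T", beta = 0.10),
                      rec(ea = "G", oa = "A", beta = 0.03))
  expect_identical(h$STATUS, "strand_flipped")
  expect_equal(h$BETA_OUT, 0.03)

  # strand flip plus swap: sign flipped
  h <- harmonize_pair(rec(ea = "C", oa = "T", beta = 0.10),
                      rec(ea = "A", oa = "G", beta = 0.03))
  expect_identical(h$STATUS, "strand_flipped")
  expect_equal(h$BETA_OUT, -0.03)

  # exact match is a no-op (idempotence), and SEs are never altered
  h <- harmonize_pair(rec(ea = "A", oa = "G", beta = 0.1, se = 0.013),
                      rec(ea = "A", oa = "G", beta = 0.2, se = 0.021))
  expect_identical(h$STATUS, "kept")
  expect_equal(h[, c("BETA_EXP", "SE_EXP", "BETA_OUT", "SE_OUT")],
               data.frame(BETA_EXP = 0.1, SE_EXP = 0.013, BETA_OUT = 0.2,
                          SE_OUT = 0.021))

  # ambiguous palindrome near eaf 0.5 is dropped
  h <- harmonize_pair(rec(ea = "A", oa = "T", eaf = 0.50),
                      rec(ea = "A", oa = "T", beta = 0.2, eaf = 0.50),
                      palindromic_eaf_window = 0.08)
  expect_identical(h$STATUS, "dropped_palindromic")
  expect_true(is.na(h$BETA_OUT))

  # palindrome with informative, agreeing frequencies is kept
  h <- harmonize_pair(rec(ea = "A", oa = "T", eaf = 0.20),
                      rec(ea = "A", oa = "T", beta = 0.2, eaf = 0.23))
  expect_identical(h$STATUS, "kept")
  expect_equal(h$BETA_OUT, 0.2)

  # palindrome with disagreeing frequencies: hidden strand flip, sign flips
  h <- harmonize_pair(rec(ea = "A", oa = "T", eaf = 0.20),
                      rec(ea = "A", oa = "T", beta = 0.2, eaf = 0.80))
  expect_identical(h$STATUS, "strand_flipped")
  expect_equal(h$BETA_OUT, -0.2)

  # palindrome with a missing frequency cannot be oriented
  h <- harmonize_pair(rec(ea = "A", oa = "T", eaf = 0.20),
                      rec(ea = "A", oa = "T", beta = 0.2, eaf = NA))
  expect_identical(h$STATUS, "dropped_palindromic")

  # irreconcilable or non-SNP alleles are incompatible
  expect_identical(harmonize_pair(rec(ea = "A", oa = "G"),
                                  rec(ea = "A", oa = "C"))$STATUS,
                   "dropped_incompatible")
  expect_identical(harmonize_pair(rec(ea = "AT", oa = "A"),
                                  rec(ea = "AT", oa = "A"))$STATUS,
                   "dropped_incompatible")

  expect_error(harmonize_pair(rec(snp = "rs1", ea = "A", oa = "G"),
                              rec(snp = "rs2", ea = "A", oa = "G")),
               "mismatch")
})

test_that("re-coding both records to the opposite allele preserves the causal content", {
  e <- rec(ea = "A", oa = "G", beta = 0.12, eaf = 0.3)
  o <- rec(ea = "A", oa = "G", beta = -0.04, eaf = 0.35)
  h1 <- harmonize_pair(e, o)
  e2 <- rec(ea = "G", oa = "A", beta = -0.12, eaf = 0.7)
  o2 <- rec(ea = "G", oa = "A", beta = 0.04, eaf = 0.65)
  h2 <- harmonize_pair(e2, o2)
  # both betas negate together, so every ratio-based estimate is unchanged
  expect_equal(h2$BETA_OUT / h2$BETA_EXP, h1$BETA_OUT / h1$BETA_EXP)
  expect_equal(abs(h2$BETA_EXP), abs(h1$BETA_EXP))
  expect_equal(h2$SE_OUT, h1$SE_OUT)
})

test_that("harmonize_sets intersects, audits and keeps exposure order", {
  expo <- make_exposure_table(23, trait = "glycine")
  outc <- make_outcome_table(expo, trait = "AD", drop = expo$SNP[c(3, 9, 15, 20)])
  h <- suppressMessages(harmonize_sets(expo, outc))
  expect_s3_class(h, "harmonized_set")
  expect_equal(nrow(h), 19L)
  expect_identical(h$SNP, setdiff(expo$SNP, expo$SNP[c(3, 9, 15, 20)]))

  audit <- attr(h, "audit")
  expect_setequal(audit$SNP, expo$SNP)           # every instrument audited once
  expect_equal(sum(audit$STATUS == "absent_outcome"), 4L)

  # identity harmonization: outcome = exposure study set
  self_out <- study_set(as.data.frame(expo), "glycine", "outcome")
  h2 <- suppressMessages(harmonize_sets(expo, self_out))
  expect_true(all(h2$STATUS == "kept"))
  expect_equal(h2$BETA_OUT, h2$BETA_EXP)

  # degenerate: everything palindromic at eaf 0.5
  pal <- study_set(data.frame(SNP = c("rs1", "rs2"), EA = "A", OA = "T",
                              EAF = 0.5, BETA = 0.1, SE = 0.01, P = 1e-9),
                   "x", "exposure")
  pal_out <- study_set(as.data.frame(pal), "y", "outcome")
  expect_error(suppressMessages(harmonize_sets(pal, pal_out)), "no usable")

  # disjoint variant sets fail naming both traits
  other <- study_set(data.frame(SNP = "rs999999", EA = "A", OA = "G",
                                BETA = 0.1, SE = 0.01, P = 0.5),
                     "AD", "outcome")
  expect_error(harmonize_sets(expo, other), "glycine.*AD")
})

test_that("harmonized sets round-trip through the TSV fixture format", {
  h <- rand_h(8, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(h, path)
  h2 <- read_harmonized(path)
  expect_equal(as.data.frame(h2), as.data.frame(h))
})
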