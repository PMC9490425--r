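test_that("summary tables round-trip through disk with full precision", {
  s <- make_exposure_table(23, trait = "glycine")
  expect_equal(nrow(s), 23L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(s, path)
  s2 <- read_summary_table(path, trait_name = "glycine", role = "exposure")
  expect_equal(as.data.frame(s2), as.data.frame(s))
  expect_identical(attr(s2, "trait_name"), "glycine")
})

test_that("column_map resolves heterogeneous source headers", {
  s <- make_exposure_table(5)
  d <- as.data.frame(s)
  names(d) <- c("rsid", "chrom", "bp", "effect_allele", "ref", "freq",
                "Effect", "StdErr", "Pval")
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  s2 <- read_summary_table(path, trait_name = "t", role = "exposure",
                           column_map = c(SNP = "rsid", CHR = "chrom",
                                          POS = "bp", EA = "effect_allele",
                                          OA = "ref", EAF = "freq",
                                          BETA = "Effect", SE = "StdErr",
                                          P = "Pval"))
  expect_equal(s2$BETA, s$BETA)
  expect_error(read_summary_table(path, "t", "exposure",
                                  column_map = c(BETA = "nonexistent")),
               "not found")
  expect_error(read_summary_table(path, "t", "exposure"), "missing required")
})

test_that("header-only input yields an empty study set with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("SNP\tEA\tOA\tBETA\tSE\tP", path)
  expect_warning(s <- read_summary_table(path, "t", "exposure"),
                 "0 records")
  expect_equal(nrow(s), 0L)
})

test_that("row validation enforces the per-record invariants", {
  base <- data.frame(SNP = c("rs1", "rs2"), EA = c("a", "G"),
                     OA = c("g", "T"), EAF = c(0.3, NA),
                     BETA = c(0.1, -0.2), SE = c(0.01, 0.02),
                     P = c(1e-9, 1e-8), stringsAsFactors = FALSE)
  s <- study_set(base, "t", "exposure")
  expect_identical(s$EA, c("A", "G"))  # alleles uppercased
  expect_true(is.na(s$EAF[2]))         # missing eaf is permitted

  bad_se <- base; bad_se$SE[2] <- 0
  expect_error(study_set(bad_se, "t", "exposure"), "row 2.*se must be > 0")
  expect_warning(lenient <- study_set(bad_se, "t", "exposure", strict = FALSE),
                 "dropping 1")
  expect_equal(nrow(lenient), 1L)

  for (mut in list(list(col = "P", val = 0, msg = "p-value"),
                   list(col = "EAF", val = 1.2, msg = "eaf"),
                   list(col = "OA", val = "A", msg = "equals"),
                   list(col = "SNP", val = "", msg = "variant_id"))) {
    bad <- base; bad[[mut$col]][1] <- mut$val
    expect_error(study_set(bad, "t", "exposure"), mut$msg)
  }
  dup <- base; dup$SNP <- c("rs1", "rs1")
  expect_error(study_set(dup, "t", "exposure"), "duplicated")
})

test_that("instrument selection filters by threshold, keeps order", {
  s <- study_set(data.frame(SNP = c("rs1", "rs2", "rs3"), EA = "A", OA = "G",
                            BETA = 0.1, SE = 0.01,
                            P = c(1e-9, 4e-8, 6e-8)), "t", "exposure")
  expect_equal(select_instruments(s, 5e-8)$SNP, c("rs1", "rs2"))
  expect_equal(nrow(select_instruments(s, 1.0)), 3L)
  expect_warning(none <- select_instruments(s, 1e-12), "no variants")
  expect_equal(nrow(none), 0L)
  expect_error(select_instruments(s, 0), "positive")
  out <- study_set(as.data.frame(s), "t", "outcome")
  expect_error(select_instruments(out, 5e-8), "exposure")
})

test_that("instrument selection is idempotent and monotone in the threshold", {
  s <- make_exposure_table(40, p_max = 1e-5)
  for (thr in c(1e-8, 5e-8, 5e-6)) {
    once <- suppressWarnings(select_instruments(s, thr))
    expect_identical(as.data.frame(suppressWarnings(select_instruments(once, thr))),
                     as.data.frame(once))
  }
  small <- suppressWarnings(select_instruments(s, 5e-8))
  large <- suppressWarnings(select_instruments(s, 5e-6))
  expect_true(all(small$SNP %in% large$SNP))
})

test_that("proxy substitution follows the r2 rule and never adds instruments", {
  expo <- study_set(data.frame(SNP = c("rs1", "rs4"), EA = "A", OA = "G",
                               BETA = 0.1, SE = 0.01, P = 1e-9),
                    "t", "exposure")
  outc <- study_set(data.frame(SNP = c("rs2", "rs4"), EA = "A", OA = "G",
                               BETA = 0.05, SE = 0.02, P = 0.5),
                    "d", "outcome")
  pm <- data.frame(MISSING_SNP = "rs1", PROXY_SNP = "rs2", R2 = 0.95)
  sub <- apply_proxy_map(expo, outc, pm)
  expect_setequal(sub$SNP, c("rs2", "rs4"))
  expect_equal(attr(sub, "proxy_log")$ACTION, "substituted")

  weak <- data.frame(MISSING_SNP = "rs1", PROXY_SNP = "rs2", R2 = 0.7)
  expect_message(dropped <- apply_proxy_map(expo, outc, weak), "dropped")
  expect_equal(dropped$SNP, "rs4")

  full <- study_set(data.frame(SNP = c("rs1", "rs4"), EA = "A", OA = "G",
                               BETA = 0.05, SE = 0.02, P = 0.5),
                    "d", "outcome")
  expect_equal(as.data.frame(apply_proxy_map(expo, full, NULL)),
               as.data.frame(expo), ignore_attr = TRUE)

  expect_error(apply_proxy_map(expo, outc,
                               data.frame(MISSING_SNP = "rs1",
                                          PROXY_SNP = "rs2", R2 = 1.3)),
               "\\[0,1\\]")

  # property: substitution can never increase the instrument count
  for (seed in 1:5) {
    set.seed(seed)
    e <- make_exposure_table(10, seed = seed)
    o <- make_outcome_table(e, seed = seed + 100,
                            drop = sample(e$SNP, 3))
    pm <- data.frame(MISSING_SNP = sample(e$SNP, 4, replace = FALSE),
                     PROXY_SNP = sample(o$SNP, 4), R2 = runif(4, 0.5, 1))
    expect_lte(nrow(suppressMessages(apply_proxy_map(e, o, pm))), nrow(e))
  }
})
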