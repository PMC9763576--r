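test_that("the packaged exposure table reads with all fields intact", {
  path <- system.file("extdata", "hcy_exposure.tsv", package = "hcymr")
  tab <- read_summary_table(path)
  expect_s3_class(tab, "snp_assoc")
  expect_equal(nrow(tab), 12)
  expect_equal(tab$rsid[1], "rs1801133")
  expect_equal(tab$beta[1], 0.1583)
  expect_equal(tab$se[1], 0.007)
  expect_equal(tab$pvalue[1], 4.34e-104)
  expect_true(all(tab$se > 0))
  expect_false(anyDuplicated(tab$rsid) > 0)
})

test_that("outcome tables tolerate absent optional columns", {
  path <- system.file("extdata", "outcome_nafld.tsv", package = "hcymr")
  tab <- read_summary_table(path)
  expect_equal(nrow(tab), 12)
  expect_true(all(is.na(tab$pvalue)))
  expect_true(all(is.na(tab$eaf)))
})

test_that("reader errors are specific: missing column, bad number, bad se", {
  hdr_only <- write_tmp_table(data.frame(rsid = character(),
                                         effect_allele = character(),
                                         beta = numeric(), se = numeric()))
  expect_equal(nrow(read_summary_table(hdr_only)), 0)

  no_se <- write_tmp_table(data.frame(rsid = "rs1", effect_allele = "A",
                                      beta = 0.1))
  expect_error(read_summary_table(no_se), "required column 'se'")

  bad_num <- write_tmp_table(data.frame(rsid = c("rs1", "rs2"),
                                        effect_allele = "A",
                                        beta = c("0.1", "oops"),
                                        se = c(0.01, 0.02)))
  expect_error(read_summary_table(bad_num), "row 2")

  zero_se <- write_tmp_table(data.frame(
    rsid = c("rs1", "rs2", "rs3"), effect_allele = "A",
    beta = 0.1, se = c(0.01, 0.02, 0)))
  expect_error(read_summary_table(zero_se), "rs3")
})

test_that("column_map renames and comma-delimited input both work", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("SNP,EA,b,stderr", "rs9,T,0.05,0.01"), path)
  tab <- read_summary_table(path, column_map = c(rsid = "SNP",
                                                 effect_allele = "EA",
                                                 beta = "b", se = "stderr"))
  expect_equal(tab$rsid, "rs9")
  expect_equal(tab$beta, 0.05)
})

test_that("write/read round-trips all numeric fields exactly", {
  tab <- hcy_table1()$exposure
  path <- tempfile(fileext = ".tsv")
  write_summary_table(tab, path)
  back <- read_summary_table(path)
  for (field in c("beta", "se", "eaf", "pvalue")) {
    expect_identical(back[[field]], tab[[field]])
  }
  expect_identical(back$rsid, tab$rsid)
})

test_that("harmonizing the pre-aligned fixture joins all SNPs with no flips", {
  d <- hcy_table1()
  ds <- harmonize(d$exposure, d$outcomes$NAFLD, outcome_label = "NAFLD")
  expect_equal(length(ds$snps), 12)
  expect_equal(nrow(ds$flip_log), 0)
  expect_equal(ds$beta_outcome, d$outcomes$NAFLD$beta)
})

test_that("swapped outcome alleles flip the outcome beta sign", {
  exposure <- snp_assoc(data.frame(rsid = "rs1", effect_allele = "A",
                                   other_allele = "G", beta = 0.1,
                                   se = 0.01))
  outcome <- snp_assoc(data.frame(rsid = "rs1", effect_allele = "G",
                                  other_allele = "A", beta = 0.05,
                                  se = 0.02))
  ds <- harmonize(exposure, outcome)
  expect_equal(ds$beta_outcome, -0.05)
  expect_equal(ds$flip_log$action, "allele_flip")
})

test_that("double allele flip is the identity", {
  d <- hcy_table1()
  out <- d$outcomes$NAFLD
  flipped <- out
  flipped$effect_allele <- c(A = "T", T = "A", C = "G",
                             G = "C")[out$effect_allele]
  flipped$other_allele <- out$effect_allele
  flipped$beta <- -out$beta
  out$other_allele <- flipped$effect_allele
  ds_ref <- harmonize(d$exposure, out)
  ds_flip <- harmonize(d$exposure, snp_assoc(flipped))
  expect_equal(ds_flip$beta_outcome, ds_ref$beta_outcome)
  expect_equal(ds_flip$snps, ds_ref$snps)
})

test_that("harmonize is idempotent on an aligned pair", {
  exposure <- snp_assoc(data.frame(rsid = c("rs1", "rs2"),
                                   effect_allele = c("A", "C"),
                                   other_allele = c("G", "T"),
                                   beta = c(0.1, -0.2), se = 0.01))
  outcome <- snp_assoc(data.frame(rsid = c("rs1", "rs2"),
                                  effect_allele = c("A", "C"),
                                  other_allele = c("G", "T"),
                                  beta = c(0.03, 0.07), se = 0.02))
  once <- harmonize(exposure, outcome)
  expect_equal(nrow(once$flip_log), 0)
  expect_equal(once$beta_outcome, outcome$beta)
})

test_that("degenerate harmonization inputs raise clean errors", {
  a <- snp_assoc(data.frame(rsid = "rs1", effect_allele = "A",
                            beta = 0.1, se = 0.01))
  b <- snp_assoc(data.frame(rsid = "rs2", effect_allele = "A",
                            beta = 0.1, se = 0.01))
  expect_error(harmonize(a, b), "no overlapping rsids")
  mismatch <- snp_assoc(data.frame(rsid = "rs1", effect_allele = "A",
                                   other_allele = "C", beta = 0.1,
                                   se = 0.01))
  exp_ag <- snp_assoc(data.frame(rsid = "rs1", effect_allele = "A",
                                 other_allele = "G", beta = 0.1, se = 0.01))
  expect_error(suppressWarnings(harmonize(exp_ag, mismatch)),
               "all overlapping SNPs dropped")
})

test_that("palindromic SNPs follow the configured policy", {
  exposure <- snp_assoc(data.frame(rsid = c("rs1", "rs2"),
                                   effect_allele = c("A", "C"),
                                   other_allele = c("T", "A"),
                                   beta = c(0.1, 0.2), se = 0.01))
  outcome <- snp_assoc(data.frame(rsid = c("rs1", "rs2"),
                                  effect_allele = c("A", "C"),
                                  other_allele = c("T", "A"),
                                  beta = c(0.01, 0.02), se = 0.02))
  flagged <- harmonize(exposure, outcome, policy = "keep_flag")
  expect_equal(length(flagged$snps), 2)
  expect_equal(flagged$flip_log$rsid, "rs1")
  expect_equal(flagged$flip_log$action, "palindromic_flag")
  dropped <- suppressWarnings(harmonize(exposure, outcome, policy = "drop"))
  expect_equal(dropped$snps, "rs2")
  silent <- harmonize(exposure, outcome, policy = "keep")
  expect_equal(nrow(silent$flip_log), 0)
})

test_that("effect-with-CI assembly matches the closed-form z-interval", {
  # frozen from exp(0.2337 -/+ qnorm(0.975) * 0.1599)
  e <- to_effect_with_ci(0.2337, 0.1599, 12, "IVW-fixed")
  expect_equal(e$or_scale, 1.26327, tolerance = 1e-4)
  expect_equal(e$ci_low, 0.92341, tolerance = 1e-4)
  expect_equal(e$ci_high, 1.72827, tolerance = 1e-4)

  null <- to_effect_with_ci(0, 1, 1, "wald")
  expect_equal(null$or_scale, 1)
  expect_equal(null$ci_low, exp(-stats::qnorm(0.975)), tolerance = 1e-12)
  expect_equal(null$ci_high, 7.0993, tolerance = 1e-4)
  expect_equal(null$pvalue, 1)

  expect_error(to_effect_with_ci(0.1, 0, 1, "bad"), "positive")
})

test_that("mr_estimate invariants hold across random inputs", {
  set.seed(11)
  for (i in 1:50) {
    e <- to_effect_with_ci(rnorm(1), rexp(1) + 1e-4, 5, "x",
                           alpha = runif(1, 0.01, 0.2))
    expect_lte(e$ci_low, e$or_scale)
    expect_gte(e$ci_high, e$or_scale)
    expect_identical(e$or_scale, exp(e$estimate_log))
    expect_gt(e$pvalue, 0)
    expect_lte(e$pvalue, 1)
  }
})
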