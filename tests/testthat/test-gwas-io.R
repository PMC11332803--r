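test_that("summary stats round-trip through TSV and enforce invariants", {
  df <- toy_panel_df(3)
  ss <- summary_stats(df, "t1")
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss), 3L)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  back <- read_summary_stats(path, trait_id = "t1")
  expect_equal(as.data.frame(back), as.data.frame(ss), tolerance = 0)

  # rows violating invariants are dropped with a warning, not fatal
  bad <- df
  bad$se[2] <- 0
  expect_warning(ss2 <- summary_stats(bad, "t1"), "dropped 1")
  expect_equal(ss2$rsid, c("rs1", "rs3"))

  bad <- df; bad$pvalue[1] <- 0
  expect_warning(summary_stats(bad), "dropped 1")
  bad <- df; bad$other_allele[3] <- "A"
  expect_warning(summary_stats(bad), "dropped 1")

  # all rows invalid -> empty-input error
  bad <- df; bad$se <- -1
  expect_error(suppressWarnings(summary_stats(bad)), "zero valid rows")
})

test_that("column_map reads foreign dialects identically to native files", {
  df <- toy_panel_df(4)
  native <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(summary_stats(df), native)

  foreign <- read.delim(native)
  names(foreign)[names(foreign) == "beta"] <- "effect"
  names(foreign)[names(foreign) == "p_value"] <- "pval"
  fpath <- withr::local_tempfile(fileext = ".tsv")
  write.table(foreign, fpath, sep = "\t", quote = FALSE, row.names = FALSE)

  a <- read_summary_stats(native, trait_id = "x")
  b <- read_summary_stats(fpath, trait_id = "x",
                          column_map = c(beta = "effect", pvalue = "pval"))
  expect_equal(as.data.frame(a), as.data.frame(b))

  # a missing mandatory column is a configuration error
  expect_error(read_summary_stats(fpath, trait_id = "x"), "required column")
})

test_that("LD matrices validate and round-trip in square and long formats", {
  r2 <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(c("rs1", "rs2"),
                                                     c("rs1", "rs2")))
  ld <- ld_matrix(r2)
  expect_equal(ld$r2["rs1", "rs2"], 0.3)

  sq <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, sq)
  expect_equal(read_ld_matrix(sq)$r2, ld$r2)

  long <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid_a\trsid_b\tr2", "rs1\trs2\t0.3"), long)
  expect_equal(read_ld_matrix(long)$r2, ld$r2)

  bad <- r2; bad[1, 2] <- 0.5
  expect_error(ld_matrix(bad), "asymmetric")
  bad <- r2; bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(ld_matrix(bad), "outside")
})

test_that("harmonization flips swapped alleles and applies palindrome policy", {
  ex <- summary_stats(data.frame(
    rsid = c("rs1", "rs2", "rs3"), chromosome = "1", position = 1:3 * 1000L,
    effect_allele = c("A", "A", "A"), other_allele = c("G", "T", "C"),
    eaf = c(0.3, 0.2, 0.3), beta = c(0.1, 0.2, 0.3), se = 0.02,
    pvalue = 1e-8, n = 1e4), "exp")
  ou <- summary_stats(data.frame(
    rsid = c("rs1", "rs2", "rs3"), chromosome = "1", position = 1:3 * 1000L,
    effect_allele = c("G", "A", "C"), other_allele = c("A", "T", "T"),
    eaf = c(0.7, 0.2, 0.5), beta = c(-0.05, 0.1, 0.4), se = 0.01,
    pvalue = 1e-4, n = 1e4), "out")

  h <- harmonize(ex, ou, palindrome_policy = "drop")
  # rs1 swapped: beta negated, flipped recorded
  expect_equal(h$beta_out[h$rsid == "rs1"], 0.05)
  expect_true(h$flipped[h$rsid == "rs1"])
  # rs2 palindromic (A/T): dropped and recorded
  expect_false("rs2" %in% h$rsid)
  expect_true("rs2" %in% attr(h, "palindromic_removed"))
  # rs3 incompatible alleles (A/C vs C/T): removed
  expect_true("rs3" %in% attr(h, "incompatible_removed"))

  # infer_by_eaf keeps unambiguous palindromic SNPs (both eaf well below .5)
  h2 <- harmonize(ex, ou, palindrome_policy = "infer_by_eaf")
  expect_true("rs2" %in% h2$rsid)
  expect_equal(h2$beta_out[h2$rsid == "rs2"], 0.1)
})

test_that("harmonization recovers the generator's truth panel under random swaps", {
  ch <- generate_chain(j_exposure = 60, j_mediator = 40, seed = 11)
  out_df <- as.data.frame(ch$outcome)
  set.seed(99)
  swap <- sample(c(TRUE, FALSE), nrow(out_df), replace = TRUE, prob = c(0.3, 0.7))
  tmp <- out_df$effect_allele[swap]
  out_df$effect_allele[swap] <- out_df$other_allele[swap]
  out_df$other_allele[swap] <- tmp
  out_df$beta[swap] <- -out_df$beta[swap]
  out_df$eaf[swap] <- 1 - out_df$eaf[swap]
  swapped <- summary_stats(out_df, "outcome", "outcome")

  h <- harmonize(ch$exposure, swapped)
  expect_equal(nrow(h), 100L)
  expect_equal(sum(h$flipped), sum(swap))
  # harmonized outcome betas equal the pre-swap panel for every SNP
  expect_equal(h$beta_out[match(ch$outcome$rsid, h$rsid)], ch$outcome$beta)
})

test_that("harmonize is idempotent and a double swap restores betas exactly", {
  ch <- generate_chain(j_exposure = 20, j_mediator = 0, seed = 5)
  h1 <- harmonize(ch$exposure, ch$outcome)
  # rebuild an outcome panel from the harmonized set (same alleles as exposure)
  redone <- as.data.frame(ch$exposure)
  redone$beta <- h1$beta_out[match(redone$rsid, h1$rsid)]
  redone$se <- h1$se_out[match(redone$rsid, h1$rsid)]
  h2 <- harmonize(ch$exposure, summary_stats(redone, "outcome", "outcome"))
  expect_equal(h2$beta_out, h1$beta_out)
  expect_false(any(h2$flipped))

  # swapping alleles twice is the identity
  df <- as.data.frame(ch$outcome)
  swap2 <- function(d) {
    tmp <- d$effect_allele; d$effect_allele <- d$other_allele; d$other_allele <- tmp
    d$beta <- -d$beta; d$eaf <- 1 - d$eaf; d
  }
  expect_equal(swap2(swap2(df)), df)

  # accounting identity: flipped + unflipped = retained <= intersection
  expect_lte(nrow(h1), min(nrow(ch$exposure), nrow(ch$outcome)))
  expect_equal(sum(h1$flipped) + sum(!h1$flipped), nrow(h1))
})

test_that("harmonized sets serialize with the documented header", {
  h <- h_ivw3()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(h, path)
  back <- read.delim(path)
  expect_equal(names(back), c("rsid", "beta_exp", "se_exp", "beta_out",
                              "se_out", "flipped"))
  expect_equal(back$beta_out, h$beta_out)
})
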