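test_that("p-value selection is a strict filter preserving order", {
  df <- toy_panel_df(3)
  df$pvalue <- c(2e-6, 5e-5, 9e-6)
  ss <- summary_stats(df)
  kept <- select_by_pvalue(ss, 1e-5)
  expect_equal(kept$rsid, c("rs1", "rs3"))

  expect_equal(nrow(select_by_pvalue(ss, 1)), 3L)
  # boundary excluded: p exactly at threshold is dropped
  df$pvalue <- c(1e-5, 1e-5, 9e-6)
  expect_equal(select_by_pvalue(summary_stats(df), 1e-5)$rsid, "rs3")
  # idempotence
  expect_equal(as.data.frame(select_by_pvalue(kept, 1e-5)),
               as.data.frame(kept))
})

test_that("p-value selection matches a brute-force scan on a large panel", {
  ch <- generate_chain(j_exposure = 500, j_mediator = 500,
                       sigma_gamma = 0.05, seed = 21)
  panel <- ch$exposure
  kept <- select_by_pvalue(panel, 1e-5)
  brute <- panel$rsid[vapply(seq_len(nrow(panel)),
                             function(i) panel$pvalue[i] < 1e-5, logical(1))]
  expect_equal(kept$rsid, brute)
  expect_gt(length(brute), 0)
})

test_that("greedy LD clumping keeps the most significant SNP per linked group", {
  df <- data.frame(
    rsid = c("A", "B", "C"), chromosome = "1",
    position = c(100000L, 105000L, 150000L),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.1, se = 0.02, pvalue = c(1e-8, 1e-6, 1e-7), n = 1e4,
    stringsAsFactors = FALSE)
  ss <- summary_stats(df)
  r2 <- diag(1, 3); dimnames(r2) <- list(df$rsid, df$rsid)
  r2["A", "B"] <- r2["B", "A"] <- 0.8
  r2["A", "C"] <- r2["C", "A"] <- 0.0005
  ld <- ld_matrix(r2)

  # B is within 5 kb of A at r2 0.8 -> discarded; C is far in LD terms
  out <- ld_clump(ss, ld, window_kb = 10000, r2_threshold = 0.001)
  expect_setequal(out$rsid, c("A", "C"))

  # all pairwise r2 = 0 -> identity
  out2 <- ld_clump(ss, ld_matrix(diag(1, 3), df$rsid))
  expect_setequal(out2$rsid, df$rsid)

  # single SNP -> itself
  one <- ss_subset(ss, 1)
  expect_equal(ld_clump(one, ld)$rsid, "A")

  # discard needs BOTH window and r2: far-apart SNPs kept regardless of r2
  far <- df; far$position <- c(1e6L, 50000000L, 200000000L)
  out3 <- ld_clump(summary_stats(far), ld)
  expect_setequal(out3$rsid, c("A", "B", "C"))
})

test_that("clumping is invariant to input order and certifies its discards", {
  ch <- generate_chain(j_exposure = 30, j_mediator = 0, seed = 31,
                       ld_blocks = list(sizes = rep(5L, 6L), r2 = 0.8))
  panel <- ch$exposure
  a <- ld_clump(panel, ch$ld)
  set.seed(1)
  perm <- sample(nrow(panel))
  b <- ld_clump(ss_subset(panel, perm), ch$ld)
  expect_setequal(a$rsid, b$rsid)
  expect_equal(nrow(a), 6L)  # one index per block

  # certificate: every discarded SNP is linked within-window to some index
  discarded <- setdiff(panel$rsid, a$rsid)
  for (d in discarded) {
    i <- match(d, panel$rsid)
    linked <- vapply(a$rsid, function(k) {
      j <- match(k, panel$rsid)
      panel$chromosome[i] == panel$chromosome[j] &&
        abs(panel$position[i] - panel$position[j]) <= 10000 * 1000 &&
        ch$ld$r2[d, k] > 0.001
    }, logical(1))
    expect_true(any(linked))
  }

  # SNPs missing from the LD matrix are kept with a warning
  small_ld <- ld_matrix(ch$ld$r2[1:10, 1:10], ch$ld$rsids[1:10])
  expect_warning(out <- ld_clump(panel, small_ld), "absent from LD matrix")
  expect_true(all(panel$rsid[11:30] %in% out$rsid))
})

test_that("F statistics match the closed forms", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 0.02), 0)
  # frequency-based form against a directly coded evaluation
  beta <- 0.1; eaf <- 0.3; n <- 5000
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  expect_equal(f_statistic(beta, 0.02, eaf, n, method = "r2_based"),
               (n - 2) * r2 / (1 - r2))
  expect_error(f_statistic(0.1, 0.02, eaf = NA, n = 5000, method = "r2_based"),
               "requires eaf and n")
})

test_that("weak-instrument filter is strict at the boundary and annotates", {
  df <- toy_panel_df(3)
  df$beta <- c(sqrt(9.9), sqrt(10), 5) * df$se   # F ~ 9.9, 10.0, 25.0
  ss <- summary_stats(df)
  f <- f_statistic(ss$beta, ss$se)
  # strict inequality: a record whose F equals f_min exactly is excluded
  out <- filter_weak(ss, f_min = f[2])
  expect_equal(out$rsid, "rs3")
  expect_equal(out$f_stat, 25)
  expect_equal(out$r2_explained, 2 * out$eaf * (1 - out$eaf) * out$beta^2)
  # F below 10 never survives the default cut
  expect_false("rs1" %in% filter_weak(ss, f_min = 10)$rsid)

  # all strong -> identity
  strong <- toy_panel_df(3)
  expect_equal(nrow(filter_weak(summary_stats(strong))), 3L)
})

test_that("planted null instruments are removed by the F filter", {
  # SNPs with true effect zero have Wald F ~ chi-square(1); far more than
  # 90% fall below 10 at any n
  removed <- vapply(1:200, function(s) {
    ch <- generate_chain(j_exposure = 10, j_mediator = 10, sigma_gamma = 0,
                         n_exp = 5000, n_med = 5000, n_out = 5000, seed = s)
    out <- filter_weak(ch$exposure, f_min = 10)
    1 - nrow(out) / 20
  }, numeric(1))
  expect_gte(mean(removed), 0.9)
})
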