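test_that("Wald ratio matches direct division and its error propagation", {
  r <- wald_ratio(0.1, 0.02, 0.05, 0.01)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.1)
  expect_equal(r$or_, exp(0.5))

  null <- wald_ratio(0.1, 0.02, 0, 0.01)
  expect_equal(null$beta, 0)
  expect_equal(null$or_, 1)

  expect_error(wald_ratio(0, 0.02, 0.05, 0.01), "zero")

  # second-order se against a Monte-Carlo oracle on a strong instrument
  set.seed(7)
  bx <- rnorm(1e6, 0.1, 0.005); by <- rnorm(1e6, 0.05, 0.01)
  mc_sd <- sd(by / bx)
  r2 <- wald_ratio(0.1, 0.005, 0.05, 0.01, se_order = "second")
  expect_lt(abs(r2$se - mc_sd) / mc_sd, 0.02)
})

test_that("IVW equals weighted least squares through the origin", {
  h <- h_ivw3()
  # independently coded WLS-through-origin oracle
  w <- 1 / h$se_out^2
  oracle <- sum(h$beta_exp * h$beta_out * w) / sum(h$beta_exp^2 * w)
  expect_equal(oracle, 820 / 1400)
  fit <- ivw(h, model = "fixed")
  expect_equal(fit$beta, oracle)
  expect_equal(fit$se, sqrt(1 / sum(h$beta_exp^2 * w)))

  # consensus data: all ratios equal -> exact estimate, Q = 0
  hc <- harmonized_set(c(0.1, 0.2, 0.4), rep(0.01, 3),
                       c(0.05, 0.1, 0.2), rep(0.01, 3))
  fc <- ivw(hc)
  expect_equal(fc$beta, 0.5)
  expect_equal(fc$extras$q_statistic, 0)
  # multiplicative random effects never deflates below the fixed se
  expect_equal(fc$se, ivw(hc, model = "fixed")$se)

  # single SNP degrades to the Wald ratio
  h1 <- harmonized_set(0.1, 0.02, 0.05, 0.01)
  expect_message(f1 <- ivw(h1), "single SNP")
  expect_equal(f1$beta, wald_ratio(0.1, 0.02, 0.05, 0.01)$beta)
  expect_equal(f1$se, wald_ratio(0.1, 0.02, 0.05, 0.01)$se)

  # degenerate exposure
  hz <- suppressWarnings(harmonized_set(c(0, 0), c(1, 1), c(0.1, 0.2), c(1, 1)))
  expect_error(ivw(hz), "zero")

  # IVW with unit outcome ses equals ordinary LS through the origin
  set.seed(3)
  bx <- rnorm(10); by <- 0.3 * bx + rnorm(10, 0, 0.1)
  hu <- harmonized_set(bx, rep(1, 10), by, rep(1, 10))
  expect_equal(ivw(hu, model = "fixed")$beta,
               unname(coef(lm(by ~ bx - 1))))
})

test_that("MR-Egger recovers slope and intercept on an exact collinear fit", {
  fit <- mr_egger(h_egger_collinear())
  expect_equal(fit$beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$extras$egger_intercept, 0.02, tolerance = 1e-10)
  expect_error(mr_egger(h_ivw3()[1:2, ]), "at least 3")
})

test_that("Egger orientation makes the fit invariant to allele recoding", {
  set.seed(12)
  bx <- rnorm(20, 0, 0.2); by <- 0.02 + 0.4 * bx + rnorm(20, 0, 0.02)
  h1 <- harmonized_set(bx, rep(0.01, 20), by, rep(0.02, 20))
  flip <- rep(c(1, -1), 10)
  h2 <- harmonized_set(bx * flip, rep(0.01, 20), by * flip, rep(0.02, 20))
  f1 <- mr_egger(h1); f2 <- mr_egger(h2)
  expect_equal(f1$beta, f2$beta)
  expect_equal(f1$extras$egger_intercept, f2$extras$egger_intercept)
})

test_that("weighted median interpolates the 50% weight point", {
  fit <- weighted_median(h_ratios3(), n_boot = 0)
  expect_equal(fit$beta, 0.5)

  # a SNP holding the majority of weight dominates
  h <- harmonized_set(rep(1, 4), rep(0.01, 4), c(0.2, 0.3, 0.8, 0.9),
                      c(1, 1, 0.05, 1))  # third SNP weight 400 vs 1 each
  expect_lt(abs(weighted_median(h, n_boot = 0)$beta - 0.8), 0.01)

  # bootstrap se is reproducible given the seed
  a <- weighted_median(h_ratios3(), n_boot = 200, seed = 42)
  b <- weighted_median(h_ratios3(), n_boot = 200, seed = 42)
  expect_equal(a$se, b$se)
  expect_gt(a$se, 0)
})

test_that("mode estimators find the dominant ratio cluster", {
  # point mass: all ratios equal
  h <- harmonized_set(rep(1, 3), rep(0.01, 3), rep(0.7, 3), rep(0.1, 3))
  expect_equal(mode_estimator(h, n_boot = 0)$beta, 0.7)

  # dominant cluster with a small bandwidth
  h2 <- harmonized_set(rep(1, 4), rep(0.01, 4), c(0.5, 0.5, 0.5, 0.9),
                       rep(0.1, 4))
  expect_lt(abs(mode_estimator(h2, phi = 0.3, n_boot = 0)$beta - 0.5), 0.05)

  # bimodal ratios: the mode tracks the majority mode while IVW is pulled
  set.seed(8)
  reps <- vapply(1:50, function(s) {
    set.seed(s)
    bx <- abs(rnorm(30, 0.3, 0.05))
    truth <- 0.4
    ratio_true <- c(rep(truth, 20), rep(1.5, 10))  # 10 invalid instruments
    by <- ratio_true * bx + rnorm(30, 0, 0.01)
    h <- harmonized_set(bx, rep(0.005, 30), by, rep(0.01, 30))
    mode_b <- mode_estimator(h, phi = 0.5, n_boot = 0)$beta
    ivw_b <- ivw(h)$beta
    c(abs(mode_b - truth), abs(ivw_b - truth))
  }, numeric(2))
  expect_lt(mean(reps[1, ]), mean(reps[2, ]))
  expect_lt(mean(reps[1, ]), 0.05)
})

test_that("estimators are scale and sign equivariant", {
  set.seed(15)
  bx <- rnorm(12, 0, 0.2); by <- 0.3 * bx + rnorm(12, 0, 0.02)
  h <- harmonized_set(bx, rep(0.01, 12), by, rep(0.02, 12))
  k <- 2.5
  hk <- harmonized_set(bx, rep(0.01, 12), k * by, k * rep(0.02, 12))
  hn <- harmonized_set(bx, rep(0.01, 12), -by, rep(0.02, 12))

  for (pair in list(list(ivw(h), ivw(hk), ivw(hn)),
                    list(mr_egger(h), mr_egger(hk), mr_egger(hn)),
                    list(weighted_median(h, 200, 1),
                         weighted_median(hk, 200, 1),
                         weighted_median(hn, 200, 1)))) {
    expect_equal(pair[[2]]$beta, k * pair[[1]]$beta, tolerance = 1e-8)
    expect_equal(pair[[2]]$se, k * pair[[1]]$se, tolerance = 1e-8)
    expect_equal(pair[[3]]$beta, -pair[[1]]$beta, tolerance = 1e-8)
    expect_equal(pair[[3]]$pvalue, pair[[1]]$pvalue, tolerance = 1e-8)
  }
})

test_that("with valid instruments all five estimators converge together", {
  spread <- function(n) {
    ch <- generate_chain(j_exposure = 50, j_mediator = 0, a = 0, b = 0,
                         c_direct = 0.2, n_exp = n, n_med = 100, n_out = n,
                         seed = 77)
    h <- select_and_harmonize(ch$exposure, ch$outcome)
    tab <- mr_all(h, n_boot = 50, seed = 77)
    max(tab$beta) - min(tab$beta)
  }
  s_small <- spread(5000)
  s_large <- spread(200000)
  expect_lt(s_large, s_small)
  expect_lt(s_large, 0.05)
})

test_that("direction classification follows the beta-sign and p rules", {
  mk <- function(beta, p) {
    r <- mr_result("ivw", beta, 0.05, p, 10L)
    r
  }
  expect_equal(classify_direction(mk(0.147, 0.04)), "risk")
  expect_equal(classify_direction(mk(-0.120, 0.03)), "protective")
  expect_equal(classify_direction(mk(0.5, 0.5)), "no_causal_evidence")
  expect_equal(classify_direction(mk(0, 0.01)), "no_causal_evidence")
})
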