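#' Cochran's Q heterogeneity test
#'
#' Q = sum over SNPs of w_j * (r_j - beta_IVW)^2, where r_j are the
#' per-SNP Wald ratios, w_j = 1 / ratio_se_j^2 their inverse-variance
#' weights, and beta_IVW the fixed-effect IVW estimate (the weighted mean
#' of the ratios). Under homogeneity Q is chi-square with J - 1 degrees
#' of freedom. Q is unitless: rescaling the outcome betas and ses by a
#' common factor leaves it unchanged.
#'
#' @param h a `harmonized_set` with at least 2 SNPs.
#' @return list with `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(h) {
  J <- nrow(h)
  if (J < 2L) stop("cochran_q: at least 2 SNPs required", call. = FALSE)
  rs <- ratio_set(h)
  beta <- sum(rs$weight * rs$ratio) / sum(rs$weight)
  q <- sum(rs$weight * (rs$ratio - beta)^2)
  list(q = q, df = J - 1L,
       pvalue = stats::pchisq(q, J - 1L, lower.tail = FALSE))
}

#' Egger-intercept test for directional pleiotropy
#'
#' Re-exposes the intercept triple from the [mr_egger()] fit: a nonzero
#' intercept indicates that the instruments' mean pleiotropic effect on
#' the outcome is not zero (directional horizontal pleiotropy).
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return list with `intercept`, `se`, `pvalue`.
#' @export
egger_intercept_test <- function(h) {
  fit <- mr_egger(h)
  list(intercept = fit$extras$egger_intercept,
       se = fit$extras$egger_intercept_se,
       pvalue = fit$extras$egger_intercept_p)
}

# leave-one-out fixed-effect IVW betas for all J SNPs at once
.loo_ivw_beta <- function(bx, by, w) {
  num <- sum(bx * by * w); den <- sum(bx^2 * w)
  (num - bx * by * w) / (den - bx^2 * w)
}

#' MR-PRESSO global and outlier tests
#'
#' Simulation-based residual-sum-of-squares test for pleiotropic outlier
#' SNPs. The observed statistic is
#' RSS = sum_j w_j * (beta_out_j - beta_IVW(-j) * beta_exp_j)^2 with
#' w_j = 1/se_out_j^2 and beta_IVW(-j) the leave-one-out fixed-effect IVW
#' estimate. `n_sim` parametric replicates draw
#' beta_out_j* ~ Normal(beta_IVW(-j) * beta_exp_j, se_out_j) and
#' recompute the statistic (including the leave-one-out fits) to give the
#' global p by the plus-one Monte-Carlo estimator
#' (1 + #\{RSS_sim >= RSS_obs\}) / (n_sim + 1); with `n_sim` = 1000 the
#' smallest reportable p is 1/1001. Each SNP's weighted squared residual
#' is compared with its own simulated distribution for a per-SNP outlier
#' p, Bonferroni-adjusted by J; adjusted p below `alpha` flags the SNP.
#' The distortion test is not implemented.
#'
#' @param h a `harmonized_set` with at least 4 SNPs.
#' @param n_sim simulation replicates (default 1000).
#' @param alpha outlier flagging level on the adjusted p (default 0.05).
#' @param seed integer seed (required).
#' @return an object of class `presso_report`: list with `observed_rss`,
#'   `global_p`, `outlier_p` (named, Bonferroni-adjusted), `outlier_rsids`,
#'   `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, alpha = 0.05, seed) {
  J <- nrow(h)
  if (J < 4L) stop("mr_presso: at least 4 SNPs required", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("mr_presso: seed required", call. = FALSE)
  bx <- h$beta_exp; by <- h$beta_out; sy <- h$se_out
  w <- 1 / sy^2
  loo <- .loo_ivw_beta(bx, by, w)
  expected <- loo * bx
  obs_res2 <- w * (by - expected)^2
  obs_rss <- sum(obs_res2)

  set.seed(seed)
  sim_rss <- numeric(n_sim)
  exceed <- numeric(J)          # per-SNP: how often sim residual >= observed
  for (s in seq_len(n_sim)) {
    by_s <- stats::rnorm(J, expected, sy)
    loo_s <- .loo_ivw_beta(bx, by_s, w)
    res2_s <- w * (by_s - loo_s * bx)^2
    sim_rss[s] <- sum(res2_s)
    exceed <- exceed + (res2_s >= obs_res2)
  }
  global_p <- (1 + sum(sim_rss >= obs_rss)) / (n_sim + 1)
  outlier_p <- pmin((1 + exceed) / (n_sim + 1) * J, 1)
  names(outlier_p) <- h$rsid
  structure(list(observed_rss = obs_rss, global_p = global_p,
                 outlier_p = outlier_p,
                 outlier_rsids = h$rsid[outlier_p < alpha],
                 n_sim = n_sim, seed = seed),
            class = "presso_report")
}

#' @export
print.presso_report <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.4g (%d sims)\n",
              x$observed_rss, x$global_p, x$n_sim))
  if (length(x$outlier_rsids)) {
    cat("outliers:", paste(x$outlier_rsids, collapse = ", "), "\n")
  } else cat("no outliers flagged\n")
  invisible(x)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW causal effect J times, each time excluding one
#' SNP. A row is flagged when its beta sign differs from the full-set
#' IVW sign, indicating a single SNP driving the direction of the
#' estimate.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param model IVW error model, see [ivw()].
#' @return data.frame with one row per excluded SNP: `excluded_rsid`,
#'   `beta`, `se`, `pvalue`, `sign_flip`.
#' @export
leave_one_out <- function(h, model = "multiplicative_random") {
  J <- nrow(h)
  if (J < 3L) stop("leave_one_out: at least 3 SNPs required", call. = FALSE)
  full <- ivw(h, model = model)
  rows <- lapply(seq_len(J), function(j) {
    sub <- h[-j, , drop = FALSE]
    attr(sub, "exposure_id") <- attr(h, "exposure_id")
    attr(sub, "outcome_id") <- attr(h, "outcome_id")
    class(sub) <- class(h)
    res <- ivw(sub, model = model)
    data.frame(excluded_rsid = h$rsid[j], beta = res$beta, se = res$se,
               pvalue = res$pvalue,
               sign_flip = sign(res$beta) != sign(full$beta),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full sensitivity-diagnostics panel
#'
#' Cochran's Q, Egger intercept, MR-PRESSO and leave-one-out for one
#' exposure-outcome pair, plus a one-row summary table suitable for
#' reporting.
#'
#' @param h a `harmonized_set`.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed master seed ([derive_seed()] gives PRESSO its own stream).
#' @return list with `q`, `egger`, `presso`, `loo`, `summary` (one-row
#'   data.frame: q, q_df, q_p, egger_intercept, egger_intercept_p,
#'   presso_global_p, presso_outliers).
#' @export
mr_diagnostics <- function(h, n_sim = 1000, seed = 1L) {
  q <- cochran_q(h)
  eg <- tryCatch(egger_intercept_test(h), error = function(e) NULL)
  pr <- tryCatch(mr_presso(h, n_sim = n_sim, seed = derive_seed(seed, "presso")),
                 error = function(e) NULL)
  lo <- tryCatch(leave_one_out(h), error = function(e) NULL)
  list(q = q, egger = eg, presso = pr, loo = lo,
       summary = data.frame(
         exposure = attr(h, "exposure_id"), outcome = attr(h, "outcome_id"),
         q = q$q, q_df = q$df, q_p = q$pvalue,
         egger_intercept = if (is.null(eg)) NA_real_ else eg$intercept,
         egger_intercept_p = if (is.null(eg)) NA_real_ else eg$pvalue,
         presso_global_p = if (is.null(pr)) NA_real_ else pr$global_p,
         presso_outliers = if (is.null(pr)) "" else
           paste(pr$outlier_rsids, collapse = ";"),
         stringsAsFactors = FALSE))
}
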