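#' Construct an MR result record
#'
#' Uniform container returned by every estimator: causal effect on the
#' outcome scale (log-odds for binary outcomes), its standard error,
#' two-sided p, odds ratio `exp(beta)` with 95% CI `exp(beta +- z*se)`
#' (z = 1.959964), the number of instruments, and a method-specific
#' `extras` list (e.g. Egger intercept, Cochran's Q).
#'
#' @param method estimator name.
#' @param beta,se effect and standard error.
#' @param pvalue two-sided p-value.
#' @param n_snp number of instruments used.
#' @param extras named list of method-specific values.
#' @return an object of class `mr_result`.
#' @export
mr_result <- function(method, beta, se, pvalue, n_snp, extras = list()) {
  stopifnot(is.character(method), length(beta) == 1L)
  structure(list(method = method, beta = beta, se = se, pvalue = pvalue,
                 or_ = exp(beta),
                 ci_low = exp(beta - Z95 * se),
                 ci_high = exp(beta + Z95 * se),
                 n_snp = as.integer(n_snp), extras = extras),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (se %.4f), p = %.3g, OR = %.3f [%.3f, %.3f], %d SNP(s)\n",
              x$method, x$beta, x$se, x$pvalue, x$or_, x$ci_low, x$ci_high, x$n_snp))
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             pvalue = x$pvalue, or = x$or_, ci_low = x$ci_low,
             ci_high = x$ci_high, stringsAsFactors = FALSE)
}

# per-SNP Wald ratios, first-order ses, inverse-variance weights
ratio_set <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  if (any(h$beta_exp == 0)) {
    stop("ratio_set: zero exposure effect gives an undefined ratio", call. = FALSE)
  }
  r <- h$beta_out / h$beta_exp
  r_se <- h$se_out / abs(h$beta_exp)
  list(ratio = r, ratio_se = r_se, weight = 1 / r_se^2)
}

#' Single-SNP Wald ratio estimate
#'
#' beta = beta_out / beta_exp with the first-order standard error
#' se_out / |beta_exp|; an optional second-order se additionally
#' propagates the exposure uncertainty:
#' sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4).
#'
#' @param beta_exp,se_exp exposure effect and se.
#' @param beta_out,se_out outcome effect and se.
#' @param se_order `"first"` or `"second"`.
#' @return an [mr_result()].
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  if (beta_exp == 0) stop("wald_ratio: beta_exp is zero", call. = FALSE)
  b <- beta_out / beta_exp
  se <- if (se_order == "first") {
    se_out / abs(beta_exp)
  } else {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  }
  mr_result("wald_ratio", b, se, two_sided_p_norm(b, se), 1L)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' through the origin with weights 1/se_out^2:
#' beta = sum(bx*by/sy^2) / sum(bx^2/sy^2). Under `"fixed"` the standard
#' error is sqrt(1/sum(bx^2/sy^2)); under `"multiplicative_random"` (the
#' default) it is inflated by sqrt(max(Q/(J-1), 1)) where Q is Cochran's
#' heterogeneity statistic, guarding against overdispersion while never
#' deflating below the fixed-effect se. A single SNP degrades to the
#' Wald ratio.
#'
#' @param h a `harmonized_set`.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return an [mr_result()]; `extras` carries `q_statistic`, `q_df`,
#'   `q_pvalue` when J >= 2.
#' @export
ivw <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  J <- nrow(h)
  if (J < 1L) stop("ivw: empty harmonized set", call. = FALSE)
  if (all(h$beta_exp == 0)) stop("ivw: all exposure effects zero", call. = FALSE)
  if (J == 1L) {
    message("ivw: single SNP, returning Wald ratio")
    res <- wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
    res$method <- "ivw"
    return(res)
  }
  w <- 1 / h$se_out^2
  denom <- sum(h$beta_exp^2 * w)
  beta <- sum(h$beta_exp * h$beta_out * w) / denom
  se_fixed <- sqrt(1 / denom)
  rs <- ratio_set(h)
  q <- sum(rs$weight * (rs$ratio - beta)^2)
  se <- if (model == "fixed") se_fixed else se_fixed * sqrt(max(q / (J - 1), 1))
  mr_result("ivw", beta, se, two_sided_p_norm(beta, se), J,
            extras = list(model = model, q_statistic = q, q_df = J - 1,
                          q_pvalue = stats::pchisq(q, J - 1, lower.tail = FALSE)))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects WITH an
#' intercept, weights 1/se_out^2, after orienting every SNP so that its
#' exposure effect is nonnegative (Egger regression is not invariant to
#' allele recoding; this is the conventional orientation). The slope is
#' the causal estimate; a nonzero intercept indicates directional
#' horizontal pleiotropy. The slope standard error uses multiplicative
#' random-effects scaling, never deflated below 1; the intercept keeps
#' the unscaled exact weighted-regression se so its test retains nominal
#' size. Both p-values use the t distribution with J - 2 df.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return an [mr_result()]; `extras` carries `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p`, `sigma`.
#' @export
mr_egger <- function(h) {
  J <- nrow(h)
  if (J < 3L) stop("mr_egger: at least 3 SNPs required", call. = FALSE)
  flip <- h$beta_exp < 0
  bx <- ifelse(flip, -h$beta_exp, h$beta_exp)
  by <- ifelse(flip, -h$beta_out, h$beta_out)
  w <- 1 / h$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma                      # sqrt(weighted RSS / (J - 2))
  coefs <- sm$coefficients
  slope <- coefs["bx", "Estimate"]
  # lm's reported se already includes sigma; floor sigma at 1 for the slope
  slope_se <- coefs["bx", "Std. Error"] / min(sigma, 1)
  int <- coefs["(Intercept)", "Estimate"]
  int_se <- coefs["(Intercept)", "Std. Error"]
  mr_result("mr_egger", slope, slope_se,
            two_sided_p_t(slope / slope_se, J - 2), J,
            extras = list(egger_intercept = int,
                          egger_intercept_se = int_se,
                          egger_intercept_p = two_sided_p_t(int / int_se, J - 2),
                          sigma = sigma))
}

# weighted median of values x with weights w: sort, standardize cumulative
# weights p_j = (S_j - w_j/2)/S_J, linearly interpolate at p = 0.5
.weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1L] >= 0.5) return(x[1L])
  if (p[length(p)] <= 0.5) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

.boot_perturb <- function(h, n_boot, seed, stat_fn) {
  set.seed(seed)
  J <- nrow(h)
  reps <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(J, h$beta_exp, h$se_exp)
    by <- stats::rnorm(J, h$beta_out, h$se_out)
    bx[bx == 0] <- .Machine$double.eps
    stat_fn(by / bx, h$se_out / abs(bx))
  }, numeric(1))
  stats::sd(reps)
}

#' Weighted-median estimator
#'
#' The weighted median of per-SNP Wald ratios, consistent when up to 50%
#' of the instrument weight comes from invalid instruments. The standard
#' error comes from a seeded parametric bootstrap: exposure and outcome
#' effects are perturbed by their standard errors and the weighted median
#' recomputed.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param n_boot bootstrap replicates for the se (default 1000); 0 skips
#'   the bootstrap and reports `se = NA` (point estimate only).
#' @param seed integer seed for the bootstrap (required when n_boot > 0).
#' @return an [mr_result()].
#' @export
weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  J <- nrow(h)
  if (J < 3L) stop("weighted_median: at least 3 SNPs required", call. = FALSE)
  rs <- ratio_set(h)
  beta <- .weighted_median(rs$ratio, rs$weight)
  if (n_boot > 0) {
    if (is.null(seed)) stop("weighted_median: seed required for bootstrap", call. = FALSE)
    se <- .boot_perturb(h, n_boot, seed,
                        function(r, r_se) .weighted_median(r, 1 / r_se^2))
    p <- two_sided_p_norm(beta, se)
  } else {
    se <- NA_real_; p <- NA_real_
  }
  res <- mr_result("weighted_median", beta, ifelse(is.na(se), 1, se),
                   ifelse(is.na(p), 1, p), J,
                   extras = list(n_boot = n_boot, seed = seed))
  if (is.na(se)) { res$se <- NA_real_; res$pvalue <- NA_real_
                   res$ci_low <- NA_real_; res$ci_high <- NA_real_ }
  res
}

# kernel-density mode of ratios; bandwidth = phi * 0.9 min(sd, mad) J^-1/5
.mode_point <- function(r, w, phi) {
  J <- length(r)
  s <- min(stats::sd(r), stats::mad(r))   # mad() includes the 1.4826 factor
  h_bw <- phi * 0.9 * s * J^(-1 / 5)
  if (!is.finite(h_bw) || h_bw <= 0) return(r[1L])
  d <- stats::density(r, weights = w / sum(w), bw = h_bw,
                      from = min(r) - 3 * h_bw, to = max(r) + 3 * h_bw, n = 512)
  d$x[which.max(d$y)]
}

#' Mode-based estimator (simple and weighted mode)
#'
#' The argmax of a normal-kernel-smoothed density of the per-SNP Wald
#' ratios; consistent when the largest group of instruments sharing the
#' same ratio is valid (the "plurality valid" assumption). The simple
#' mode uses unit weights, the weighted mode inverse-variance weights.
#' Bandwidth = `phi * 0.9 * min(sd, mad) * J^(-1/5)` over the ratios
#' (mad on the normal-consistent scale). If all ratios coincide the
#' common ratio is returned directly. Standard error by seeded
#' parametric bootstrap as in [weighted_median()].
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param weighted use inverse-variance weights (TRUE) or unit weights.
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates (default 1000; 0 skips).
#' @param seed integer seed for the bootstrap.
#' @return an [mr_result()].
#' @export
mode_estimator <- function(h, weighted = FALSE, phi = 1, n_boot = 1000,
                           seed = NULL) {
  J <- nrow(h)
  if (J < 3L) stop("mode_estimator: at least 3 SNPs required", call. = FALSE)
  rs <- ratio_set(h)
  w <- if (weighted) rs$weight else rep(1, J)
  beta <- if (stats::sd(rs$ratio) == 0) rs$ratio[1L] else .mode_point(rs$ratio, w, phi)
  method <- if (weighted) "weighted_mode" else "simple_mode"
  if (n_boot > 0) {
    if (is.null(seed)) stop("mode_estimator: seed required for bootstrap", call. = FALSE)
    se <- .boot_perturb(h, n_boot, seed, function(r, r_se) {
      wb <- if (weighted) 1 / r_se^2 else rep(1, length(r))
      if (stats::sd(r) == 0) r[1L] else .mode_point(r, wb, phi)
    })
    p <- two_sided_p_norm(beta, se)
    mr_result(method, beta, se, p, J,
              extras = list(phi = phi, n_boot = n_boot, seed = seed))
  } else {
    res <- mr_result(method, beta, 1, 1, J, extras = list(phi = phi, n_boot = 0))
    res$se <- NA_real_; res$pvalue <- NA_real_
    res$ci_low <- NA_real_; res$ci_high <- NA_real_
    res
  }
}

#' Run the standard five-estimator panel
#'
#' IVW, MR-Egger, weighted median, simple mode and weighted mode on one
#' harmonized set, returned as a tidy results table (one row per method).
#' Methods whose instrument-count preconditions fail are skipped with a
#' message.
#'
#' @param h a `harmonized_set`.
#' @param n_boot bootstrap replicates for median/mode ses.
#' @param seed master seed; per-method seeds are derived with
#'   [derive_seed()].
#' @param ivw_model IVW error model, see [ivw()].
#' @return data.frame with columns method, exposure, outcome, n_snp,
#'   beta, se, pvalue, or, ci_low, ci_high.
#' @export
mr_all <- function(h, n_boot = 1000, seed = 1L,
                   ivw_model = "multiplicative_random") {
  runs <- list(
    function() ivw(h, model = ivw_model),
    function() mr_egger(h),
    function() weighted_median(h, n_boot, derive_seed(seed, "weighted_median")),
    function() mode_estimator(h, weighted = FALSE, n_boot = n_boot,
                              seed = derive_seed(seed, "simple_mode")),
    function() mode_estimator(h, weighted = TRUE, n_boot = n_boot,
                              seed = derive_seed(seed, "weighted_mode"))
  )
  rows <- list()
  for (f in runs) {
    res <- tryCatch(f(), error = function(e) {
      message("mr_all: skipped a method: ", conditionMessage(e)); NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- as.data.frame(res)
  }
  out <- do.call(rbind, rows)
  out <- data.frame(method = out$method,
                    exposure = attr(h, "exposure_id"),
                    outcome = attr(h, "outcome_id"),
                    out[, c("n_snp", "beta", "se", "pvalue", "or",
                            "ci_low", "ci_high")],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify the causal direction of an MR result
#'
#' Applies the conventional decision rule: if the p-value is at or above
#' `alpha` there is no causal evidence; otherwise a positive effect
#' (OR > 1) marks the exposure as a risk factor and a negative effect
#' (OR < 1) as protective.
#'
#' @param res an [mr_result()].
#' @param alpha significance level (default 0.05).
#' @return one of `"risk"`, `"protective"`, `"no_causal_evidence"`.
#' @export
classify_direction <- function(res, alpha = 0.05) {
  stopifnot(inherits(res, "mr_result"))
  if (is.na(res$pvalue) || res$pvalue >= alpha || res$beta == 0) {
    "no_causal_evidence"
  } else if (res$beta > 0) "risk" else "protective"
}
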