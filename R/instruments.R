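#' Select SNPs by association p-value
#'
#' Keeps exactly the records with `pvalue` strictly below `threshold`
#' (boundary values are excluded), preserving input order.
#'
#' @param panel a [summary_stats()] panel.
#' @param threshold p-value threshold (default `1e-5`, the conventional
#'   genome-wide-suggestive cut for instrument discovery).
#' @return a [summary_stats()] panel (possibly zero-row as a plain subset).
#' @export
select_by_pvalue <- function(panel, threshold = 1e-5) {
  stopifnot(inherits(panel, "summary_stats"),
            is.numeric(threshold), threshold > 0, threshold <= 1)
  keep <- panel$pvalue < threshold
  if (!any(keep)) {
    message(sprintf("select_by_pvalue[%s]: no SNP below %g",
                    attr(panel, "trait_id"), threshold))
  }
  ss_subset(panel, keep)
}

#' Greedy LD clumping
#'
#' Repeatedly takes the not-yet-claimed SNP with the smallest p-value as
#' an index SNP, then discards every unclaimed SNP that is BOTH on the
#' same chromosome within `window_kb` kilobases of the index AND in LD
#' with it above `r2_threshold`. Index SNPs form the result. Ties on
#' p-value are broken by (chromosome, position) ascending, so the output
#' does not depend on input order. SNP pairs absent from the LD matrix
#' are treated as independent (r-squared 0), with a warning listing the
#' missing SNPs.
#'
#' @param candidates a [summary_stats()] panel.
#' @param ld an [ld_matrix()].
#' @param window_kb clumping window in kilobases (default 10000).
#' @param r2_threshold r-squared above which linked SNPs are discarded
#'   (default 0.001).
#' @return the clumped [summary_stats()] panel, in index-selection order.
#' @export
ld_clump <- function(candidates, ld, window_kb = 10000, r2_threshold = 0.001) {
  stopifnot(inherits(candidates, "summary_stats"), inherits(ld, "ld_matrix"))
  n <- nrow(candidates)
  if (n <= 1L) return(candidates)
  missing <- setdiff(candidates$rsid, ld$rsids)
  if (length(missing)) {
    warning(sprintf("ld_clump: %d SNP(s) absent from LD matrix treated as independent: %s",
                    length(missing),
                    paste(utils::head(missing, 5L), collapse = ", ")),
            call. = FALSE)
  }
  ord <- order(candidates$pvalue, candidates$chromosome, candidates$position)
  claimed <- rep(FALSE, n)
  idx_ld <- match(candidates$rsid, ld$rsids)
  kept <- integer(0)
  for (i in ord) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    kept <- c(kept, i)
    near <- !claimed &
      candidates$chromosome == candidates$chromosome[i] &
      abs(candidates$position - candidates$position[i]) <= window_kb * 1000
    if (any(near)) {
      r2_with_index <- rep(0, n)
      if (!is.na(idx_ld[i])) {
        have <- !is.na(idx_ld)
        r2_with_index[have] <- ld$r2[idx_ld[have], idx_ld[i]]
      }
      claimed[near & r2_with_index > r2_threshold] <- TRUE
    }
  }
  ss_subset(candidates, kept)
}

#' Per-SNP instrument-strength F statistic
#'
#' Two forms are offered. `wald`: F = (beta / se)^2, the conventional
#' per-SNP approximation needing only the reported effect and its
#' standard error. `r2_based`: the variance in the exposure explained by
#' the SNP is approximated as r2 = 2 * eaf * (1 - eaf) * beta^2 (additive
#' coding, unit-variance trait), and F = (n - 2) * r2 / (1 - r2).
#'
#' @param beta per-allele effect estimate.
#' @param se its standard error (> 0).
#' @param eaf effect-allele frequency (required for `r2_based`).
#' @param n sample size (required for `r2_based`).
#' @param method `"wald"` (default) or `"r2_based"`.
#' @return nonnegative F statistic (vectorized).
#' @export
f_statistic <- function(beta, se, eaf = NA, n = NA,
                        method = c("wald", "r2_based")) {
  method <- match.arg(method)
  if (method == "wald") {
    stopifnot(all(se > 0))
    (beta / se)^2
  } else {
    if (any(is.na(eaf)) || any(is.na(n))) {
      stop("f_statistic: method 'r2_based' requires eaf and n", call. = FALSE)
    }
    r2 <- 2 * eaf * (1 - eaf) * beta^2
    r2 <- pmin(r2, 1 - 1e-12)
    (n - 2) * r2 / (1 - r2)
  }
}

#' Remove weak instruments by F statistic
#'
#' Keeps records whose F statistic strictly exceeds `f_min` (the
#' customary cut is F > 10) and annotates the survivors with `f_stat`
#' and `r2_explained` (the 2*eaf*(1-eaf)*beta^2 approximation, `NA` when
#' eaf is missing).
#'
#' @param candidates a [summary_stats()] panel.
#' @param f_min minimum F (strict inequality; default 10).
#' @param method F-statistic form, see [f_statistic()].
#' @return an `instrument_set`: the filtered panel with the two extra
#'   columns.
#' @export
filter_weak <- function(candidates, f_min = 10, method = c("wald", "r2_based")) {
  method <- match.arg(method)
  stopifnot(inherits(candidates, "summary_stats"))
  f <- f_statistic(candidates$beta, candidates$se, candidates$eaf,
                   candidates$n, method = method)
  keep <- f > f_min
  out <- ss_subset(candidates, keep)
  out$f_stat <- f[keep]
  out$r2_explained <- ifelse(is.na(out$eaf), NA_real_,
                             2 * out$eaf * (1 - out$eaf) * out$beta^2)
  class(out) <- c("instrument_set", class(out))
  out
}

#' Full instrument-selection pipeline for one exposure
#'
#' p-value threshold, then greedy LD clumping (skipped when `ld` is
#' `NULL`), then the weak-instrument F filter.
#'
#' @param panel a [summary_stats()] panel.
#' @param ld an [ld_matrix()] or `NULL`.
#' @param p_threshold instrument p-value cut (default 1e-5).
#' @param window_kb,r2_threshold clumping parameters.
#' @param f_min,f_method weak-instrument filter parameters.
#' @return an `instrument_set`.
#' @export
select_instruments <- function(panel, ld = NULL, p_threshold = 1e-5,
                               window_kb = 10000, r2_threshold = 0.001,
                               f_min = 10, f_method = "wald") {
  sel <- select_by_pvalue(panel, p_threshold)
  if (nrow(sel) == 0L) {
    out <- sel
    out$f_stat <- numeric(0)
    out$r2_explained <- numeric(0)
    class(out) <- c("instrument_set", class(out))
    return(out)
  }
  if (!is.null(ld)) sel <- ld_clump(sel, ld, window_kb, r2_threshold)
  filter_weak(sel, f_min = f_min, method = f_method)
}

#' Write an instrument set as TSV
#'
#' Summary-stat header plus `f_stat` and `r2_explained`.
#'
#' @param x an `instrument_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(x, path) {
  write_tsv_precise(as.data.frame(x), path)
}
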