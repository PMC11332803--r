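# internal helpers shared across modules

# z quantile for 95% confidence intervals
Z95 <- 1.959964

#' Derive a component seed from a master seed
#'
#' Fans a single master seed out to independent per-component seeds by a
#' fixed string hash, so that adding or removing one stochastic component
#' never shifts the random stream of another.
#'
#' @param master integer master seed.
#' @param component character scalar naming the component
#'   (e.g. `"weighted_median"`, `"presso"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, component) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(component))
  h <- 0
  for (ch in utf8ToInt(component)) h <- (h * 131 + ch) %% 1048573
  as.integer((abs(master) %% 65521) * 32749 + h * 7 + 1) %% 2147483646L + 1L
}

two_sided_p_norm <- function(beta, se) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

two_sided_p_t <- function(stat, df) {
  p <- 2 * stats::pt(-abs(stat), df = df)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# full-precision numeric formatting for deterministic text output
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    sprintf("%.17g", v)
  }, character(1))
  out
}

# write a data.frame as TSV with full numeric precision, deterministically
write_tsv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
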