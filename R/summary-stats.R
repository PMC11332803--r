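#' Construct a validated GWAS summary-statistics panel
#'
#' A panel is a data.frame with one row per SNP and the columns
#' `rsid`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pvalue`, `n`, carrying the trait identity as
#' attributes. Rows violating the per-SNP invariants (`se > 0`,
#' `pvalue` in (0, 1], `eaf` in [0, 1] or missing, effect allele distinct
#' from other allele, finite `beta`) are dropped with a warning; duplicate
#' rsids keep the first occurrence.
#'
#' @param df data.frame with the columns above (`eaf` and `n` may be `NA`).
#' @param trait_id character identifier for the trait.
#' @param trait_role one of `"exposure"`, `"mediator"`, `"outcome"`.
#' @return an object of class `summary_stats` (a data.frame).
#' @export
summary_stats <- function(df, trait_id = "trait", trait_role = "exposure") {
  trait_role <- match.arg(trait_role, c("exposure", "mediator", "outcome"))
  required <- c("rsid", "chromosome", "position", "effect_allele",
                "other_allele", "eaf", "beta", "se", "pvalue", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("summary_stats: missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[required]
  df$rsid <- as.character(df$rsid)
  df$chromosome <- as.character(df$chromosome)
  df$position <- as.integer(df$position)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.numeric(df$n)

  ok <- !is.na(df$rsid) & nzchar(df$rsid) &
    is.finite(df$beta) &
    is.finite(df$se) & df$se > 0 &
    is.finite(df$pvalue) & df$pvalue > 0 & df$pvalue <= 1 &
    (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1)) &
    df$effect_allele != df$other_allele
  ok[is.na(ok)] <- FALSE
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("summary_stats[%s]: dropped %d row(s) failing validation",
                    trait_id, n_bad), call. = FALSE)
    df <- df[ok, , drop = FALSE]
  }
  dup <- duplicated(df$rsid)
  if (any(dup)) {
    warning(sprintf("summary_stats[%s]: dropped %d duplicate rsid row(s)",
                    trait_id, sum(dup)), call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    stop("summary_stats[", trait_id, "]: zero valid rows", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, trait_id = trait_id, trait_role = trait_role,
            class = c("summary_stats", "data.frame"))
}

#' Subset a summary-statistics panel by row, keeping trait attributes
#' @param x a `summary_stats` object.
#' @param i row index.
#' @param ... ignored.
#' @return a `summary_stats` object.
#' @export
ss_subset <- function(x, i, ...) {
  df <- as.data.frame(x)[i, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, trait_id = attr(x, "trait_id"), trait_role = attr(x, "trait_role"),
            class = c("summary_stats", "data.frame"))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs\n",
              attr(x, "trait_id"), attr(x, "trait_role"), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# default GWAS-SSF-like header accepted natively
.ssf_default_map <- c(
  rsid = "rsid", chromosome = "chromosome", position = "base_pair_location",
  effect_allele = "effect_allele", other_allele = "other_allele",
  eaf = "effect_allele_frequency", beta = "beta", se = "standard_error",
  pvalue = "p_value", n = "n"
)

#' Read GWAS summary statistics from a delimited text file
#'
#' Accepts a GWAS-SSF-like header natively (`rsid`, `chromosome`,
#' `base_pair_location`, `effect_allele`, `other_allele`,
#' `effect_allele_frequency`, `beta`, `standard_error`, `p_value`, `n`).
#' Other dialects are mapped through `column_map`, a named character vector
#' whose names are the canonical fields (`rsid`, `chromosome`, `position`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`)
#' and whose values are the column names in the file. Plain or gzipped
#' files are handled transparently. Rows failing validation are dropped
#' with a warning (see [summary_stats()]).
#'
#' `eaf` and `n` are optional: if neither native nor mapped column exists
#' they are filled with `NA` (they are only required for the
#' frequency-based F statistic and for palindrome inference).
#'
#' @param path path to a tab- (or white-space-) delimited file.
#' @param trait_id trait identifier; defaults to the file name.
#' @param trait_role one of `"exposure"`, `"mediator"`, `"outcome"`.
#' @param column_map named character vector overriding the default header
#'   mapping for any subset of fields.
#' @return a [summary_stats()] panel.
#' @export
read_summary_stats <- function(path, trait_id = NULL,
                               trait_role = "exposure", column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  map <- .ssf_default_map
  map["position"] <- "base_pair_location"
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(map))
    if (length(bad)) stop("column_map: unknown field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    map[names(column_map)] <- column_map
  }
  optional <- c("eaf", "n")
  out <- list()
  for (field in names(map)) {
    src <- map[[field]]
    if (src %in% names(raw)) {
      out[[field]] <- raw[[src]]
    } else if (field %in% optional) {
      out[[field]] <- rep(NA_real_, nrow(raw))
    } else {
      stop("read_summary_stats: required column '", src, "' (field '", field,
           "') absent from ", path, call. = FALSE)
    }
  }
  summary_stats(as.data.frame(out, stringsAsFactors = FALSE),
                trait_id = trait_id %||% basename(path),
                trait_role = trait_role)
}

#' Write a summary-statistics panel as GWAS-SSF-like TSV
#'
#' @param ss a [summary_stats()] panel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(ss, path) {
  df <- as.data.frame(ss)
  names(df) <- c("rsid", "chromosome", "base_pair_location", "effect_allele",
                 "other_allele", "effect_allele_frequency", "beta",
                 "standard_error", "p_value", "n")
  write_tsv_precise(df, path)
}
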