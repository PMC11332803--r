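.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome panels onto a shared effect allele
#'
#' Takes the rsid intersection of the two panels and aligns the outcome
#' effects to the exposure's effect allele. When the outcome's
#' effect/other alleles are swapped relative to the exposure, the outcome
#' beta is negated and its allele frequency complemented (`flipped`).
#' SNPs whose allele sets are incompatible are removed. Palindromic SNPs
#' (A/T or C/G) carry no strand information in summary data and are
#' handled per `palindrome_policy`:
#' \describe{
#'   \item{`"drop"`}{always removed (the conservative default).}
#'   \item{`"infer_by_eaf"`}{kept when both panels report an allele
#'     frequency on the same side of 0.5 (frequencies near 0.5, i.e.
#'     within `eaf_tol` of it, or missing, force removal).}
#' }
#'
#' @param exposure,outcome [summary_stats()] panels.
#' @param palindrome_policy `"drop"` or `"infer_by_eaf"`.
#' @param eaf_tol ambiguity band around 0.5 for `infer_by_eaf`.
#' @return an object of class `harmonized_set`: a data.frame with columns
#'   `rsid`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`,
#'   `flipped`, plus attributes `exposure_id`, `outcome_id`,
#'   `palindromic_removed` (rsids), `incompatible_removed` (rsids).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "infer_by_eaf"),
                      eaf_tol = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0L) {
    stop("harmonize: no shared rsids between panels", call. = FALSE)
  }
  ex <- as.data.frame(exposure)[match(shared, exposure$rsid), ]
  ou <- as.data.frame(outcome)[match(shared, outcome$rsid), ]

  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  # A/T and C/G pairs look "swapped" on the opposite strand too; treat the
  # allele-level match as the only usable signal and defer to the policy.
  palin <- .is_palindromic(ex$effect_allele, ex$other_allele)
  compatible <- same | swapped

  keep_palin <- rep(FALSE, length(shared))
  if (palindrome_policy == "infer_by_eaf") {
    both_eaf <- !is.na(ex$eaf) & !is.na(ou$eaf)
    eaf_out_aligned <- ifelse(swapped, 1 - ou$eaf, ou$eaf)
    unambiguous <- both_eaf &
      abs(ex$eaf - 0.5) > eaf_tol & abs(eaf_out_aligned - 0.5) > eaf_tol &
      sign(ex$eaf - 0.5) == sign(eaf_out_aligned - 0.5)
    keep_palin <- unambiguous
  }
  keep <- compatible & (!palin | keep_palin)

  beta_out <- ifelse(swapped, -ou$beta, ou$beta)
  h <- data.frame(
    rsid = ex$rsid,
    chromosome = ex$chromosome,
    position = ex$position,
    beta_exp = ex$beta, se_exp = ex$se,
    beta_out = beta_out, se_out = ou$se,
    eaf_exp = ex$eaf,
    pvalue_exp = ex$pvalue,
    n_exp = ex$n,
    flipped = swapped,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(h) <- NULL
  if (nrow(h) == 0L) {
    stop("harmonize: no SNPs retained after allele alignment", call. = FALSE)
  }
  structure(h,
            exposure_id = attr(exposure, "trait_id"),
            outcome_id = attr(outcome, "trait_id"),
            palindromic_removed = shared[palin & !keep_palin & compatible],
            incompatible_removed = shared[!compatible],
            class = c("harmonized_set", "data.frame"))
}

#' Construct a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for estimator inputs that are already on a
#' shared effect allele (e.g. simulation output or published tables).
#'
#' @param beta_exp,se_exp exposure effects and standard errors.
#' @param beta_out,se_out outcome effects and standard errors.
#' @param rsid SNP identifiers (generated if omitted).
#' @param exposure_id,outcome_id trait labels.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out,
                           rsid = paste0("snp", seq_along(beta_exp)),
                           exposure_id = "exposure", outcome_id = "outcome") {
  stopifnot(length(beta_exp) == length(se_exp),
            length(beta_exp) == length(beta_out),
            length(beta_exp) == length(se_out),
            all(se_exp > 0), all(se_out > 0))
  h <- data.frame(rsid = as.character(rsid),
                  chromosome = NA_character_, position = NA_integer_,
                  beta_exp = as.numeric(beta_exp), se_exp = as.numeric(se_exp),
                  beta_out = as.numeric(beta_out), se_out = as.numeric(se_out),
                  eaf_exp = NA_real_, pvalue_exp = NA_real_, n_exp = NA_real_,
                  flipped = FALSE, stringsAsFactors = FALSE)
  structure(h, exposure_id = exposure_id, outcome_id = outcome_id,
            palindromic_removed = character(0),
            incompatible_removed = character(0),
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s, %d SNPs (%d flipped, %d palindromic removed)\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x),
              sum(x$flipped), length(attr(x, "palindromic_removed"))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Write a harmonized set as TSV
#'
#' Fixed header: `rsid`, `beta_exp`, `se_exp`, `beta_out`, `se_out`,
#' `flipped`.
#'
#' @param h a `harmonized_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path) {
  write_tsv_precise(as.data.frame(h)[, c("rsid", "beta_exp", "se_exp",
                                         "beta_out", "se_out", "flipped")],
                    path)
}
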