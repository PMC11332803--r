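#' Construct a validated LD matrix
#'
#' Pairwise squared-correlation (r-squared) matrix over a set of SNPs.
#' The matrix must be symmetric (to `tol`), have unit diagonal, and all
#' entries in \[0, 1\].
#'
#' @param r2 square numeric matrix of pairwise r-squared values.
#' @param rsids character vector of SNP identifiers (defaults to the
#'   matrix dimnames).
#' @param positions optional integer base-pair coordinates aligned to
#'   `rsids`.
#' @param tol symmetry tolerance.
#' @return an object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, rsids = rownames(r2), positions = NULL, tol = 1e-8) {
  r2 <- as.matrix(r2)
  if (is.null(rsids)) stop("ld_matrix: rsids required", call. = FALSE)
  rsids <- as.character(rsids)
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(rsids)) {
    stop("ld_matrix: dimensions do not match rsids", call. = FALSE)
  }
  if (any(abs(r2 - t(r2)) > tol)) {
    stop("ld_matrix: matrix is asymmetric beyond tolerance ", tol, call. = FALSE)
  }
  r2 <- (r2 + t(r2)) / 2
  if (any(r2 < -tol | r2 > 1 + tol)) {
    stop("ld_matrix: entries outside [0, 1]", call. = FALSE)
  }
  r2 <- pmin(pmax(r2, 0), 1)
  if (any(abs(diag(r2) - 1) > tol)) {
    stop("ld_matrix: diagonal must be exactly 1", call. = FALSE)
  }
  diag(r2) <- 1
  dimnames(r2) <- list(rsids, rsids)
  structure(list(rsids = rsids, r2 = r2, positions = positions),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("LD matrix: %d SNPs\n", length(x$rsids)))
  invisible(x)
}

#' Read an LD matrix from TSV
#'
#' Two layouts are accepted: square (a header row of rsids plus a leading
#' rsid column) and long (three columns `rsid_a`, `rsid_b`, `r2`; missing
#' pairs are treated as r-squared 0, the diagonal is implied).
#'
#' @param path path to the TSV file.
#' @param format `"auto"`, `"square"` or `"long"`.
#' @return an [ld_matrix()].
#' @export
read_ld_matrix <- function(path, format = c("auto", "square", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  if (format == "auto") {
    format <- if (all(c("rsid_a", "rsid_b", "r2") %in% names(raw))) "long" else "square"
  }
  if (format == "long") {
    ids <- sort(unique(c(raw$rsid_a, raw$rsid_b)))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(match(raw$rsid_a, ids), match(raw$rsid_b, ids))] <- raw$r2
    m[cbind(match(raw$rsid_b, ids), match(raw$rsid_a, ids))] <- raw$r2
    diag(m) <- 1
    ld_matrix(m, ids)
  } else {
    ids <- as.character(raw[[1L]])
    m <- as.matrix(raw[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    ld_matrix(m, ids)
  }
}

#' Write an LD matrix as square TSV
#'
#' @param ld an [ld_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(rsid = ld$rsids, as.data.frame(ld$r2),
                   check.names = FALSE)
  write_tsv_precise(df, path)
}
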