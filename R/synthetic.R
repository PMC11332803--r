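# Synthetic two-sample GWAS summary statistics with known causal structure.
#
# Statistics are generated directly at the summary level: for a SNP with
# minor-allele frequency f and a GWAS of n individuals on a unit-variance
# trait, the sampling standard error of the per-allele estimate is
# approximately 1/sqrt(2 f (1-f) n), and the estimated beta is the true
# marginal effect plus independent normal noise of that scale. The three
# panels (exposure, mediator, outcome) use independent noise draws,
# emulating non-overlapping GWAS cohorts.

.nonpalindromic_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                  "G", "A", "C", "A", "G", "T", "C", "T"),
                                ncol = 2, byrow = TRUE)

# place LD blocks 20 Mb apart, 5 kb between SNPs within a block, cycling
# over 22 autosomes so coordinates stay within integer range at any scale
.assign_coords <- function(sizes) {
  n_blocks <- length(sizes)
  chrom_of_block <- ((seq_len(n_blocks) - 1L) %% 22L) + 1L
  idx_on_chrom <- stats::ave(seq_len(n_blocks), chrom_of_block,
                             FUN = seq_along)
  chromosome <- character(sum(sizes))
  position <- integer(sum(sizes))
  i <- 1L
  for (bk in seq_len(n_blocks)) {
    idx <- i:(i + sizes[bk] - 1L)
    chromosome[idx] <- as.character(chrom_of_block[bk])
    position[idx] <- as.integer(1e6 + (idx_on_chrom[bk] - 1L) * 2e7 +
                                  (seq_len(sizes[bk]) - 1L) * 5000)
    i <- i + sizes[bk]
  }
  list(chromosome = chromosome, position = position)
}

.make_panel <- function(rsid, chromosome, position, ea, oa, eaf,
                        true_beta, n, trait_id, trait_role) {
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * n)
  beta <- stats::rnorm(length(true_beta), true_beta, se)
  summary_stats(data.frame(
    rsid = rsid, chromosome = chromosome, position = position,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se, pvalue = two_sided_p_norm(beta, se), n = n,
    stringsAsFactors = FALSE
  ), trait_id = trait_id, trait_role = trait_role)
}

.block_ld <- function(rsids, positions, ld_blocks) {
  J <- length(rsids)
  r2 <- diag(1, J)
  if (!is.null(ld_blocks)) {
    sizes <- ld_blocks$sizes
    within <- ld_blocks$r2 %||% 0.8
    if (sum(sizes) > J) stop("ld_blocks: block sizes exceed SNP count",
                             call. = FALSE)
    start <- 1L
    for (s in sizes) {
      idx <- start:(start + s - 1L)
      r2[idx, idx] <- within
      diag(r2)[idx] <- 1
      start <- start + s
    }
    diag(r2) <- 1
  }
  ld_matrix(r2, rsids, positions = positions)
}

#' Generate a synthetic exposure-mediator-outcome GWAS chain
#'
#' Simulates three summary-statistic panels sharing one SNP set with a
#' known mediation structure. SNPs come in two groups: `j_exposure`
#' exposure instruments with per-SNP effects gamma_j ~ Normal(0,
#' sigma_gamma^2) on the exposure, and `j_mediator` mediator instruments
#' with effects delta_j ~ Normal(0, sigma_delta^2) acting directly on the
#' mediator (emulating the mediator's own GWAS discovery panel, as in a
#' two-sample two-step design where each trait contributes its own
#' instruments). True marginal effects are
#' \itemize{
#'   \item exposure: gamma_j
#'   \item mediator: a * gamma_j + delta_j
#'   \item outcome:  (c_direct + a * b) * gamma_j + b * delta_j + alpha_j
#' }
#' so stage-1 MR (exposure instruments) recovers `a`, stage-2 MR
#' (mediator instruments) recovers `b`, and total-effect MR recovers
#' c_total = c_direct + a * b. alpha_j are horizontal-pleiotropy effects
#' (zero unless requested via `pleiotropy` or [inject_pleiotropy()]).
#' Minor-allele frequencies are Uniform(0.05, 0.5); estimated betas get
#' independent per-panel noise with se = 1/sqrt(2 maf (1-maf) n);
#' p-values are two-sided Wald. The LD matrix is block-diagonal per
#' `ld_blocks` (identity when `NULL`); SNPs within a block are placed
#' 5 kb apart and blocks 20 Mb apart, cycling over the 22 autosomes, so
#' default clumping (10,000 kb, r2 0.001) keeps exactly one SNP per
#' block.
#'
#' @param j_exposure,j_mediator instrument counts for the two groups.
#' @param n_exp,n_med,n_out per-panel GWAS sample sizes.
#' @param a,b,c_direct true stage-1, stage-2 and direct effects.
#' @param sigma_gamma,sigma_delta per-SNP effect scale for each group.
#' @param pleiotropy optional list(mode, magnitude, fraction) applied to
#'   the exposure instruments' outcome effects, see [inject_pleiotropy()].
#' @param ld_blocks optional list(sizes = integer vector, r2 = scalar)
#'   describing LD blocks over the SNPs in order.
#' @param seed integer seed (required; the generator is deterministic
#'   given it).
#' @return list of class `synthetic_chain`: `exposure`, `mediator`,
#'   `outcome` ([summary_stats()] panels), `ld` ([ld_matrix()]), `truth`
#'   (class `synthetic_truth`).
#' @export
generate_chain <- function(j_exposure = 50, j_mediator = 50,
                           n_exp = 50000, n_med = 50000, n_out = 50000,
                           a = 0.3, b = -0.25, c_direct = -0.05,
                           sigma_gamma = 0.15, sigma_delta = 0.15,
                           pleiotropy = NULL, ld_blocks = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("generate_chain: seed required",
                                           call. = FALSE)
  stopifnot(j_exposure >= 1, j_mediator >= 0,
            n_exp >= 100, n_med >= 100, n_out >= 100)
  set.seed(seed)
  J <- j_exposure + j_mediator
  rsid <- sprintf("rs%06d", seq_len(J))
  sizes <- if (is.null(ld_blocks)) rep(1L, J) else {
    s <- ld_blocks$sizes
    c(s, rep(1L, J - sum(s)))
  }
  coords <- .assign_coords(sizes)
  chromosome <- coords$chromosome
  position <- coords$position
  pair <- .nonpalindromic_pairs[sample.int(8, J, replace = TRUE), , drop = FALSE]
  maf <- stats::runif(J, 0.05, 0.5)

  gamma <- c(stats::rnorm(j_exposure, 0, sigma_gamma), rep(0, j_mediator))
  delta <- c(rep(0, j_exposure),
             if (j_mediator > 0) stats::rnorm(j_mediator, 0, sigma_delta) else numeric(0))
  alpha <- rep(0, J)
  c_total <- c_direct + a * b

  true_exp <- gamma
  true_med <- a * gamma + delta
  true_out <- c_total * gamma + b * delta + alpha

  exposure <- .make_panel(rsid, chromosome, position, pair[, 1], pair[, 2],
                          maf, true_exp, n_exp, "exposure", "exposure")
  mediator <- .make_panel(rsid, chromosome, position, pair[, 1], pair[, 2],
                          maf, true_med, n_med, "mediator", "mediator")
  outcome <- .make_panel(rsid, chromosome, position, pair[, 1], pair[, 2],
                         maf, true_out, n_out, "outcome", "outcome")
  truth <- structure(list(
    gamma = gamma, delta = delta, alpha = alpha,
    a_true = a, b_true = b, c_direct_true = c_direct, c_total = c_total,
    maf = maf, rsid = rsid,
    j_exposure = j_exposure, j_mediator = j_mediator,
    n_exp = n_exp, n_med = n_med, n_out = n_out,
    pleiotropy_mode = "none", seed = seed
  ), class = "synthetic_truth")
  bundle <- structure(list(exposure = exposure, mediator = mediator,
                           outcome = outcome,
                           ld = .block_ld(rsid, position, ld_blocks),
                           truth = truth),
                      class = "synthetic_chain")
  if (!is.null(pleiotropy)) {
    bundle <- inject_pleiotropy(bundle, mode = pleiotropy$mode,
                                magnitude = pleiotropy$magnitude,
                                fraction = pleiotropy$fraction %||% 1,
                                seed = derive_seed(seed, "pleiotropy"))
  }
  bundle
}

#' Generate a synthetic exposure-outcome GWAS pair
#'
#' Two panels with `j_x` SNPs instrumenting trait X (effects gamma_j)
#' and `j_y` SNPs instrumenting trait Y (effects delta_j). The forward
#' effect `effect_xy` propagates X instruments onto Y
#' (Y marginal = effect_xy * gamma_j) and the reverse effect `effect_yx`
#' propagates Y instruments onto X, giving a test bed for forward
#' screening and reverse-MR checks.
#'
#' @param j_x,j_y instrument counts.
#' @param n_x,n_y GWAS sample sizes.
#' @param effect_xy,effect_yx forward and reverse causal effects.
#' @param sigma_gamma,sigma_delta per-SNP effect scales.
#' @param seed integer seed (required).
#' @return list with `x`, `y` panels, `ld` (identity) and `truth`.
#' @export
generate_pair <- function(j_x = 30, j_y = 30, n_x = 50000, n_y = 50000,
                          effect_xy = 0, effect_yx = 0,
                          sigma_gamma = 0.15, sigma_delta = 0.15, seed) {
  if (missing(seed) || is.null(seed)) stop("generate_pair: seed required",
                                           call. = FALSE)
  set.seed(seed)
  J <- j_x + j_y
  rsid <- sprintf("rs%06d", seq_len(J))
  coords <- .assign_coords(rep(1L, J))
  chromosome <- coords$chromosome
  position <- coords$position
  pair <- .nonpalindromic_pairs[sample.int(8, J, replace = TRUE), , drop = FALSE]
  maf <- stats::runif(J, 0.05, 0.5)
  gamma <- c(stats::rnorm(j_x, 0, sigma_gamma), rep(0, j_y))
  delta <- c(rep(0, j_x), stats::rnorm(j_y, 0, sigma_delta))
  true_x <- gamma + effect_yx * delta
  true_y <- effect_xy * gamma + delta
  x <- .make_panel(rsid, chromosome, position, pair[, 1], pair[, 2], maf,
                   true_x, n_x, "trait_x", "exposure")
  y <- .make_panel(rsid, chromosome, position, pair[, 1], pair[, 2], maf,
                   true_y, n_y, "trait_y", "outcome")
  list(x = x, y = y,
       ld = ld_matrix(diag(1, J), rsid, positions = position),
       truth = list(gamma = gamma, delta = delta,
                    effect_xy = effect_xy, effect_yx = effect_yx,
                    j_x = j_x, j_y = j_y, seed = seed))
}

#' Generate a multi-exposure screening panel set
#'
#' `k` exposure panels on disjoint SNP blocks plus one shared outcome
#' panel covering every SNP, with per-trait causal effects `effects` on
#' the outcome. Used to exercise forward screening with planted signals.
#'
#' @param effects numeric vector of true exposure-on-outcome effects,
#'   one per trait.
#' @param j_per_trait instruments per exposure.
#' @param n sample size for every panel.
#' @param sigma_gamma per-SNP effect scale.
#' @param seed integer seed (required).
#' @return list with `exposures` (list of panels), `outcome`, `ld`,
#'   `effects`.
#' @export
generate_screen_set <- function(effects, j_per_trait = 20, n = 50000,
                                sigma_gamma = 0.15, seed) {
  if (missing(seed) || is.null(seed)) stop("generate_screen_set: seed required",
                                           call. = FALSE)
  set.seed(seed)
  k <- length(effects)
  J <- k * j_per_trait
  rsid <- sprintf("rs%06d", seq_len(J))
  coords <- .assign_coords(rep(1L, J))
  chromosome <- coords$chromosome
  position <- coords$position
  pair <- .nonpalindromic_pairs[sample.int(8, J, replace = TRUE), , drop = FALSE]
  maf <- stats::runif(J, 0.05, 0.5)
  gamma <- stats::rnorm(J, 0, sigma_gamma)
  out_true <- rep(effects, each = j_per_trait) * gamma
  exposures <- vector("list", k)
  for (t in seq_len(k)) {
    idx <- ((t - 1L) * j_per_trait + 1L):(t * j_per_trait)
    set.seed(derive_seed(seed, paste0("exposure", t)))
    exposures[[t]] <- .make_panel(rsid[idx], chromosome[idx], position[idx],
                                  pair[idx, 1], pair[idx, 2], maf[idx],
                                  gamma[idx], n, paste0("trait_", t), "exposure")
  }
  set.seed(derive_seed(seed, "outcome"))
  outcome <- .make_panel(rsid, chromosome, position, pair[, 1], pair[, 2],
                         maf, out_true, n, "outcome", "outcome")
  list(exposures = exposures, outcome = outcome,
       ld = ld_matrix(diag(1, J), rsid, positions = position),
       effects = effects)
}

#' Inject horizontal pleiotropy into a synthetic chain
#'
#' Adds per-SNP pleiotropic effects alpha_j to the outcome panel's
#' effects over a random `fraction` of the exposure instruments:
#' `balanced` draws alpha_j ~ Normal(0, magnitude^2) (zero mean, inflates
#' heterogeneity without biasing the slope), `directional` sets
#' alpha_j = magnitude on the exposure-increasing allele, i.e. the
#' outcome beta is shifted by magnitude * sign(gamma_j) in the panel's
#' allele coding (biases IVW upward and is detected by the Egger
#' intercept, which regresses on the same orientation). Outcome p-values
#' are recomputed; the truth record is updated so diagnostics can be
#' scored against it.
#'
#' @param bundle a `synthetic_chain` from [generate_chain()].
#' @param mode `"balanced"` or `"directional"`.
#' @param magnitude pleiotropy scale (per-SNP outcome-effect units).
#' @param fraction fraction of exposure instruments affected, in \[0, 1\].
#' @param seed integer seed (required when fraction > 0).
#' @return the modified bundle.
#' @export
inject_pleiotropy <- function(bundle, mode = c("balanced", "directional"),
                              magnitude, fraction = 1, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(bundle, "synthetic_chain"),
            fraction >= 0, fraction <= 1)
  if (fraction == 0) return(bundle)
  if (is.null(seed)) stop("inject_pleiotropy: seed required", call. = FALSE)
  set.seed(seed)
  jx <- bundle$truth$j_exposure
  n_hit <- round(fraction * jx)
  if (n_hit == 0) return(bundle)
  hit <- sort(sample.int(jx, n_hit))
  alpha <- bundle$truth$alpha
  alpha[hit] <- alpha[hit] + if (mode == "balanced") {
    stats::rnorm(n_hit, 0, magnitude)
  } else {
    g <- bundle$truth$gamma[hit]
    magnitude * ifelse(g < 0, -1, 1)    # planted on the exposure-increasing allele
  }
  out <- as.data.frame(bundle$outcome)
  shift <- alpha - bundle$truth$alpha
  out$beta <- out$beta + shift
  out$pvalue <- two_sided_p_norm(out$beta, out$se)
  bundle$outcome <- summary_stats(out, trait_id = attr(bundle$outcome, "trait_id"),
                                  trait_role = "outcome")
  bundle$truth$alpha <- alpha
  bundle$truth$pleiotropy_mode <- mode
  bundle
}

#' Write a synthetic chain to a fixture directory
#'
#' Emits `exposure.tsv`, `mediator.tsv`, `outcome.tsv` (GWAS-SSF-like),
#' `ld.tsv` (square) and `truth.json` with full numeric precision, so
#' re-reading reproduces the in-memory panels exactly and a fixed seed
#' yields byte-identical files.
#'
#' @param bundle a `synthetic_chain`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_chain"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_summary_stats(bundle$exposure, file.path(dir, "exposure.tsv"))
  write_summary_stats(bundle$mediator, file.path(dir, "mediator.tsv"))
  write_summary_stats(bundle$outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(bundle$ld, file.path(dir, "ld.tsv"))
  jsonlite::write_json(unclass(bundle$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic fixture directory back into a chain bundle
#'
#' @param dir directory written by [write_fixture()].
#' @return a `synthetic_chain`.
#' @export
read_fixture <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  structure(list(
    exposure = read_summary_stats(file.path(dir, "exposure.tsv"),
                                  trait_id = "exposure", trait_role = "exposure"),
    mediator = read_summary_stats(file.path(dir, "mediator.tsv"),
                                  trait_id = "mediator", trait_role = "mediator"),
    outcome = read_summary_stats(file.path(dir, "outcome.tsv"),
                                 trait_id = "outcome", trait_role = "outcome"),
    ld = read_ld_matrix(file.path(dir, "ld.tsv")),
    truth = structure(truth, class = "synthetic_truth")
  ), class = "synthetic_chain")
}
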