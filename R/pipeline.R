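#' Build a run configuration
#'
#' Central parameter record for the screening / mediation pipeline.
#' Defaults follow the conventional two-sample MR settings: instrument
#' p < 1e-5, clumping window 10,000 kb at r2 0.001, F > 10, screening
#' and reverse-check level 0.05, IVW as the primary estimator, no
#' multiple-testing adjustment (bonferroni / fdr_bh available).
#'
#' @param p_instrument instrument p-value threshold.
#' @param clump_kb,clump_r2 LD clumping parameters.
#' @param f_min weak-instrument F cut (strict).
#' @param f_method `"wald"` or `"r2_based"`.
#' @param alpha_screen forward-screening significance level (pass when
#'   p strictly below it).
#' @param alpha_reverse reverse-check level (pass when p at or above it).
#' @param estimators which estimators [run_mediation_chain()] runs;
#'   subset of c("ivw", "mr_egger", "weighted_median", "simple_mode",
#'   "weighted_mode").
#' @param ivw_model IVW error model.
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param presso_n_sim MR-PRESSO simulation count (0 disables PRESSO).
#' @param mt_method multiple-testing adjustment for screening p-values:
#'   `"none"`, `"bonferroni"` or `"fdr_bh"`.
#' @param seed master seed; every stochastic component derives its own
#'   stream from it via [derive_seed()].
#' @return a list of class `run_config`.
#' @export
run_config <- function(p_instrument = 1e-5, clump_kb = 10000,
                       clump_r2 = 0.001, f_min = 10, f_method = "wald",
                       alpha_screen = 0.05, alpha_reverse = 0.05,
                       estimators = c("ivw", "mr_egger", "weighted_median",
                                      "simple_mode", "weighted_mode"),
                       ivw_model = "multiplicative_random",
                       n_boot = 1000, presso_n_sim = 1000,
                       mt_method = c("none", "bonferroni", "fdr_bh"),
                       seed = 1L) {
  mt_method <- match.arg(mt_method)
  stopifnot(p_instrument > 0, p_instrument <= 1, clump_kb > 0,
            clump_r2 >= 0, clump_r2 <= 1, f_min >= 0,
            alpha_screen >= 0, alpha_screen <= 1,
            alpha_reverse >= 0, alpha_reverse <= 1,
            n_boot >= 0, presso_n_sim >= 0, is.numeric(seed))
  estimators <- match.arg(estimators, several.ok = TRUE)
  structure(list(p_instrument = p_instrument, clump_kb = clump_kb,
                 clump_r2 = clump_r2, f_min = f_min, f_method = f_method,
                 alpha_screen = alpha_screen, alpha_reverse = alpha_reverse,
                 estimators = estimators, ivw_model = ivw_model,
                 n_boot = n_boot, presso_n_sim = presso_n_sim,
                 mt_method = mt_method, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys take the
#' defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("read_run_config: unknown key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  do.call(run_config, vals)
}

# one exposure -> outcome IVW with instrument selection; NULL-safe
.screen_one <- function(exposure, outcome, ld, cfg) {
  inst <- select_instruments(exposure, ld, cfg$p_instrument, cfg$clump_kb,
                             cfg$clump_r2, cfg$f_min, cfg$f_method)
  if (nrow(inst) < 1L) return(list(res = NULL, reason = "no instruments"))
  h <- tryCatch(harmonize(inst, outcome),
                error = function(e) NULL)
  if (is.null(h)) return(list(res = NULL, reason = "harmonization failed"))
  res <- tryCatch(ivw(h, model = cfg$ivw_model), error = function(e) NULL)
  if (is.null(res)) return(list(res = NULL, reason = "ivw failed"))
  list(res = res, reason = NA_character_)
}

#' Forward-screen exposures against an outcome
#'
#' For each exposure panel: select instruments, harmonize with the
#' outcome, run IVW, and mark the trait as passing when its
#' (optionally multiplicity-adjusted) p-value is strictly below
#' `cfg$alpha_screen`. Per-trait failures (no surviving instruments, no
#' shared SNPs) are recorded, never fatal.
#'
#' @param exposures list of [summary_stats()] panels.
#' @param outcome a [summary_stats()] outcome panel.
#' @param cfg a [run_config()].
#' @param ld an [ld_matrix()] or `NULL` to skip clumping.
#' @return data.frame with one row per exposure: trait_id, direction,
#'   n_snp, beta, se, pvalue, pvalue_adj, passed, reason.
#' @export
forward_screen <- function(exposures, outcome, cfg = run_config(), ld = NULL) {
  stopifnot(length(exposures) >= 1L)
  rows <- lapply(exposures, function(ex) {
    out <- .screen_one(ex, outcome, ld, cfg)
    if (is.null(out$res)) {
      data.frame(trait_id = attr(ex, "trait_id"), direction = "forward",
                 n_snp = 0L, beta = NA_real_, se = NA_real_,
                 pvalue = NA_real_, stringsAsFactors = FALSE,
                 reason = out$reason)
    } else {
      data.frame(trait_id = attr(ex, "trait_id"), direction = "forward",
                 n_snp = out$res$n_snp, beta = out$res$beta, se = out$res$se,
                 pvalue = out$res$pvalue, stringsAsFactors = FALSE,
                 reason = NA_character_)
    }
  })
  tab <- do.call(rbind, rows)
  adj_method <- switch(cfg$mt_method, none = "none",
                       bonferroni = "bonferroni", fdr_bh = "BH")
  tab$pvalue_adj <- if (adj_method == "none") tab$pvalue else
    stats::p.adjust(tab$pvalue, method = adj_method)
  tab$passed <- !is.na(tab$pvalue_adj) & tab$pvalue_adj < cfg$alpha_screen
  rownames(tab) <- NULL
  tab[, c("trait_id", "direction", "n_snp", "beta", "se", "pvalue",
          "pvalue_adj", "passed", "reason")]
}

#' Reverse-MR check
#'
#' Runs MR in the reverse direction (the original outcome as exposure,
#' the screened trait as outcome). The check passes when the reverse IVW
#' p-value is at or above `cfg$alpha_reverse`, i.e. no evidence of
#' reverse causation; a boundary p exactly equal to the level passes.
#'
#' @param outcome_as_exposure the original outcome trait's panel.
#' @param trait_as_outcome the screened trait's panel.
#' @param cfg a [run_config()].
#' @param ld an [ld_matrix()] or `NULL`.
#' @return one-row data.frame as in [forward_screen()] with
#'   direction = "reverse".
#' @export
reverse_check <- function(outcome_as_exposure, trait_as_outcome,
                          cfg = run_config(), ld = NULL) {
  out <- .screen_one(outcome_as_exposure, trait_as_outcome, ld, cfg)
  if (is.null(out$res)) {
    return(data.frame(trait_id = attr(trait_as_outcome, "trait_id"),
                      direction = "reverse", n_snp = 0L, beta = NA_real_,
                      se = NA_real_, pvalue = NA_real_, pvalue_adj = NA_real_,
                      passed = FALSE, reason = out$reason,
                      stringsAsFactors = FALSE))
  }
  data.frame(trait_id = attr(trait_as_outcome, "trait_id"),
             direction = "reverse", n_snp = out$res$n_snp,
             beta = out$res$beta, se = out$res$se, pvalue = out$res$pvalue,
             pvalue_adj = out$res$pvalue,
             passed = out$res$pvalue >= cfg$alpha_reverse,
             reason = NA_character_, stringsAsFactors = FALSE)
}

# run the configured estimator panel on one harmonized set
.estimate_panel <- function(h, cfg, stage) {
  seed <- derive_seed(cfg$seed, stage)
  runs <- list(
    ivw = function() ivw(h, model = cfg$ivw_model),
    mr_egger = function() mr_egger(h),
    weighted_median = function() weighted_median(h, cfg$n_boot,
                                                 derive_seed(seed, "weighted_median")),
    simple_mode = function() mode_estimator(h, weighted = FALSE,
                                            n_boot = cfg$n_boot,
                                            seed = derive_seed(seed, "simple_mode")),
    weighted_mode = function() mode_estimator(h, weighted = TRUE,
                                              n_boot = cfg$n_boot,
                                              seed = derive_seed(seed, "weighted_mode"))
  )
  fits <- list()
  for (m in cfg$estimators) {
    fits[[m]] <- tryCatch(runs[[m]](), error = function(e) {
      message("estimate[", stage, "]: skipped ", m, ": ", conditionMessage(e))
      NULL
    })
  }
  fits[!vapply(fits, is.null, logical(1))]
}

.stage_mr <- function(exposure, outcome, ld, cfg, stage, exclude_rsids = NULL) {
  inst <- select_instruments(exposure, ld, cfg$p_instrument, cfg$clump_kb,
                             cfg$clump_r2, cfg$f_min, cfg$f_method)
  if (!is.null(exclude_rsids)) {
    inst <- ss_subset(inst, !inst$rsid %in% exclude_rsids)
  }
  if (nrow(inst) < 1L) {
    stop("run_mediation_chain[", stage, "]: no instruments survived selection",
         call. = FALSE)
  }
  h <- harmonize(inst, outcome)
  fits <- .estimate_panel(h, cfg, stage)
  diag <- if (cfg$presso_n_sim > 0 && nrow(h) >= 2L) {
    mr_diagnostics(h, n_sim = cfg$presso_n_sim,
                   seed = derive_seed(cfg$seed, paste0(stage, "_diag")))
  } else NULL
  list(harmonized = h, fits = fits, diagnostics = diag)
}

#' Run the full three-MR mediation chain
#'
#' Executes the two-step mediation design on three summary-statistic
#' panels: MR1 exposure -> mediator (stage-1 effect a), MR2 mediator ->
#' outcome (stage-2 effect b), MR3 exposure -> outcome (total effect c),
#' each with the configured estimator panel and sensitivity diagnostics;
#' the mediation decomposition (indirect a*b, direct c - a*b, proportion
#' mediated) uses the IVW triple. Stage 2 instruments the mediator with
#' its own variants: SNPs already instrumenting the exposure are
#' excluded, since their association with the mediator runs through the
#' exposure and their Wald ratio against the outcome estimates the total
#' effect divided by a rather than b.
#'
#' @param exposure,mediator,outcome [summary_stats()] panels. The
#'   mediator must not be the same panel as the exposure.
#' @param cfg a [run_config()].
#' @param ld an [ld_matrix()] covering the SNPs, or `NULL`.
#' @param ci_method CI method for the indirect effect.
#' @return list of class `mediation_chain`: `stages` (per-stage fits and
#'   diagnostics), `mediation` (a [mediate()] result), `estimates`
#'   (long table over stages and estimators, forest-plot-ready),
#'   `diagnostics` (per-stage summary rows), `config`.
#' @export
run_mediation_chain <- function(exposure, mediator, outcome,
                                cfg = run_config(), ld = NULL,
                                ci_method = c("delta", "monte_carlo")) {
  ci_method <- match.arg(ci_method)
  if (identical(as.data.frame(exposure), as.data.frame(mediator))) {
    stop("run_mediation_chain: mediator panel is identical to the exposure panel",
         call. = FALSE)
  }
  if (!"ivw" %in% cfg$estimators) {
    stop("run_mediation_chain: the mediation decomposition requires 'ivw' ",
         "among cfg$estimators", call. = FALSE)
  }
  stage1 <- .stage_mr(exposure, mediator, ld, cfg, "stage1")
  # stage 2 instruments the mediator with its own variants only: SNPs that
  # already instrument the exposure act on the mediator through the
  # exposure, so their mediator-outcome ratio reflects the total effect
  # over a, not b, and they are excluded
  stages <- list(
    stage1 = stage1,
    stage2 = .stage_mr(mediator, outcome, ld, cfg, "stage2",
                       exclude_rsids = stage1$harmonized$rsid),
    total = .stage_mr(exposure, outcome, ld, cfg, "total")
  )
  med <- mediate(stages$stage1$fits$ivw, stages$stage2$fits$ivw,
                 stages$total$fits$ivw, ci_method = ci_method,
                 seed = derive_seed(cfg$seed, "mediation_ci"))
  est <- do.call(rbind, lapply(names(stages), function(s) {
    fits <- stages[[s]]$fits
    tab <- do.call(rbind, lapply(fits, as.data.frame))
    data.frame(stage = s,
               exposure = attr(stages[[s]]$harmonized, "exposure_id"),
               outcome = attr(stages[[s]]$harmonized, "outcome_id"),
               tab, stringsAsFactors = FALSE)
  }))
  rownames(est) <- NULL
  diag_tab <- do.call(rbind, lapply(names(stages), function(s) {
    d <- stages[[s]]$diagnostics
    if (is.null(d)) return(NULL)
    data.frame(stage = s, d$summary, stringsAsFactors = FALSE)
  }))
  structure(list(stages = stages, mediation = med, estimates = est,
                 diagnostics = diag_tab, config = cfg),
            class = "mediation_chain")
}

#' @export
print.mediation_chain <- function(x, ...) {
  cat("Three-MR mediation chain\n")
  print(x$estimates[x$estimates$method == "ivw",
                    c("stage", "exposure", "outcome", "n_snp", "beta", "se",
                      "pvalue")], row.names = FALSE)
  cat("\n")
  print(x$mediation)
  invisible(x)
}

#' Write the mediation-chain report to a directory
#'
#' Emits `estimates.tsv` (forest-table data: one row per stage and
#' estimator), `diagnostics.tsv`, `mediation.tsv` and `mediation.json`,
#' all deterministically formatted so identical inputs and seeds give
#' byte-identical files.
#'
#' @param chain a `mediation_chain`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_chain_report <- function(chain, dir) {
  stopifnot(inherits(chain, "mediation_chain"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tsv_precise(chain$estimates, file.path(dir, "estimates.tsv"))
  if (!is.null(chain$diagnostics)) {
    write_tsv_precise(chain$diagnostics, file.path(dir, "diagnostics.tsv"))
  }
  write_tsv_precise(as.data.frame(chain$mediation), file.path(dir, "mediation.tsv"))
  write_mediation_json(chain$mediation, file.path(dir, "mediation.json"))
  invisible(dir)
}
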