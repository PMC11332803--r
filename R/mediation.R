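#' Indirect (mediated) effect by the product of coefficients
#'
#' The indirect effect of an exposure on an outcome through a mediator is
#' the product a * b of the stage-1 (exposure to mediator) and stage-2
#' (mediator to outcome) effects. Uncertainty via the first-order delta
#' method, se = sqrt(b^2 * a_se^2 + a^2 * b_se^2) with a normal 95% CI,
#' or via seeded Monte-Carlo (independent normal draws of a and b,
#' empirical 2.5/97.5 percentiles of their product).
#'
#' @param a,a_se stage-1 effect and standard error.
#' @param b,b_se stage-2 effect and standard error.
#' @param ci_method `"delta"` (default) or `"monte_carlo"`.
#' @param seed integer seed (required for Monte-Carlo).
#' @param n_draws Monte-Carlo draws (default 1e5).
#' @return list with `indirect`, `se`, `ci_low`, `ci_high`, `ci_method`.
#' @export
indirect_effect <- function(a, a_se, b, b_se,
                            ci_method = c("delta", "monte_carlo"),
                            seed = NULL, n_draws = 1e5) {
  ci_method <- match.arg(ci_method)
  stopifnot(a_se > 0, b_se > 0)
  ind <- a * b
  if (ci_method == "delta") {
    se <- sqrt(b^2 * a_se^2 + a^2 * b_se^2)
    ci <- ind + c(-1, 1) * Z95 * se
  } else {
    if (is.null(seed)) stop("indirect_effect: seed required for monte_carlo",
                            call. = FALSE)
    set.seed(seed)
    draws <- stats::rnorm(n_draws, a, a_se) * stats::rnorm(n_draws, b, b_se)
    se <- stats::sd(draws)
    ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  }
  list(indirect = ind, se = se, ci_low = ci[1L], ci_high = ci[2L],
       ci_method = ci_method)
}

#' Decompose a total effect into direct effect and proportion mediated
#'
#' direct = total - indirect (the c' = c - a*b identity) and
#' proportion mediated = indirect / total. The proportion is undefined
#' (`NA`) when the total effect is zero, and is reported without
#' truncation to \[0, 1\]; `inconsistent` flags the case where indirect
#' and total effects have opposite signs (inconsistent mediation, where
#' the proportion is negative).
#'
#' @param total total effect (exposure to outcome).
#' @param indirect indirect effect a * b.
#' @return list with `direct`, `proportion_mediated`, `inconsistent`.
#' @export
decompose <- function(total, indirect) {
  direct <- total - indirect
  if (total == 0) {
    warning("decompose: total effect is zero; proportion mediated undefined",
            call. = FALSE)
    prop <- NA_real_
  } else {
    prop <- indirect / total
  }
  list(direct = direct, proportion_mediated = prop,
       inconsistent = is.finite(prop) && prop < 0)
}

#' Assemble a full mediation result from three MR fits
#'
#' Combines the stage-1 (exposure to mediator), stage-2 (mediator to
#' outcome) and total (exposure to outcome) MR results into the standard
#' product-method decomposition: indirect = a * b, direct = total -
#' indirect, proportion mediated = indirect / total, with uncertainty on
#' the indirect effect from [indirect_effect()]. All three results must
#' come from the same estimator (the usual choice is IVW).
#'
#' @param stage1,stage2,total [mr_result()] objects from the same method.
#' @param ci_method CI method for the indirect effect, see
#'   [indirect_effect()].
#' @param seed integer seed (Monte-Carlo CI only).
#' @return an object of class `mediation_result`.
#' @export
mediate <- function(stage1, stage2, total,
                    ci_method = c("delta", "monte_carlo"), seed = NULL) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(stage1, "mr_result"), inherits(stage2, "mr_result"),
            inherits(total, "mr_result"))
  methods <- c(stage1$method, stage2$method, total$method)
  if (length(unique(methods)) != 1L) {
    stop("mediate: stage1/stage2/total use different estimators: ",
         paste(methods, collapse = ", "), call. = FALSE)
  }
  ind <- indirect_effect(stage1$beta, stage1$se, stage2$beta, stage2$se,
                         ci_method = ci_method, seed = seed)
  dec <- decompose(total$beta, ind$indirect)
  structure(list(
    a = stage1$beta, a_se = stage1$se, a_p = stage1$pvalue,
    b = stage2$beta, b_se = stage2$se, b_p = stage2$pvalue,
    total = total$beta, total_se = total$se, total_p = total$pvalue,
    indirect = ind$indirect, indirect_se = ind$se,
    indirect_ci_low = ind$ci_low, indirect_ci_high = ind$ci_high,
    direct = dec$direct, proportion_mediated = dec$proportion_mediated,
    inconsistent = dec$inconsistent,
    estimator = methods[1L], ci_method = ci_method, seed = seed
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation analysis (", x$estimator, ")\n", sep = "")
  cat(sprintf("  a (exposure->mediator): %8.4f (se %.4f, p %.3g)\n", x$a, x$a_se, x$a_p))
  cat(sprintf("  b (mediator->outcome):  %8.4f (se %.4f, p %.3g)\n", x$b, x$b_se, x$b_p))
  cat(sprintf("  total (c):              %8.4f (se %.4f, p %.3g)\n",
              x$total, x$total_se, x$total_p))
  cat(sprintf("  indirect (a*b):         %8.4f [%0.4f, %0.4f] (%s)\n",
              x$indirect, x$indirect_ci_low, x$indirect_ci_high, x$ci_method))
  cat(sprintf("  direct (c' = c - a*b):  %8.4f\n", x$direct))
  cat(sprintf("  proportion mediated:    %8.4f%s\n", x$proportion_mediated,
              if (isTRUE(x$inconsistent)) " (inconsistent mediation)" else ""))
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(a = x$a, a_se = x$a_se, b = x$b, b_se = x$b_se,
             total = x$total, total_se = x$total_se,
             indirect = x$indirect, indirect_se = x$indirect_se,
             indirect_ci_low = x$indirect_ci_low,
             indirect_ci_high = x$indirect_ci_high,
             direct = x$direct, proportion_mediated = x$proportion_mediated,
             estimator = x$estimator, ci_method = x$ci_method,
             stringsAsFactors = FALSE)
}

#' Write a mediation result as JSON
#'
#' @param x a `mediation_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mediation_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
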