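#' Two-step MR mediation decomposition
#'
#' Combines three IVW legs — exposure to mediator (`beta1`, path a),
#' mediator to outcome (`beta2`, path b) and exposure to outcome
#' (`beta_all`, total effect) — into the product-of-coefficients
#' decomposition: indirect effect `beta12 = beta1 * beta2`, direct effect
#' `beta_dir = beta_all - beta12`, mediation proportion
#' `beta12 / beta_all` (reported as a percentage). The indirect-effect
#' standard error is the Sobel delta-method form
#' `sqrt(beta1^2 se2^2 + beta2^2 se1^2)` and its p-value a two-sided
#' normal test. The proportion confidence interval uses the delta method
#' on the ratio with the three legs treated as independent (separate
#' cohorts):
#' `var(P) = se12^2 / beta_all^2 + beta12^2 se_all^2 / beta_all^4`.
#'
#' @param leg_a `mr_result` (or list with `estimate`, `se`) for the
#'   exposure-to-mediator leg.
#' @param leg_b Same, mediator to outcome.
#' @param leg_total Same, exposure to outcome (total effect).
#' @param exposure_id,mediator_id,outcome_id Trait labels.
#' @return A one-row `mediation_result` data.frame with the decomposition,
#'   the proportion (percent scale) and its CI, the Sobel p-value, and
#'   pass flags left `NA` until [mediate_retention()] is applied.
#' @export
#' @examples
#' m <- mediate_decompose(list(estimate = -0.125, se = NA),
#'                        list(estimate = -0.223, se = NA),
#'                        list(estimate = 0.168, se = NA))
#' round(m$beta12, 3)          # 0.028
#' round(m$proportion_pct, 2)  # 16.59
mediate_decompose <- function(leg_a, leg_b, leg_total,
                              exposure_id = "exposure", mediator_id = "mediator",
                              outcome_id = "outcome") {
  g <- function(leg, f) as.numeric(leg[[f]][1])
  beta1 <- g(leg_a, "estimate"); se1 <- g(leg_a, "se")
  beta2 <- g(leg_b, "estimate"); se2 <- g(leg_b, "se")
  beta_all <- g(leg_total, "estimate"); se_all <- g(leg_total, "se")
  beta12 <- beta1 * beta2
  beta_dir <- beta_all - beta12
  se12 <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  pval <- if (is.finite(se12) && se12 > 0) p_two_sided(beta12 / se12) else NA_real_
  if (beta_all == 0) {
    warning("total effect is zero: mediation proportion undefined", call. = FALSE)
    prop <- NA_real_
    prop_var <- NA_real_
  } else {
    prop <- beta12 / beta_all
    prop_var <- se12^2 / beta_all^2 + beta12^2 * se_all^2 / beta_all^4
  }
  ci <- if (is.finite(prop_var)) prop + c(-1, 1) * Z95 * sqrt(prop_var) else c(NA_real_, NA_real_)
  out <- data.frame(
    exposure = exposure_id, mediator = mediator_id, outcome = outcome_id,
    beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
    beta_all = beta_all, se_all = se_all,
    beta_dir = beta_dir, beta12 = beta12, se12 = se12,
    proportion = prop,
    proportion_pct = 100 * prop,
    proportion_ci_low = 100 * ci[1], proportion_ci_high = 100 * ci[2],
    pval = pval,
    inconsistent = is.finite(prop) && abs(prop) > 1,
    p_ok = NA, proportion_ok = NA, direction_ok = NA, all_ok = NA,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("mediation_result", "data.frame"))
}

#' Apply pathway retention criteria
#'
#' A mediation pathway is retained when (i) its p-value is below `alpha`,
#' (ii) the mediation proportion exceeds `min_proportion`, and (iii) the
#' indirect and total effects have the same (nonzero) sign.
#'
#' @param m A `mediation_result`.
#' @param alpha Significance level (default 0.05).
#' @param min_proportion Minimum proportion as a fraction (default 0.10).
#' @param pval Override for the pathway p-value; defaults to the Sobel
#'   p-value carried by `m` (useful when an externally computed pathway p
#'   is to be gated instead).
#' @return `m` with `p_ok`, `proportion_ok`, `direction_ok`, `all_ok`
#'   filled in.
#' @export
mediate_retention <- function(m, alpha = 0.05, min_proportion = 0.10, pval = NULL) {
  p <- (pval %||% m$pval)[1]
  m$p_ok <- !is.na(p) && p < alpha
  m$proportion_ok <- is.finite(m$proportion) && m$proportion > min_proportion
  s12 <- sign(m$beta12); sall <- sign(m$beta_all)
  m$direction_ok <- s12 != 0 && sall != 0 && s12 == sall
  m$all_ok <- m$p_ok && m$proportion_ok && m$direction_ok
  m
}

#' @export
print.mediation_result <- function(x, ...) {
  if (nrow(x) != 1L) {
    cat(sprintf("<mediation_result> %d pathways\n", nrow(x)))
    print(as.data.frame(x))
    return(invisible(x))
  }
  cat(sprintf("<mediation_result> %s -> %s -> %s\n",
              x$exposure, x$mediator, x$outcome))
  cat(sprintf("  path a  (beta1)    = %8.3f\n", x$beta1))
  cat(sprintf("  path b  (beta2)    = %8.3f\n", x$beta2))
  cat(sprintf("  total   (beta_all) = %8.3f\n", x$beta_all))
  cat(sprintf("  direct  (beta_dir) = %8.3f\n", x$beta_dir))
  cat(sprintf("  indirect(beta12)   = %8.3f\n", x$beta12))
  if (is.finite(x$proportion_pct)) {
    cat(sprintf("  proportion mediated = %.2f%% (95%% CI %.2f to %.2f)\n",
                x$proportion_pct, x$proportion_ci_low, x$proportion_ci_high))
  }
  if (!is.na(x$pval)) cat(sprintf("  p (indirect effect) = %.4g\n", x$pval))
  if (!is.na(x$all_ok)) {
    cat(sprintf("  retained: %s (p_ok=%s, proportion_ok=%s, direction_ok=%s)\n",
                x$all_ok, x$p_ok, x$proportion_ok, x$direction_ok))
  }
  invisible(x)
}
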