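#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (b_j - b_ivw)^2` over the Wald ratios, with the
#' fixed-effect IVW estimate as center (regardless of the error model used
#' for estimation); p-value from the upper tail of a chi-square with
#' n - 1 degrees of freedom. A single instrument yields Q = 0 with 0
#' degrees of freedom and a missing p-value.
#'
#' @param r A `ratio_estimates` or `harmonized_set`.
#' @return A list with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(r) {
  r <- as_ratios(r)
  n <- nrow(r)
  if (n < 2L) return(list(q_stat = 0, q_df = 0L, q_pval = NA_real_))
  est <- sum(r$w * r$b) / sum(r$w)
  q <- sum(r$w * (r$b - est)^2)
  list(q_stat = q, q_df = n - 1L,
       q_pval = stats::pchisq(q, df = n - 1L, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-uses the [mr_egger()] regression; the intercept's p-value comes from
#' a t distribution with n - 2 degrees of freedom. With fewer than 3
#' instruments the test cannot run and the result is missing with
#' `flag = FALSE` and a warning.
#'
#' @param h A `harmonized_set`.
#' @param alpha Flagging level (default 0.05).
#' @return A list with `intercept`, `se`, `pval`, `flag`.
#' @export
egger_intercept_test <- function(h, alpha = 0.05) {
  if (nrow(h) < 3L) {
    warning("fewer than 3 instruments: Egger intercept test not available", call. = FALSE)
    return(list(intercept = NA_real_, se = NA_real_, pval = NA_real_, flag = FALSE))
  }
  e <- mr_egger(h)
  list(intercept = e$egger_intercept, se = e$egger_intercept_se,
       pval = e$egger_intercept_pval, flag = e$egger_intercept_pval < alpha)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW effect with each instrument omitted in turn and
#' reports whether any single omission flips the sign of the estimate or
#' moves its p-value across `alpha`.
#'
#' @param h A `harmonized_set` with at least 3 variants (fewer returns an
#'   empty table with a warning).
#' @param re_mode IVW error model, as in [mr_ivw()].
#' @param alpha Significance level for the crossing check (default 0.05).
#' @return A data.frame (`omitted_variant_id`, `estimate`, `se`, `pval`,
#'   `sign_change`, `crosses_alpha`) with one row per instrument, carrying
#'   attributes `full_estimate` and `influential` (any flag set).
#' @export
leave_one_out <- function(h, re_mode = c("multiplicative_random", "fixed"), alpha = 0.05) {
  re_mode <- match.arg(re_mode)
  n <- nrow(h)
  if (n < 3L) {
    warning("fewer than 3 instruments: leave-one-out analysis skipped", call. = FALSE)
    return(data.frame(omitted_variant_id = character(0), estimate = numeric(0),
                      se = numeric(0), pval = numeric(0),
                      sign_change = logical(0), crosses_alpha = logical(0)))
  }
  full <- mr_ivw(h, re_mode = re_mode)
  rows <- lapply(seq_len(n), function(i) {
    sub <- h[-i, , drop = FALSE]
    class(sub) <- class(h)
    fit <- mr_ivw(sub, re_mode = re_mode)
    data.frame(omitted_variant_id = h$variant_id[i],
               estimate = fit$estimate, se = fit$se, pval = fit$pval,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$sign_change <- sign(tab$estimate) != sign(full$estimate)
  tab$crosses_alpha <- (tab$pval < alpha) != (full$pval < alpha)
  structure(tab, full_estimate = full$estimate,
            influential = any(tab$sign_change | tab$crosses_alpha))
}

#' Full diagnostics for one harmonized set
#'
#' Bundles Cochran's Q, the Egger intercept test and the leave-one-out
#' table, with boolean flags at the configured level.
#'
#' @param h A `harmonized_set`.
#' @param alpha Level for both flags (default 0.05).
#' @param re_mode IVW error model for the leave-one-out estimates.
#' @return A list of class `mr_diagnostics`: `q_stat`, `q_df`, `q_pval`,
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_pval`,
#'   `loo_table`, `heterogeneity_detected`, `pleiotropy_detected`.
#' @export
mr_diagnostics <- function(h, alpha = 0.05,
                           re_mode = c("multiplicative_random", "fixed")) {
  re_mode <- match.arg(re_mode)
  q <- cochran_q(h)
  eg <- if (nrow(h) >= 3L) {
    egger_intercept_test(h, alpha)
  } else {
    suppressWarnings(egger_intercept_test(h, alpha))
  }
  loo <- if (nrow(h) >= 3L) {
    leave_one_out(h, re_mode = re_mode, alpha = alpha)
  } else {
    suppressWarnings(leave_one_out(h, re_mode = re_mode, alpha = alpha))
  }
  structure(list(
    q_stat = q$q_stat, q_df = q$q_df, q_pval = q$q_pval,
    egger_intercept = eg$intercept, egger_intercept_se = eg$se,
    egger_intercept_pval = eg$pval,
    loo_table = loo,
    heterogeneity_detected = !is.na(q$q_pval) && q$q_pval < alpha,
    pleiotropy_detected = isTRUE(eg$flag)
  ), class = "mr_diagnostics")
}

#' Serialize diagnostics to JSON
#'
#' @param d An `mr_diagnostics`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(d, path) {
  jsonlite::write_json(list(
    Q = d$q_stat, df = d$q_df, p_Q = d$q_pval,
    egger_intercept = d$egger_intercept, p_intercept = d$egger_intercept_pval,
    heterogeneity_detected = d$heterogeneity_detected,
    pleiotropy_detected = d$pleiotropy_detected,
    loo = as.data.frame(d$loo_table)
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
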