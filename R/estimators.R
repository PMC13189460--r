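#' Per-variant Wald ratios
#'
#' For each harmonized variant, the ratio estimate
#' `b_j = beta_out_j / beta_exp_j` with first-order standard error
#' `s_j = se_out_j / |beta_exp_j|` (second-order adds the
#' exposure-uncertainty term `beta_out^2 se_exp^2 / beta_exp^4` under the
#' square root). Inverse-variance weights are `w_j = s_j^-2`. Rows with
#' `beta_exp = 0` are dropped with a warning.
#'
#' @param h A `harmonized_set`.
#' @param se_order 1 (default) or 2.
#' @return A `ratio_estimates` data.frame with columns `variant_id`, `b`,
#'   `s`, `w`.
#' @export
wald_ratios <- function(h, se_order = 1) {
  stopifnot(se_order %in% c(1, 2))
  df <- as.data.frame(h)
  zero <- df$beta_exp == 0
  if (any(zero)) {
    warning(sprintf("%d variant(s) with beta_exp = 0 dropped from ratio estimates", sum(zero)),
            call. = FALSE)
    df <- df[!zero, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop_mrm("no usable variants for ratio estimates", "mrmediate_empty_ratios")
  b <- df$beta_out / df$beta_exp
  s <- if (se_order == 1) {
    df$se_out / abs(df$beta_exp)
  } else {
    sqrt(df$se_out^2 / df$beta_exp^2 + df$beta_out^2 * df$se_exp^2 / df$beta_exp^4)
  }
  structure(data.frame(variant_id = df$variant_id, b = b, s = s, w = s^-2,
                       stringsAsFactors = FALSE),
            class = c("ratio_estimates", "data.frame"))
}

#' @noRd
as_ratios <- function(x, se_order = 1) {
  if (inherits(x, "ratio_estimates")) x else wald_ratios(x, se_order = se_order)
}

#' @noRd
new_mr_result <- function(method, estimate, se, pval, n_snp,
                          egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                          egger_intercept_pval = NA_real_) {
  structure(data.frame(
    method = method, estimate = estimate, se = se,
    ci_low = estimate - Z95 * se, ci_high = estimate + Z95 * se,
    pval = pval, n_snp = as.integer(n_snp),
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_pval = egger_intercept_pval,
    stringsAsFactors = FALSE
  ), class = c("mr_result", "data.frame"))
}

#' Wald-ratio estimate for a single instrument
#'
#' @param h A `harmonized_set` with one row (extra rows error).
#' @return An `mr_result` with method `"wald_ratio"`.
#' @export
mr_wald_ratio <- function(h) {
  r <- as_ratios(h)
  if (nrow(r) != 1L) {
    stop_mrm("mr_wald_ratio requires exactly one instrument", "mrmediate_insufficient_instruments")
  }
  new_mr_result("wald_ratio", r$b, r$s, p_two_sided(r$b / r$s), 1L)
}

#' Inverse-variance weighted estimator
#'
#' Precision-weighted average of the per-variant Wald ratios:
#' `estimate = sum(w b) / sum(w)` with fixed-effect standard error
#' `(sum w)^{-1/2}`. Under the multiplicative random-effects model
#' (default) the fixed SE is inflated by `sqrt(max(Q/(n-1), 1))`, where Q
#' is Cochran's heterogeneity statistic, so the random-effects SE is never
#' smaller than the fixed one. The p-value is a two-sided normal test.
#' With a single instrument the estimate falls back to the Wald ratio.
#'
#' @param h A `harmonized_set` or `ratio_estimates`.
#' @param re_mode `"multiplicative_random"` (default) or `"fixed"`.
#' @param se_order Wald-ratio SE order, see [wald_ratios()].
#' @return An `mr_result` with method `"ivw"` (or `"wald_ratio"` for n = 1).
#' @export
mr_ivw <- function(h, re_mode = c("multiplicative_random", "fixed"), se_order = 1) {
  re_mode <- match.arg(re_mode)
  r <- as_ratios(h, se_order)
  n <- nrow(r)
  if (n < 1L) stop_mrm("no instruments", "mrmediate_insufficient_instruments")
  if (n == 1L) {
    return(new_mr_result("wald_ratio", r$b, r$s, p_two_sided(r$b / r$s), 1L))
  }
  sw <- sum(r$w)
  est <- sum(r$w * r$b) / sw
  se <- sqrt(1 / sw)
  if (re_mode == "multiplicative_random") {
    q <- sum(r$w * (r$b - est)^2)
    se <- se * sqrt(max(q / (n - 1), 1))
  }
  new_mr_result("ivw", est, se, p_two_sided(est / se), n)
}

# Weighted simple linear regression of y on x by explicit normal equations.
# Returns unscaled coefficient SEs (sigma = 1) plus the weighted RSS so
# callers can apply their own dispersion model.
#' @noRd
wreg <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x * x); sxy <- sum(w * x * y)
  det <- sw * sxx - sx * sx
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sxx * sy - sx * sxy) / det
  fit <- intercept + slope * x
  rss <- sum(w * (y - fit)^2)
  # (X'WX)^-1 diagonal
  var_slope <- sw / det
  var_intercept <- sxx / det
  list(slope = slope, intercept = intercept, rss = rss,
       se_slope = sqrt(var_slope), se_intercept = sqrt(var_intercept))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome associations on the exposure
#' associations with an unconstrained intercept, weights `se_out^-2`,
#' after orienting every variant so its exposure association is
#' non-negative. The slope estimates the causal effect; the intercept
#' estimates average directional pleiotropy. Coefficient standard errors
#' use multiplicative overdispersion floored at 1
#' (`max(1, sqrt(RSS_w/(n-2)))`); inference uses a t distribution with
#' n - 2 degrees of freedom.
#'
#' @param h A `harmonized_set` with at least 3 variants.
#' @return An `mr_result` with method `"egger"`; the intercept, its SE and
#'   p-value are carried in the `egger_intercept*` columns.
#' @export
mr_egger <- function(h) {
  df <- as.data.frame(h)
  n <- nrow(df)
  if (n < 3L) stop_mrm("MR-Egger requires at least 3 instruments", "mrmediate_insufficient_instruments")
  flip <- ifelse(df$beta_exp < 0, -1, 1)
  x <- df$beta_exp * flip
  y <- df$beta_out * flip
  w <- df$se_out^-2
  fit <- wreg(x, y, w)
  disp <- max(1, sqrt(fit$rss / (n - 2)))
  se_slope <- fit$se_slope * disp
  se_int <- fit$se_intercept * disp
  p_slope <- 2 * stats::pt(-abs(fit$slope / se_slope), df = n - 2)
  p_int <- 2 * stats::pt(-abs(fit$intercept / se_int), df = n - 2)
  new_mr_result("egger", fit$slope, se_slope, max(p_slope, .Machine$double.xmin), n,
                egger_intercept = fit$intercept, egger_intercept_se = se_int,
                egger_intercept_pval = max(p_int, .Machine$double.xmin))
}

# weighted-median point estimate from ratios b with weights w:
# cumulative standardized weights p_j = (S_j - w_j/2)/S_n over b sorted
# ascending, linearly interpolated at 0.5
#' @noRd
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(b[1])
  if (0.5 >= p[length(p)]) return(b[length(b)])
  stats::approx(p, b, xout = 0.5, ties = "ordered")$y
}

#' @noRd
boot_se <- function(b, s, w, n_boot, seed, point_fun) {
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      point_fun(stats::rnorm(length(b), mean = b, sd = s), w)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median estimator
#'
#' Median of the Wald-ratio distribution weighted by inverse variance:
#' with ratios sorted ascending and standardized cumulative weights
#' `p_j = (S_j - w_j/2)/S_n`, the estimate interpolates the ratios at
#' p = 0.5. The standard error comes from a parametric bootstrap
#' (`b_j* ~ Normal(b_j, s_j)`, re-estimating each replicate); the p-value
#' is a two-sided normal test. Consistent when valid instruments carry at
#' least half the weight.
#'
#' @param r A `ratio_estimates` or `harmonized_set` (n >= 3).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (required).
#' @return An `mr_result` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(r, n_boot = 1000, seed) {
  r <- as_ratios(r)
  n <- nrow(r)
  if (n < 3L) stop_mrm("weighted median requires at least 3 instruments",
                       "mrmediate_insufficient_instruments")
  if (missing(seed) || is.null(seed)) {
    stop_mrm("a seed is required for the bootstrap standard error", "mrmediate_config_error")
  }
  est <- weighted_median_point(r$b, r$w)
  se <- boot_se(r$b, r$s, r$w, n_boot, seed, weighted_median_point)
  new_mr_result("weighted_median", est, se, p_two_sided(est / se), n)
}

# kernel-density mode of ratios b with weights wt (normalized internally);
# bandwidth h0; 512-point grid spanning [min - 3h, max + 3h]; plateau ties
# resolve to the smallest grid value (which.max takes the first maximum)
#' @noRd
mode_point <- function(b, wt, phi, grid_n = 512L) {
  s_b <- stats::sd(b)
  raw_mad <- stats::mad(b, constant = 1)
  h0 <- 0.9 * min(s_b, raw_mad / 0.6745) * length(b)^(-1 / 5)
  if (!is.finite(h0) || h0 == 0) h0 <- 0.9 * s_b * length(b)^(-1 / 5)
  if (!is.finite(h0) || h0 == 0) return(b[1]) # all ratios identical
  h <- phi * h0
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = grid_n)
  wt <- wt / sum(wt)
  dens <- as.vector(exp(-(outer(grid, b, "-") / h)^2 / 2) %*% wt) # common kernel constants cancel in the argmax
  grid[which.max(dens)]
}

#' Mode-based estimators
#'
#' Kernel-smoothed mode of the Wald-ratio distribution: a normal-kernel
#' density with bandwidth `phi * 0.9 * min(sd(b), MAD(b)/0.6745) * n^(-1/5)`
#' is evaluated on a 512-point grid over `[min(b) - 3h, max(b) + 3h]` and
#' the estimate is its argmax (ties resolve to the smallest grid value).
#' The simple mode weights every ratio equally; the weighted mode weights
#' by inverse variance. Standard errors use the same parametric bootstrap
#' as [mr_weighted_median()]. Consistent when the largest cluster of
#' instruments is valid.
#'
#' @param r A `ratio_estimates` or `harmonized_set` (n >= 3).
#' @param weighted Use inverse-variance weights (`TRUE`) or uniform
#'   weights (`FALSE`).
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (required).
#' @return An `mr_result` with method `"weighted_mode"` or `"simple_mode"`.
#' @export
mr_mode <- function(r, weighted = TRUE, phi = 1, n_boot = 1000, seed) {
  r <- as_ratios(r)
  n <- nrow(r)
  if (n < 3L) stop_mrm("mode estimators require at least 3 instruments",
                       "mrmediate_insufficient_instruments")
  if (phi <= 0) stop_mrm("phi must be positive", "mrmediate_validation_error")
  if (missing(seed) || is.null(seed)) {
    stop_mrm("a seed is required for the bootstrap standard error", "mrmediate_config_error")
  }
  wt <- if (weighted) r$w else rep(1, n)
  point <- function(b, w) mode_point(b, w, phi)
  est <- point(r$b, wt)
  se <- boot_se(r$b, r$s, wt, n_boot, seed, point)
  method <- if (weighted) "weighted_mode" else "simple_mode"
  new_mr_result(method, est, se, p_two_sided(est / se), n)
}

#' Run all five MR estimators
#'
#' Applies IVW (primary), MR-Egger, weighted median, simple mode and
#' weighted mode to one harmonized set; estimators whose instrument-count
#' requirement is not met are omitted. With a single instrument only the
#' Wald ratio is reported.
#'
#' @param h A `harmonized_set`.
#' @param config An [mr_config()]; supplies `re_mode`, `n_boot`, `phi`,
#'   `ratio_se_order` and the seed the bootstrap sub-streams derive from.
#' @return A data.frame of `mr_result` rows, one per method, with
#'   `exposure` and `outcome` columns prepended.
#' @export
mr_all <- function(h, config = mr_config(seed = 1)) {
  n <- nrow(h)
  res <- list(mr_ivw(h, re_mode = config$re_mode, se_order = config$ratio_se_order))
  if (n >= 3L) {
    r <- wald_ratios(h, se_order = config$ratio_se_order)
    seed0 <- config$seed %||% 1
    res <- c(res, list(
      mr_egger(h),
      mr_weighted_median(r, n_boot = config$n_boot, seed = derive_seed(seed0, 1)),
      mr_mode(r, weighted = FALSE, phi = config$phi, n_boot = config$n_boot,
              seed = derive_seed(seed0, 2)),
      mr_mode(r, weighted = TRUE, phi = config$phi, n_boot = config$n_boot,
              seed = derive_seed(seed0, 3))
    ))
  }
  out <- do.call(rbind, res)
  out <- cbind(data.frame(exposure = attr(h, "exposure_id") %||% "exposure",
                          outcome = attr(h, "outcome_id") %||% "outcome",
                          stringsAsFactors = FALSE)[rep(1, nrow(out)), , drop = FALSE],
               out)
  rownames(out) <- NULL
  out
}
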