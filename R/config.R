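#' Analysis configuration
#'
#' Assemble and validate the configuration used by every stage of the
#' pipeline. Defaults follow the conventions of microbiome / pQTL
#' two-sample MR screens: a suggestive threshold (5e-6) for polygenic
#' exposures such as microbial taxa, genome-wide significance (5e-8) for
#' protein quantitative trait loci, a 10,000 kb clumping window with an
#' r-squared cutoff of 0.1, and exclusion of instruments with F < 10.
#'
#' @param p_threshold_exposure Instrument p-value threshold for exposure
#'   traits (default `5e-6`).
#' @param p_threshold_pqtl Instrument p-value threshold for molecular
#'   mediator traits (default `5e-8`).
#' @param window_kb Clumping window in kilobases (default `10000`).
#' @param r2_cutoff LD r-squared at or above which a variant is clumped to a
#'   more significant index variant (default `0.1`; retention requires
#'   r2 strictly below the cutoff).
#' @param min_f Minimum per-variant F-statistic, `(beta/se)^2` (default `10`).
#' @param alpha Significance level used for leg significance and for the
#'   heterogeneity / pleiotropy exclusion gates (default `0.05`).
#' @param min_proportion Minimum mediation proportion (as a fraction) for a
#'   pathway to be retained (default `0.10`).
#' @param re_mode IVW error model: `"multiplicative_random"` (default;
#'   inflates the fixed-effect SE by `sqrt(max(Q/(n-1), 1))`) or `"fixed"`.
#' @param n_boot Parametric-bootstrap replicates for median/mode standard
#'   errors (default `1000`).
#' @param phi Mode-estimator bandwidth multiplier (default `1`).
#' @param palindrome_eaf_window Half-width of the allele-frequency ambiguity
#'   zone around 0.5 within which palindromic variants are dropped
#'   (default `0.08`).
#' @param ratio_se_order `1` (default) for the first-order Wald-ratio SE
#'   `se_out/|beta_exp|`, `2` to add the exposure-uncertainty term.
#' @param proportion_ci_method `"delta"` (default) or `"bootstrap"` for the
#'   mediation-proportion confidence interval.
#' @param missing_ld Policy for variant pairs absent from the LD input:
#'   `"zero"` (default; treated as unlinked and retained) or `"drop"`.
#' @param seed Master seed; every stochastic component derives its own
#'   sub-stream from it. Required whenever a stochastic step runs.
#'
#' @return A validated list of class `mr_config`.
#' @export
#' @examples
#' cfg <- mr_config(seed = 1)
#' cfg$p_threshold_exposure
mr_config <- function(p_threshold_exposure = 5e-6,
                      p_threshold_pqtl = 5e-8,
                      window_kb = 10000,
                      r2_cutoff = 0.1,
                      min_f = 10,
                      alpha = 0.05,
                      min_proportion = 0.10,
                      re_mode = c("multiplicative_random", "fixed"),
                      n_boot = 1000,
                      phi = 1,
                      palindrome_eaf_window = 0.08,
                      ratio_se_order = 1,
                      proportion_ci_method = c("delta", "bootstrap"),
                      missing_ld = c("zero", "drop"),
                      seed = NULL) {
  cfg <- list(
    p_threshold_exposure = p_threshold_exposure,
    p_threshold_pqtl = p_threshold_pqtl,
    window_kb = window_kb,
    r2_cutoff = r2_cutoff,
    min_f = min_f,
    alpha = alpha,
    min_proportion = min_proportion,
    re_mode = match.arg(re_mode),
    n_boot = n_boot,
    phi = phi,
    palindrome_eaf_window = palindrome_eaf_window,
    ratio_se_order = ratio_se_order,
    proportion_ci_method = match.arg(proportion_ci_method),
    missing_ld = match.arg(missing_ld),
    seed = seed
  )
  validate_config(cfg)
  structure(cfg, class = "mr_config")
}

#' @noRd
validate_config <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!ok) stop_mrm(sprintf("config key '%s' %s", key, what), "mrmediate_config_error")
  }
  in01 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0 && x < 1
  chk(in01(cfg$p_threshold_exposure), "p_threshold_exposure", "must be in (0,1)")
  chk(in01(cfg$p_threshold_pqtl), "p_threshold_pqtl", "must be in (0,1)")
  chk(is.numeric(cfg$window_kb) && cfg$window_kb > 0, "window_kb", "must be positive")
  chk(is.numeric(cfg$r2_cutoff) && cfg$r2_cutoff > 0 && cfg$r2_cutoff <= 1,
      "r2_cutoff", "must be in (0,1]")
  chk(is.numeric(cfg$min_f) && cfg$min_f >= 0, "min_f", "must be non-negative")
  chk(in01(cfg$alpha), "alpha", "must be in (0,1)")
  chk(is.numeric(cfg$min_proportion) && cfg$min_proportion >= 0 && cfg$min_proportion < 1,
      "min_proportion", "must be in [0,1)")
  chk(is.numeric(cfg$n_boot) && cfg$n_boot >= 1, "n_boot", "must be >= 1")
  chk(is.numeric(cfg$phi) && cfg$phi > 0, "phi", "must be positive")
  chk(is.numeric(cfg$palindrome_eaf_window) && cfg$palindrome_eaf_window >= 0 &&
        cfg$palindrome_eaf_window < 0.5, "palindrome_eaf_window", "must be in [0,0.5)")
  chk(cfg$ratio_se_order %in% c(1, 2), "ratio_se_order", "must be 1 or 2")
  if (!is.null(cfg$seed)) {
    chk(is.numeric(cfg$seed) && is.finite(cfg$seed), "seed", "must be a finite number")
  }
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a YAML file of configuration keys, fills defaults for keys not
#' present, and validates the result. Unknown keys raise an error so typos
#' do not silently fall back to defaults.
#'
#' @param path Path to a YAML file (an empty file yields all defaults).
#' @return An `mr_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_mrm(paste0("config file not found: ", path), "mrmediate_io_error")
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(mr_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop_mrm(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
             "mrmediate_config_error")
  }
  do.call(mr_config, vals)
}

#' Write a configuration file
#'
#' Serializes an `mr_config` to YAML so that `load_config(dump_config(cfg))`
#' round-trips to an identical configuration.
#'
#' @param cfg An `mr_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mr_config"))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' Write a run report
#'
#' Emits a JSON provenance record for a completed run: package version,
#' effective configuration, seed, per-stage counts and wall time. Every
#' results table produced by [screen()] can be traced back to one report
#' through its run id.
#'
#' @param counts Named list of per-stage counts (from [screen()]'s audit).
#' @param cfg The effective `mr_config`.
#' @param path Output JSON path.
#' @param run_id Optional identifier; derived from the seed when omitted.
#' @param elapsed Optional wall time in seconds.
#' @param complete Logical; `FALSE` marks partial output from an
#'   interrupted run as invalid.
#' @return The report list, invisibly.
#' @export
run_report <- function(counts, cfg, path, run_id = NULL, elapsed = NA_real_,
                       complete = TRUE) {
  rep <- list(
    run_id = run_id %||% sprintf("run-seed%s", format(cfg$seed %||% "none")),
    package = "mrmediate",
    version = as.character(utils::packageVersion("mrmediate")),
    complete = isTRUE(complete),
    valid = isTRUE(complete),
    seed = cfg$seed,
    config = unclass(cfg)[!vapply(cfg, is.null, logical(1))],
    counts = counts,
    elapsed_sec = elapsed
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rep)
}
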