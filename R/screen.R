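#' Analyze one exposure-outcome pair end to end
#'
#' Runs the full single-pair pipeline: instrument selection (p-value
#' threshold, LD clumping, F filter), harmonization, the five MR
#' estimators and the diagnostics, then applies the exclusion gates: a
#' pair with a heterogeneity p-value below `alpha` is marked
#' `excluded_heterogeneity`, one with an Egger intercept p below `alpha`
#' `excluded_pleiotropy`; pairs with no usable instruments are
#' `insufficient_instruments` (not an error). Diagnostics that cannot be
#' computed (too few instruments) do not exclude.
#'
#' @param exposure A [sumstats] for the exposure side of this leg.
#' @param outcome A [sumstats] for the outcome side.
#' @param ld An [ld_info] covering the exposure's candidate instruments.
#' @param config An [mr_config()].
#' @param p_threshold Instrument threshold; defaults to
#'   `config$p_threshold_pqtl` when the exposure's role is `"mediator"`
#'   and `config$p_threshold_exposure` otherwise.
#' @return A `pair_record` list: `exposure_id`, `outcome_id`, `status`,
#'   `n_instruments`, `primary` (IVW `mr_result` or `NULL`), `secondary`
#'   (other methods), `diagnostics`, `selection_log`,
#'   `harmonization_log`.
#' @export
run_pair <- function(exposure, outcome, ld, config = mr_config(seed = 1),
                     p_threshold = NULL) {
  p_thr <- p_threshold %||%
    if (identical(attr(exposure, "trait_role"), "mediator")) {
      config$p_threshold_pqtl
    } else {
      config$p_threshold_exposure
    }
  rec <- list(exposure_id = attr(exposure, "trait_id") %||% "exposure",
              outcome_id = attr(outcome, "trait_id") %||% "outcome",
              status = "ok", n_instruments = 0L,
              primary = NULL, secondary = NULL, diagnostics = NULL,
              selection_log = NULL, harmonization_log = NULL)
  inst <- select_instruments(exposure, ld,
                             p_threshold = p_thr, window_kb = config$window_kb,
                             r2_cutoff = config$r2_cutoff, min_f = config$min_f,
                             missing_ld = config$missing_ld)
  rec$selection_log <- attr(inst, "selection_log")
  if (nrow(inst) == 0L) {
    rec$status <- "insufficient_instruments"
    return(structure(rec, class = "pair_record"))
  }
  h <- tryCatch(
    harmonize(inst, outcome, palindrome_eaf_window = config$palindrome_eaf_window),
    mrmediate_empty_harmonization = function(e) NULL
  )
  if (is.null(h)) {
    rec$status <- "insufficient_instruments"
    return(structure(rec, class = "pair_record"))
  }
  rec$harmonization_log <- attr(h, "harmonization_log")
  rec$n_instruments <- nrow(h)
  all_res <- mr_all(h, config)
  rec$primary <- all_res[all_res$method %in% c("ivw", "wald_ratio"), , drop = FALSE]
  rec$secondary <- all_res[!all_res$method %in% c("ivw", "wald_ratio"), , drop = FALSE]
  d <- suppressWarnings(mr_diagnostics(h, alpha = config$alpha, re_mode = config$re_mode))
  rec$diagnostics <- d
  # directional pleiotropy is the more specific diagnosis, so it takes
  # precedence when both tests fire
  if (d$pleiotropy_detected) {
    rec$status <- "excluded_pleiotropy"
  } else if (d$heterogeneity_detected) {
    rec$status <- "excluded_heterogeneity"
  }
  structure(rec, class = "pair_record")
}

#' @export
print.pair_record <- function(x, ...) {
  cat(sprintf("<pair_record> %s -> %s [%s], %d instruments\n",
              x$exposure_id, x$outcome_id, x$status, x$n_instruments))
  if (!is.null(x$primary)) print(as.data.frame(x$primary))
  invisible(x)
}

#' Assemble a screening manifest
#'
#' @param exposures,mediators,outcomes Lists of [sumstats] objects, or
#'   character vectors of file paths readable by [read_sumstats()].
#' @param ld An [ld_info], or a path readable by [read_ld()].
#' @return A `screen_manifest` list.
#' @export
screen_manifest <- function(exposures, mediators, outcomes, ld) {
  load_role <- function(x, role) {
    if (is.character(x)) x <- as.list(x)
    out <- lapply(x, function(el) {
      if (is.character(el)) read_sumstats(el, trait_role = role) else el
    })
    names(out) <- vapply(out, function(s) attr(s, "trait_id"), character(1))
    out
  }
  if (is.character(ld)) ld <- read_ld(ld)
  m <- list(exposures = load_role(exposures, "exposure"),
            mediators = load_role(mediators, "mediator"),
            outcomes = load_role(outcomes, "outcome"),
            ld = ld)
  if (!length(m$exposures) || !length(m$mediators) || !length(m$outcomes)) {
    stop_mrm("manifest needs at least one trait per role", "mrmediate_validation_error")
  }
  structure(m, class = "screen_manifest")
}

#' @noRd
pair_row <- function(p) {
  pri <- p$primary
  data.frame(
    exposure = p$exposure_id, outcome = p$outcome_id, status = p$status,
    nsnp = p$n_instruments,
    method = if (!is.null(pri)) pri$method else NA_character_,
    b = if (!is.null(pri)) pri$estimate else NA_real_,
    se = if (!is.null(pri)) pri$se else NA_real_,
    ci_low = if (!is.null(pri)) pri$ci_low else NA_real_,
    ci_high = if (!is.null(pri)) pri$ci_high else NA_real_,
    pval = if (!is.null(pri)) pri$pval else NA_real_,
    q_pval = if (!is.null(p$diagnostics)) p$diagnostics$q_pval else NA_real_,
    egger_intercept_pval = if (!is.null(p$diagnostics)) p$diagnostics$egger_intercept_pval else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Screen a trait grid for mediation pathways
#'
#' Orchestrates the full two-step MR mediation screen over a manifest:
#' every exposure-outcome total effect, every exposure-mediator leg and
#' every mediator-outcome leg is analyzed with [run_pair()]; legs must
#' have status `ok` and a primary p-value below `config$alpha` to enter a
#' candidate pathway; candidates are decomposed with
#' [mediate_decompose()] and gated with [mediate_retention()]. Row order
#' of every output table is deterministic (sorted by trait ids), so the
#' result does not depend on manifest order.
#'
#' @param manifest A [screen_manifest()].
#' @param config An [mr_config()].
#' @return A list of class `screen_result`: `totals`, `leg_a`, `leg_b`
#'   (per-pair tables with status and diagnostics p-values), `mediation`
#'   (all candidate decompositions with retention flags), `retained`
#'   (subset with `all_ok`), and `audit` (per-stage counts).
#' @export
screen <- function(manifest, config = mr_config(seed = 1)) {
  stopifnot(inherits(manifest, "screen_manifest"))
  exps <- manifest$exposures[order(names(manifest$exposures))]
  meds <- manifest$mediators[order(names(manifest$mediators))]
  outs <- manifest$outcomes[order(names(manifest$outcomes))]
  ld <- manifest$ld
  pairs_to_df <- function(pl) {
    df <- do.call(rbind, lapply(pl, pair_row))
    rownames(df) <- NULL
    df
  }
  totals <- list(); leg_a <- list(); leg_b <- list()
  rec_tot <- list(); rec_a <- list(); rec_b <- list()
  for (o in outs) {
    oid <- attr(o, "trait_id")
    for (e in exps) {
      key <- paste(attr(e, "trait_id"), oid, sep = "|")
      rec_tot[[key]] <- run_pair(e, o, ld, config)
    }
    for (m in meds) {
      key <- paste(attr(m, "trait_id"), oid, sep = "|")
      rec_b[[key]] <- run_pair(m, o, ld, config)
    }
  }
  for (m in meds) {
    mid <- attr(m, "trait_id")
    for (e in exps) {
      key <- paste(attr(e, "trait_id"), mid, sep = "|")
      rec_a[[key]] <- run_pair(e, m, ld, config)
    }
  }
  totals <- pairs_to_df(rec_tot)
  leg_a <- pairs_to_df(rec_a)
  leg_b <- pairs_to_df(rec_b)
  ok_sig <- function(df) df$status == "ok" & !is.na(df$pval) & df$pval < config$alpha
  tot_ok <- totals[ok_sig(totals), , drop = FALSE]
  a_ok <- leg_a[ok_sig(leg_a), , drop = FALSE]
  b_ok <- leg_b[ok_sig(leg_b), , drop = FALSE]
  med_rows <- list()
  for (oid in sort(names(outs))) {
    for (eid in sort(names(exps))) {
      if (!any(tot_ok$exposure == eid & tot_ok$outcome == oid)) next
      for (mid in sort(names(meds))) {
        if (!any(a_ok$exposure == eid & a_ok$outcome == mid)) next
        if (!any(b_ok$exposure == mid & b_ok$outcome == oid)) next
        la <- rec_a[[paste(eid, mid, sep = "|")]]$primary
        lb <- rec_b[[paste(mid, oid, sep = "|")]]$primary
        lt <- rec_tot[[paste(eid, oid, sep = "|")]]$primary
        dec <- mediate_decompose(la, lb, lt, exposure_id = eid,
                                 mediator_id = mid, outcome_id = oid)
        med_rows[[paste(eid, mid, oid, sep = "|")]] <-
          mediate_retention(dec, alpha = config$alpha,
                            min_proportion = config$min_proportion)
      }
    }
  }
  mediation <- if (length(med_rows)) {
    out <- do.call(rbind, med_rows)
    rownames(out) <- NULL
    out
  } else {
    mediate_empty()
  }
  retained <- mediation[!is.na(mediation$all_ok) & mediation$all_ok, , drop = FALSE]
  audit <- list(
    n_exposures = length(exps), n_mediators = length(meds), n_outcomes = length(outs),
    n_total_pairs = nrow(totals), n_total_ok_sig = nrow(tot_ok),
    n_leg_a_pairs = nrow(leg_a), n_leg_a_ok_sig = nrow(a_ok),
    n_leg_b_pairs = nrow(leg_b), n_leg_b_ok_sig = nrow(b_ok),
    n_candidates = nrow(mediation), n_retained = nrow(retained),
    n_tests = nrow(totals) + nrow(leg_a) + nrow(leg_b)
  )
  structure(list(totals = totals, leg_a = leg_a, leg_b = leg_b,
                 mediation = mediation, retained = retained,
                 audit = audit,
                 pair_records = list(total = rec_tot, a = rec_a, b = rec_b)),
            class = "screen_result")
}

#' @noRd
mediate_empty <- function() {
  structure(data.frame(
    exposure = character(0), mediator = character(0), outcome = character(0),
    beta1 = numeric(0), se1 = numeric(0), beta2 = numeric(0), se2 = numeric(0),
    beta_all = numeric(0), se_all = numeric(0), beta_dir = numeric(0),
    beta12 = numeric(0), se12 = numeric(0), proportion = numeric(0),
    proportion_pct = numeric(0), proportion_ci_low = numeric(0),
    proportion_ci_high = numeric(0), pval = numeric(0), inconsistent = logical(0),
    p_ok = logical(0), proportion_ok = logical(0), direction_ok = logical(0),
    all_ok = logical(0), stringsAsFactors = FALSE
  ), class = c("mediation_result", "data.frame"))
}

#' @export
print.screen_result <- function(x, ...) {
  a <- x$audit
  cat(sprintf("<screen_result> %d exposures x %d mediators x %d outcomes\n",
              a$n_exposures, a$n_mediators, a$n_outcomes))
  cat(sprintf("  legs ok & significant: total %d/%d, a %d/%d, b %d/%d\n",
              a$n_total_ok_sig, a$n_total_pairs, a$n_leg_a_ok_sig, a$n_leg_a_pairs,
              a$n_leg_b_ok_sig, a$n_leg_b_pairs))
  cat(sprintf("  candidate pathways: %d, retained: %d (of %d tests run)\n",
              a$n_candidates, a$n_retained, a$n_tests))
  if (nrow(x$retained)) {
    print(as.data.frame(x$retained[, c("exposure", "mediator", "outcome",
                                       "beta1", "beta2", "beta_all",
                                       "proportion_pct", "pval")]))
  }
  invisible(x)
}

#' Write all screening outputs to a directory
#'
#' Emits `totals.tsv`, `leg_a.tsv`, `leg_b.tsv`, `mediation.tsv`,
#' `retained.tsv` and a JSON run report.
#'
#' @param res A `screen_result`.
#' @param dir Output directory (created if needed).
#' @param config The `mr_config` used for the run.
#' @return `dir`, invisibly.
#' @export
write_screen <- function(res, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    utils::write.table(format_tsv_num(df), file.path(dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }
  wt(res$totals, "totals.tsv")
  wt(res$leg_a, "leg_a.tsv")
  wt(res$leg_b, "leg_b.tsv")
  wt(res$mediation, "mediation.tsv")
  wt(res$retained, "retained.tsv")
  run_report(res$audit, config, file.path(dir, "run_report.json"))
  invisible(dir)
}

# render numerics at 6 significant digits for stable on-disk tables
#' @noRd
format_tsv_num <- function(df) {
  df <- as.data.frame(df)
  for (cn in names(df)) {
    if (is.numeric(df[[cn]]) && !is.integer(df[[cn]])) {
      df[[cn]] <- ifelse(is.na(df[[cn]]), NA, formatC(df[[cn]], digits = 6, format = "g"))
    }
  }
  df
}
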