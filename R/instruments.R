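#' Per-variant F-statistic
#'
#' Instrument-strength statistic `(beta/se)^2`. Variants with F below 10
#' are conventionally considered weak instruments and excluded.
#'
#' @param beta Effect estimate(s), or a `sumstats`/data.frame with `beta`
#'   and `se` columns.
#' @param se Standard error(s), strictly positive.
#' @return Numeric vector of F-statistics.
#' @export
#' @examples
#' f_statistic(0.1, 0.05) # 4
f_statistic <- function(beta, se = NULL) {
  if (is.data.frame(beta)) {
    se <- beta$se
    beta <- beta$beta
  }
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop_mrm("se must be strictly positive", "mrmediate_validation_error")
  }
  (beta / se)^2
}

#' @noRd
new_instrument_set <- function(records, trait_id, selection_log) {
  rownames(records) <- NULL
  structure(records,
            trait_id = trait_id, trait_role = "exposure",
            selection_log = selection_log,
            class = c("instrument_set", "sumstats", "data.frame"))
}

#' Greedy LD clumping
#'
#' Selects approximately independent instruments: variants with
#' `pval >= p_threshold` are discarded; among the rest, the most
#' significant remaining variant is repeatedly taken as an index and all
#' remaining variants on the same chromosome within `window_kb` of it with
#' `r2 >= r2_cutoff` against it are removed. Equal p-values break ties by
#' lexicographic `variant_id`, so the result is independent of input row
#' order.
#'
#' Variant pairs absent from `ld` are treated as unlinked (`r2 = 0`) and
#' counted in the selection log, or removed when `missing_ld = "drop"`.
#'
#' @param ss A [sumstats] object with `chrom`/`pos` populated.
#' @param ld An [ld_info].
#' @param p_threshold Instrument p-value threshold (exclusive: retained
#'   variants have `pval < p_threshold`).
#' @param window_kb Window in kb; the pair test is
#'   `|pos_index - pos_other| <= window_kb * 1000` on the same chromosome,
#'   inclusive.
#' @param r2_cutoff Variants with `r2 >= r2_cutoff` to a better index are
#'   clumped away (retention requires r2 strictly below the cutoff).
#' @param missing_ld `"zero"` or `"drop"` (see [mr_config()]).
#' @return An `instrument_set` (a `sumstats` subclass) with attribute
#'   `selection_log`.
#' @export
clump <- function(ss, ld, p_threshold = 5e-6, window_kb = 10000, r2_cutoff = 0.1,
                  missing_ld = c("zero", "drop")) {
  missing_ld <- match.arg(missing_ld)
  if (p_threshold <= 0 || p_threshold >= 1) {
    stop_mrm("p_threshold must be in (0,1)", "mrmediate_validation_error")
  }
  if (r2_cutoff <= 0 || r2_cutoff > 1) {
    stop_mrm("r2_cutoff must be in (0,1]", "mrmediate_validation_error")
  }
  rec <- as.data.frame(ss)
  n_in <- nrow(rec)
  rec <- rec[!is.na(rec$pval) & rec$pval < p_threshold, , drop = FALSE]
  n_fail_p <- n_in - nrow(rec)
  rec <- rec[order(rec$pval, rec$variant_id), , drop = FALSE]
  keep <- logical(nrow(rec))
  alive <- rep(TRUE, nrow(rec))
  n_missing_ld <- 0L
  while (any(alive)) {
    i <- which(alive)[1L]
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive)
    if (!length(cand)) break
    in_window <- !is.na(rec$chrom[cand]) & !is.na(rec$chrom[i]) &
      rec$chrom[cand] == rec$chrom[i] &
      !is.na(rec$pos[cand]) & !is.na(rec$pos[i]) &
      abs(rec$pos[cand] - rec$pos[i]) <= window_kb * 1000
    cand <- cand[in_window]
    if (!length(cand)) next
    r2 <- ld_lookup(ld, rec$variant_id[i], rec$variant_id[cand])
    n_missing_ld <- n_missing_ld + sum(is.na(r2))
    drop <- if (missing_ld == "zero") !is.na(r2) & r2 >= r2_cutoff else is.na(r2) | r2 >= r2_cutoff
    alive[cand[drop]] <- FALSE
  }
  out <- rec[keep, , drop = FALSE]
  out <- out[order(out$variant_id), , drop = FALSE]
  log <- list(n_input = n_in, n_fail_p = n_fail_p,
              n_clumped = nrow(rec) - nrow(out), n_retained = nrow(out),
              n_missing_ld_pairs = n_missing_ld, n_fail_f = 0L)
  new_instrument_set(out, attr(ss, "trait_id") %||% "trait", log)
}

#' Filter instruments on strength
#'
#' Removes instruments with F-statistic `(beta/se)^2` below `min_f`.
#'
#' @param inst An `instrument_set` (or any `sumstats`).
#' @param min_f Minimum F (default 10).
#' @return An `instrument_set` with updated selection log.
#' @export
filter_instruments <- function(inst, min_f = 10) {
  rec <- as.data.frame(inst)
  if (nrow(rec) == 0L) {
    return(new_instrument_set(rec, attr(inst, "trait_id") %||% "trait",
                              attr(inst, "selection_log") %||%
                                list(n_input = 0L, n_fail_p = 0L, n_clumped = 0L,
                                     n_retained = 0L, n_missing_ld_pairs = 0L, n_fail_f = 0L)))
  }
  keep <- f_statistic(rec$beta, rec$se) >= min_f
  log <- attr(inst, "selection_log") %||%
    list(n_input = nrow(rec), n_fail_p = 0L, n_clumped = 0L,
         n_retained = nrow(rec), n_missing_ld_pairs = 0L, n_fail_f = 0L)
  log$n_fail_f <- (log$n_fail_f %||% 0L) + sum(!keep)
  log$n_retained <- sum(keep)
  new_instrument_set(rec[keep, , drop = FALSE], attr(inst, "trait_id") %||% "trait", log)
}

#' Select instruments for a trait
#'
#' Convenience wrapper: p-value threshold + greedy clumping + F filter.
#'
#' @param ss A [sumstats].
#' @param ld An [ld_info].
#' @param p_threshold,window_kb,r2_cutoff,min_f,missing_ld See [clump()] and
#'   [filter_instruments()].
#' @return An `instrument_set`.
#' @export
select_instruments <- function(ss, ld, p_threshold = 5e-6, window_kb = 10000,
                               r2_cutoff = 0.1, min_f = 10,
                               missing_ld = c("zero", "drop")) {
  filter_instruments(
    clump(ss, ld, p_threshold = p_threshold, window_kb = window_kb,
          r2_cutoff = r2_cutoff, missing_ld = match.arg(missing_ld)),
    min_f = min_f
  )
}
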