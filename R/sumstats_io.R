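#' GWAS summary statistics container
#'
#' A `sumstats` object holds one trait's per-variant association records in
#' canonical form: `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`. Alleles are single
#' uppercase nucleotides; `se > 0`; `pval` in (0, 1]; `variant_id` unique.
#'
#' @param records A data.frame with the canonical columns (missing optional
#'   columns `chrom`, `pos`, `eaf`, `n` are filled with `NA`).
#' @param trait_id Non-empty trait identifier.
#' @param trait_role One of `"exposure"`, `"mediator"`, `"outcome"`.
#' @param validate Drop invalid rows (with a report) rather than erroring.
#' @return A `sumstats` object: the records data.frame with attributes
#'   `trait_id`, `trait_role` and, when validated, `load_report`.
#' @export
sumstats <- function(records, trait_id, trait_role = c("exposure", "mediator", "outcome"),
                     validate = TRUE) {
  trait_role <- match.arg(trait_role)
  if (!is.character(trait_id) || length(trait_id) != 1L || !nzchar(trait_id)) {
    stop_mrm("trait_id must be a non-empty string", "mrmediate_validation_error")
  }
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop_mrm(paste0("missing mandatory column(s): ", paste(miss, collapse = ", ")),
             "mrmediate_validation_error")
  }
  for (opt in c("chrom", "pos", "eaf", "n")) {
    if (!opt %in% names(records)) records[[opt]] <- NA
  }
  records <- records[, c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                         "eaf", "beta", "se", "pval", "n")]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (num in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[num]] <- suppressWarnings(as.numeric(records[[num]]))
  }
  report <- NULL
  if (validate) {
    v <- validate_records(records)
    records <- v$records
    report <- v$report
    if (nrow(records) == 0L) {
      stop_mrm(paste0("no valid rows for trait '", trait_id, "'"), "mrmediate_empty_input")
    }
  }
  rownames(records) <- NULL
  structure(records,
            trait_id = trait_id, trait_role = trait_role, load_report = report,
            class = c("sumstats", "data.frame"))
}

# Row-level validation. Returns the retained rows plus a drop report with
# per-reason counts; the retained set is independent of input row order
# (duplicates resolve to the globally smallest p-value, ties to the first
# after ordering by variant_id).
#' @noRd
validate_records <- function(records) {
  n0 <- nrow(records)
  reasons <- c(
    missing_field = 0L, bad_allele = 0L, identical_alleles = 0L,
    nonpositive_se = 0L, bad_pval = 0L, bad_eaf = 0L, duplicate_variant = 0L
  )
  nuc <- c("A", "C", "G", "T")
  ok_field <- !is.na(records$variant_id) & nzchar(records$variant_id) &
    !is.na(records$beta) & !is.na(records$se) & !is.na(records$pval)
  reasons["missing_field"] <- sum(!ok_field)
  keep <- ok_field
  ok_allele <- records$effect_allele %in% nuc & records$other_allele %in% nuc
  reasons["bad_allele"] <- sum(keep & !ok_allele)
  keep <- keep & ok_allele
  ok_diff <- records$effect_allele != records$other_allele
  reasons["identical_alleles"] <- sum(keep & !ok_diff)
  keep <- keep & ok_diff
  ok_se <- !is.na(records$se) & records$se > 0
  reasons["nonpositive_se"] <- sum(keep & !ok_se)
  keep <- keep & ok_se
  ok_p <- !is.na(records$pval) & records$pval > 0 & records$pval <= 1
  reasons["bad_pval"] <- sum(keep & !ok_p)
  keep <- keep & ok_p
  ok_eaf <- is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1)
  reasons["bad_eaf"] <- sum(keep & !ok_eaf)
  keep <- keep & ok_eaf
  records <- records[keep, , drop = FALSE]
  if (anyDuplicated(records$variant_id)) {
    ord <- order(records$pval, records$variant_id)
    records <- records[ord, , drop = FALSE]
    dup <- duplicated(records$variant_id)
    reasons["duplicate_variant"] <- sum(dup)
    warning(sprintf("%d duplicate variant_id row(s) dropped (kept smallest p)", sum(dup)),
            call. = FALSE)
    records <- records[!dup, , drop = FALSE]
    records <- records[order(records$variant_id), , drop = FALSE]
  } else {
    records <- records[order(records$variant_id), , drop = FALSE]
  }
  list(records = records,
       report = list(rows_read = n0, rows_kept = nrow(records),
                     rows_dropped = n0 - nrow(records), reasons = as.list(reasons)))
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table into a validated [sumstats] object. Common
#' column dialects (e.g. `A1`/`A2`, `SNP`, `P`) are handled through
#' `column_map`; rows failing validation are dropped and counted in the
#' load report attached to the result.
#'
#' @param path Path to a TSV with a header row.
#' @param trait_id Trait identifier; defaults to the file name.
#' @param trait_role `"exposure"`, `"mediator"` or `"outcome"`.
#' @param column_map Named character vector mapping file column names to
#'   canonical fields, e.g. `c(SNP = "variant_id", A1 = "effect_allele")`.
#' @param report_path Optional path; when given the load report is written
#'   there as JSON.
#' @return A [sumstats] object with attribute `load_report`.
#' @export
read_sumstats <- function(path, trait_id = NULL,
                          trait_role = c("exposure", "mediator", "outcome"),
                          column_map = NULL, report_path = NULL) {
  trait_role <- match.arg(trait_role)
  if (!file.exists(path)) stop_mrm(paste0("cannot read file: ", path), "mrmediate_io_error")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    hit <- names(tab) %in% names(column_map)
    names(tab)[hit] <- unname(column_map[names(tab)[hit]])
  }
  ss <- sumstats(tab, trait_id = trait_id %||% basename(path), trait_role = trait_role)
  if (!is.null(report_path)) {
    jsonlite::write_json(c(list(file = path), attr(ss, "load_report")),
                         report_path, auto_unbox = TRUE, digits = NA)
  }
  ss
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (%s), %d variants\n",
              attr(x, "trait_id"), attr(x, "trait_role"), nrow(x)))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# columns written for each result flavour; order is part of the file format
mr_result_cols <- c("exposure", "outcome", "method", "nsnp", "b", "se",
                    "ci_low", "ci_high", "pval",
                    "egger_intercept", "egger_intercept_se", "egger_intercept_pval")
mediation_cols <- c("exposure", "mediator", "outcome", "beta1", "se1", "beta2", "se2",
                    "beta_all", "se_all", "beta_dir", "beta12", "se12",
                    "proportion_pct", "proportion_ci_low", "proportion_ci_high",
                    "pval", "p_ok", "proportion_ok", "direction_ok", "all_ok")

#' Write MR or mediation results
#'
#' Writes a results table as TSV with a fixed column order. In the default
#' mode reals are rendered with 6 significant digits so that a write/read
#' cycle preserves values to better than 1e-6 relative; `report = TRUE`
#' renders effects at 3 decimals and percentages at 2 decimals for
#' human-readable reports.
#'
#' @param results A data.frame of MR results (`mr_result` rows) or mediation
#'   results; an empty data.frame writes the header only.
#' @param path Output path.
#' @param report Render at report precision instead of round-trip precision.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, report = FALSE) {
  cols <- if (all(c("beta12", "proportion_pct") %in% names(results)) ||
              (nrow(results) == 0L && inherits(results, "mediation_result"))) {
    mediation_cols
  } else {
    mr_result_cols
  }
  out <- as.data.frame(results)[, intersect(cols, names(results)), drop = FALSE]
  for (missing_col in setdiff(cols, names(out))) {
    out[[missing_col]] <- rep(NA, nrow(out))
  }
  out <- out[, cols, drop = FALSE]
  # 8 significant digits so a write/read cycle stays well within 1e-6 relative
  fmt <- function(x, digits3 = FALSE) {
    if (!is.numeric(x)) return(as.character(x))
    if (report && digits3) return(ifelse(is.na(x), NA, sprintf("%.3f", x)))
    ifelse(is.na(x), NA, formatC(x, digits = 8, format = "g"))
  }
  eff_cols <- c("b", "beta1", "beta2", "beta_all", "beta_dir", "beta12")
  pct_cols <- c("proportion_pct", "proportion_ci_low", "proportion_ci_high")
  for (cn in cols) {
    if (is.numeric(out[[cn]]) && !cn %in% c("nsnp")) {
      if (report && cn %in% pct_cols) {
        out[[cn]] <- ifelse(is.na(out[[cn]]), NA, sprintf("%.2f", out[[cn]]))
      } else {
        out[[cn]] <- fmt(out[[cn]], digits3 = cn %in% eff_cols)
      }
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_mrm(paste0("cannot write results to: ", path), "mrmediate_io_error")
  invisible(path)
}

#' Read back a results table
#'
#' Counterpart of [write_results()] for round-trip checks and downstream
#' consumption of saved result tables.
#'
#' @param path Path written by [write_results()].
#' @return A data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_mrm(paste0("cannot read file: ", path), "mrmediate_io_error")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
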