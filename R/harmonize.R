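#' Watson-Crick complement of a nucleotide
#'
#' @param allele Character vector over `A`, `C`, `G`, `T`.
#' @return The complementary base(s).
#' @export
#' @examples
#' complement_alleles(c("A", "C")) # "T" "G"
complement_alleles <- function(allele) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  allele <- toupper(allele)
  if (any(!allele %in% names(map))) {
    stop_mrm("alleles must be one of A, C, G, T", "mrmediate_validation_error")
  }
  unname(map[allele])
}

#' Construct a harmonized exposure-outcome set directly
#'
#' For data already aligned to a shared effect allele (e.g. simulated
#' tables), builds the per-variant table consumed by the MR estimators.
#'
#' @param variant_id Character vector.
#' @param beta_exp,se_exp Exposure association and SE (`se_exp > 0`).
#' @param beta_out,se_out Outcome association and SE (`se_out > 0`).
#' @param eaf_exp,eaf_out Optional effect-allele frequencies.
#' @param exposure_id,outcome_id Trait labels.
#' @return A `harmonized_set` data.frame.
#' @export
harmonized_set <- function(variant_id, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = NA_real_, eaf_out = NA_real_,
                           exposure_id = "exposure", outcome_id = "outcome") {
  df <- data.frame(variant_id = as.character(variant_id),
                   beta_exp = beta_exp, se_exp = se_exp,
                   beta_out = beta_out, se_out = se_out,
                   eaf_exp = eaf_exp, eaf_out = eaf_out,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_mrm("harmonized set must have at least 1 row", "mrmediate_empty_harmonization")
  if (any(df$se_exp <= 0) || any(df$se_out <= 0)) {
    stop_mrm("standard errors must be strictly positive", "mrmediate_validation_error")
  }
  structure(df, exposure_id = exposure_id, outcome_id = outcome_id,
            harmonization_log = NULL,
            class = c("harmonized_set", "data.frame"))
}

#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns each exposure instrument and its outcome record to a shared
#' effect allele. Per variant: identical allele pairs are kept as-is;
#' swapped orientation negates the outcome beta and reflects its allele
#' frequency; strand-complement pairs are complemented first; palindromic
#' pairs (A/T, C/G) cannot be resolved by allele labels and are aligned by
#' allele-frequency concordance when both frequencies sit outside the
#' ambiguity zone `0.5 +/- palindrome_eaf_window`, and dropped otherwise.
#' Variants absent from the outcome or with irreconcilable allele pairs
#' are dropped. All actions are counted in the `harmonization_log`
#' attribute; the six categories sum to the number of exposure
#' instruments.
#'
#' @param exposure An `instrument_set` (or `sumstats`) for the exposure.
#' @param outcome A [sumstats] for the outcome trait.
#' @param palindrome_eaf_window Half-width of the frequency ambiguity zone
#'   (default 0.08: drop when either eaf is in [0.42, 0.58] or missing).
#' @return A `harmonized_set` with columns `variant_id`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  ex <- as.data.frame(exposure)
  out <- as.data.frame(outcome)
  n_ex <- nrow(ex)
  m <- match(ex$variant_id, out$variant_id)
  log <- c(matched = 0L, sign_flipped = 0L, palindromic_inferred = 0L,
           palindromic_dropped = 0L, unmatched_dropped = sum(is.na(m)),
           incompatible_dropped = 0L)
  idx <- which(!is.na(m))
  rows <- vector("list", length(idx))
  k <- 0L
  lo <- 0.5 - palindrome_eaf_window
  hi <- 0.5 + palindrome_eaf_window
  for (i in idx) {
    o <- out[m[i], ]
    e1 <- ex$effect_allele[i]; e2 <- ex$other_allele[i]
    o1 <- o$effect_allele; o2 <- o$other_allele
    beta_out <- o$beta; eaf_out <- o$eaf
    palindromic <- identical(complement_alleles(e2), e1)
    same <- (o1 == e1 && o2 == e2)
    swapped <- (o1 == e2 && o2 == e1)
    if (!palindromic && !same && !swapped) {
      # try the opposite strand
      o1 <- complement_alleles(o1); o2 <- complement_alleles(o2)
      same <- (o1 == e1 && o2 == e2)
      swapped <- (o1 == e2 && o2 == e1)
    }
    if (!same && !swapped) {
      log["incompatible_dropped"] <- log["incompatible_dropped"] + 1L
      next
    }
    if (swapped) {
      beta_out <- -beta_out
      if (!is.na(eaf_out)) eaf_out <- 1 - eaf_out
    }
    if (palindromic) {
      eaf_exp <- ex$eaf[i]
      unambiguous <- !is.na(eaf_exp) && !is.na(eaf_out) &&
        (eaf_exp < lo || eaf_exp > hi) && (eaf_out < lo || eaf_out > hi)
      if (!unambiguous) {
        log["palindromic_dropped"] <- log["palindromic_dropped"] + 1L
        next
      }
      if ((eaf_exp - 0.5) * (eaf_out - 0.5) < 0) {
        # frequencies disagree: the outcome file is on the other strand
        beta_out <- -beta_out
        eaf_out <- 1 - eaf_out
      }
      log["palindromic_inferred"] <- log["palindromic_inferred"] + 1L
    } else if (swapped) {
      log["sign_flipped"] <- log["sign_flipped"] + 1L
    } else {
      log["matched"] <- log["matched"] + 1L
    }
    k <- k + 1L
    rows[[k]] <- data.frame(variant_id = ex$variant_id[i],
                            beta_exp = ex$beta[i], se_exp = ex$se[i],
                            beta_out = beta_out, se_out = o$se,
                            eaf_exp = ex$eaf[i], eaf_out = eaf_out,
                            stringsAsFactors = FALSE)
  }
  stopifnot(sum(log) == n_ex)
  if (k == 0L) {
    stop_mrm("no instruments survived harmonization", "mrmediate_empty_harmonization")
  }
  df <- do.call(rbind, rows[seq_len(k)])
  df <- df[order(df$variant_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            exposure_id = attr(exposure, "trait_id") %||% "exposure",
            outcome_id = attr(outcome, "trait_id") %||% "outcome",
            harmonization_log = as.list(log),
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s, %d variants\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x)))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}
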