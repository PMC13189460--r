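#' Pairwise LD information
#'
#' Container for a square r-squared matrix over a set of variants. The
#' matrix must be symmetric with unit diagonal and entries in [0, 1].
#'
#' @param variant_ids Character vector of variant identifiers.
#' @param r2 Square numeric matrix, `length(variant_ids)` on a side.
#' @return An `ld_info` object.
#' @export
ld_info <- function(variant_ids, r2) {
  variant_ids <- as.character(variant_ids)
  r2 <- as.matrix(r2)
  n <- length(variant_ids)
  if (!all(dim(r2) == c(n, n))) {
    stop_mrm("r2 matrix dimensions do not match variant_ids", "mrmediate_validation_error")
  }
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop_mrm("r2 entries must be in [0,1]", "mrmediate_validation_error")
  }
  if (max(abs(r2 - t(r2))) > 1e-12) {
    stop_mrm("r2 matrix must be symmetric (tolerance 1e-12)", "mrmediate_validation_error")
  }
  if (any(abs(diag(r2) - 1) > 0)) {
    stop_mrm("r2 diagonal must be exactly 1", "mrmediate_validation_error")
  }
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids, r2 = r2), class = "ld_info")
}

#' Identity LD (no linkage) over a set of variants
#'
#' @param variant_ids Character vector.
#' @return An `ld_info` with an identity r-squared matrix.
#' @export
ld_identity <- function(variant_ids) {
  n <- length(variant_ids)
  ld_info(variant_ids, diag(1, n))
}

#' Block-diagonal LD fixture
#'
#' Builds an r-squared matrix with constant LD inside consecutive blocks of
#' variants and zero between blocks, useful for exercising clumping.
#'
#' @param n_snp Number of variants (ids `snp1..snpN` unless supplied).
#' @param block_size Variants per block; the last block may be smaller.
#' @param within_r2 r-squared between distinct variants within a block.
#' @param variant_ids Optional ids, length `n_snp`.
#' @return An `ld_info`.
#' @export
#' @examples
#' ld <- make_ld_blocks(4, 2, 0.8)
#' ld$r2
make_ld_blocks <- function(n_snp, block_size, within_r2, variant_ids = NULL) {
  if (block_size > n_snp || block_size < 1) {
    stop_mrm("block_size must be in [1, n_snp]", "mrmediate_validation_error")
  }
  if (within_r2 < 0 || within_r2 > 1) {
    stop_mrm("within_r2 must be in [0,1]", "mrmediate_validation_error")
  }
  ids <- variant_ids %||% paste0("snp", seq_len(n_snp))
  blk <- rep(seq_len(ceiling(n_snp / block_size)), each = block_size)[seq_len(n_snp)]
  r2 <- outer(blk, blk, function(a, b) ifelse(a == b, within_r2, 0))
  diag(r2) <- 1
  ld_info(ids, r2)
}

#' Read LD information from file
#'
#' Accepts either a long-form TSV (`variant_a`, `variant_b`, `r2`) or a
#' square matrix TSV whose first column and header carry variant ids.
#' Long-form input is symmetrized; pairs not listed are taken as r2 = 0.
#'
#' @param path Path to a TSV.
#' @return An `ld_info`.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop_mrm(paste0("cannot read file: ", path), "mrmediate_io_error")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) == 3L && all(c("variant_a", "variant_b", "r2") %in% names(tab))) {
    ids <- sort(unique(c(tab$variant_a, tab$variant_b)))
    r2 <- diag(1, length(ids))
    dimnames(r2) <- list(ids, ids)
    ia <- match(tab$variant_a, ids)
    ib <- match(tab$variant_b, ids)
    r2[cbind(ia, ib)] <- tab$r2
    r2[cbind(ib, ia)] <- tab$r2
    diag(r2) <- 1
    ld_info(ids, r2)
  } else {
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    ld_info(ids, m)
  }
}

# r2 lookup for one index variant against a set; pairs unknown to the LD
# input come back NA so the clumping policy can decide.
#' @noRd
ld_lookup <- function(ld, index_id, other_ids) {
  out <- rep(NA_real_, length(other_ids))
  if (!index_id %in% ld$variant_ids) return(out)
  hit <- other_ids %in% ld$variant_ids
  out[hit] <- ld$r2[index_id, other_ids[hit]]
  out
}
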