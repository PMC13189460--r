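#' Ground truth for a simulated three-trait mediation system
#'
#' Describes an exposure X, mediator M and outcome Y linked by
#' `X -> M -> Y` with direct effect `theta_dir`, path a `theta_a`, path b
#' `theta_b`, so the true total effect is `theta_dir + theta_a * theta_b`
#' and the true mediation proportion `theta_a * theta_b / total`. The
#' exposure has `n_snp` instrument SNPs with per-allele effects `gamma`;
#' the mediator additionally has `n_snp_med` instruments of its own with
#' effects `delta` (the pQTL analogue), which is what makes the
#' mediator-to-outcome leg estimable from the mediator's instruments.
#' Horizontal pleiotropy adds per-SNP direct outcome effects
#' `Normal(pleiotropy_mean, pleiotropy_sd^2)` at the exposure's SNPs.
#'
#' Default sample sizes mirror the cohort scales typical of microbiome
#' GWAS (~6000) and plasma proteome pQTL panels (~35,500). Because the
#' simulated outcome is continuous, the default outcome size is the
#' effective sample size of a biobank-scale binary GWAS with ~13,000
#' cases (`4 n_case n_control / n` of roughly 51,000), so simulated
#' outcome standard errors match the precision of the emulated
#' log-odds-scale associations. Mediator instruments default to strong
#' effects (0.15-0.5), the cis-pQTL regime in which protein instruments
#' reach genome-wide significance.
#'
#' @param n_snp Exposure instrument count (default 20).
#' @param gamma Optional vector of exposure SNP effects; drawn as
#'   `runif(n_snp, 0.05, 0.3)` with random signs when `NULL`.
#' @param n_snp_med Mediator instrument count (default `n_snp`).
#' @param delta Optional mediator SNP effects; drawn as
#'   `runif(n_snp_med, 0.15, 0.5)` with random signs when `NULL`.
#' @param theta_a,theta_b,theta_dir True path a, path b and direct effects.
#' @param pleiotropy_mean,pleiotropy_sd Per-SNP direct outcome effects at
#'   exposure SNPs (defaults 0, 0: no pleiotropy).
#' @param n_exp,n_med,n_out GWAS sample sizes of the three cohorts.
#' @param maf_range Minor-allele-frequency range, in (0, 0.5].
#' @param seed Master seed; all draws derive sub-streams from it.
#' @return A validated list of class `sim_truth`, including the implied
#'   `total` and `proportion`.
#' @export
sim_truth <- function(n_snp = 20, gamma = NULL, n_snp_med = n_snp, delta = NULL,
                      theta_a = 0, theta_b = 0, theta_dir = 0,
                      pleiotropy_mean = 0, pleiotropy_sd = 0,
                      n_exp = 5959, n_med = 35559, n_out = 51340,
                      maf_range = c(0.05, 0.5), seed = 1) {
  if (n_snp < 1 || n_snp_med < 0) stop_mrm("invalid instrument counts", "mrmediate_validation_error")
  if (any(c(n_exp, n_med, n_out) < 1)) stop_mrm("sample sizes must be >= 1", "mrmediate_validation_error")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop_mrm("maf_range must be within (0, 0.5]", "mrmediate_validation_error")
  }
  if (pleiotropy_sd < 0) stop_mrm("pleiotropy_sd must be >= 0", "mrmediate_validation_error")
  if (!is.null(gamma) && length(gamma) != n_snp) {
    stop_mrm("gamma length must equal n_snp", "mrmediate_validation_error")
  }
  if (!is.null(delta) && length(delta) != n_snp_med) {
    stop_mrm("delta length must equal n_snp_med", "mrmediate_validation_error")
  }
  total <- theta_dir + theta_a * theta_b
  structure(list(
    n_snp = as.integer(n_snp), gamma = gamma,
    n_snp_med = as.integer(n_snp_med), delta = delta,
    theta_a = theta_a, theta_b = theta_b, theta_dir = theta_dir,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    n_exp = n_exp, n_med = n_med, n_out = n_out,
    maf_range = maf_range, seed = seed,
    total = total,
    proportion = if (total != 0) theta_a * theta_b / total else NA_real_
  ), class = "sim_truth")
}

# draw effect sizes of typical instrument strength with random signs
#' @noRd
draw_effects <- function(n, lo = 0.05, hi = 0.3) {
  if (n == 0L) return(numeric(0))
  stats::runif(n, lo, hi) * sample(c(-1, 1), n, replace = TRUE)
}

# non-palindromic allele pairs only, so simulated tables harmonize without
# frequency inference
#' @noRd
draw_alleles <- function(n) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "A"),
                 c("C", "A"), c("T", "G"), c("T", "C"))
  pick <- sample(nrow(pairs), n, replace = TRUE)
  list(effect = pairs[pick, 1], other = pairs[pick, 2])
}

# shared engine: given true per-SNP effects for each trait, emit observed
# summary tables with se = 1/sqrt(2 maf (1-maf) n_trait)
#' @noRd
sim_tables <- function(true_beta, maf, n_by_trait, roles, snp_meta, seed) {
  traits <- colnames(true_beta)
  out <- vector("list", length(traits))
  names(out) <- traits
  for (k in seq_along(traits)) {
    se <- 1 / sqrt(2 * maf * (1 - maf) * n_by_trait[k])
    beta <- with_seed(derive_seed(seed, 100 + k), {
      stats::rnorm(nrow(true_beta), mean = true_beta[, k], sd = se)
    })
    rec <- data.frame(
      variant_id = snp_meta$variant_id, chrom = snp_meta$chrom, pos = snp_meta$pos,
      effect_allele = snp_meta$effect_allele, other_allele = snp_meta$other_allele,
      eaf = maf, beta = beta, se = se,
      pval = p_two_sided(beta / se), n = n_by_trait[k],
      stringsAsFactors = FALSE
    )
    out[[k]] <- sumstats(rec, trait_id = traits[k], trait_role = roles[k], validate = FALSE)
    class(out[[k]]) <- c("sumstats", "data.frame")
  }
  out
}

# SNP bookkeeping: each SNP gets its own locus, far apart so clumping with
# the default identity LD never interacts across instruments; block LD
# places block members at the same locus
#' @noRd
snp_layout <- function(n, prefix = "rs", block_size = NULL) {
  id <- sprintf("%s%04d", prefix, seq_len(n))
  if (is.null(block_size)) {
    chrom <- as.character(((seq_len(n) - 1L) %% 22L) + 1L)
    pos <- 1e6 + ((seq_len(n) - 1L) %/% 22L) * 2.5e7
  } else {
    blk <- (seq_len(n) - 1L) %/% block_size
    chrom <- as.character((blk %% 22L) + 1L)
    pos <- 1e6 + (blk %/% 22L) * 2.5e7 + ((seq_len(n) - 1L) %% block_size) * 1e3
  }
  data.frame(variant_id = id, chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Simulate GWAS summary statistics for a mediation system
#'
#' Generates the three summary-statistic tables of a two-step MR study
#' with known truth. Per SNP, allele frequencies are uniform over
#' `maf_range`; the exposure's SNPs have true effects `gamma` on the
#' exposure, `theta_a * gamma` on the mediator and
#' `(theta_dir + theta_a * theta_b) * gamma + pi` on the outcome, with
#' pleiotropy `pi ~ Normal(pleiotropy_mean, pleiotropy_sd^2)`; the
#' mediator's own SNPs have effects `delta` on the mediator and
#' `theta_b * delta` on the outcome. Observed effects are drawn
#' `Normal(truth, se^2)` with `se = 1/sqrt(2 maf (1-maf) n)` for the
#' cohort's sample size; p-values are two-sided normal. LD defaults to
#' identity (independent instruments); a block structure is available for
#' clumping exercises. Fully reproducible from `truth$seed`.
#'
#' @param truth A [sim_truth()].
#' @param ld_blocks Optional `list(block_size =, within_r2 =)` to emit
#'   block LD (and co-locate block members) instead of identity LD.
#' @return A `sim_output` list: `exposure`, `mediator`, `outcome`
#'   ([sumstats]), `ld` ([ld_info]) and `truth`.
#' @export
#' @examples
#' sim <- simulate_summary(sim_truth(n_snp = 10, theta_a = 0.3, seed = 7))
#' head(sim$exposure)
simulate_summary <- function(truth, ld_blocks = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  n_e <- truth$n_snp
  n_m <- truth$n_snp_med
  n <- n_e + n_m
  meta <- snp_layout(n, block_size = ld_blocks$block_size %||% NULL)
  setup <- with_seed(derive_seed(truth$seed, 1), {
    maf <- stats::runif(n, truth$maf_range[1], truth$maf_range[2])
    al <- draw_alleles(n)
    gamma <- truth$gamma %||% draw_effects(n_e)
    delta <- truth$delta %||% draw_effects(n_m, 0.15, 0.5)
    pleio <- stats::rnorm(n_e, truth$pleiotropy_mean, truth$pleiotropy_sd)
    list(maf = maf, al = al, gamma = gamma, delta = delta, pleio = pleio)
  })
  meta$effect_allele <- setup$al$effect
  meta$other_allele <- setup$al$other
  is_e <- seq_len(n) <= n_e
  b_exp <- ifelse(is_e, c(setup$gamma, rep(0, n_m)), 0)
  b_med <- c(truth$theta_a * setup$gamma, setup$delta)
  b_out <- c(truth$total * setup$gamma + setup$pleio, truth$theta_b * setup$delta)
  true_beta <- cbind(exposure = b_exp, mediator = b_med, outcome = b_out)
  tabs <- sim_tables(true_beta, setup$maf,
                     c(truth$n_exp, truth$n_med, truth$n_out),
                     c("exposure", "mediator", "outcome"), meta, truth$seed)
  ld <- if (is.null(ld_blocks)) {
    ld_identity(meta$variant_id)
  } else {
    make_ld_blocks(n, ld_blocks$block_size, ld_blocks$within_r2,
                   variant_ids = meta$variant_id)
  }
  structure(list(exposure = tabs$exposure, mediator = tabs$mediator,
                 outcome = tabs$outcome, ld = ld, truth = truth),
            class = "sim_output")
}

#' Simulate individual-level data and derive summary statistics
#'
#' Oracle generator: genotypes `Binomial(2, maf)` in three non-overlapping
#' cohorts; `X = G gamma + e`, `M = theta_a X + G_med delta + e`,
#' `Y = theta_dir X + theta_b M + G pi + e` with unit-variance noises.
#' Per-SNP univariate regressions in each cohort produce the three
#' summary tables, and a two-stage least-squares estimate of path a in
#' the mediator cohort is reported as an individual-level oracle.
#'
#' @param truth A [sim_truth()].
#' @param n_per_cohort Integer vector of cohort sizes (exposure, mediator,
#'   outcome); defaults to the truth's `n_exp`, `n_med`, `n_out`.
#' @return A `sim_output` with an extra `oracle` element
#'   (`tsls_a`: 2SLS estimate of `theta_a` and its SE).
#' @export
simulate_individual <- function(truth, n_per_cohort = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  ns <- n_per_cohort %||% c(truth$n_exp, truth$n_med, truth$n_out)
  n_e <- truth$n_snp; n_m <- truth$n_snp_med; p <- n_e + n_m
  meta <- snp_layout(p)
  setup <- with_seed(derive_seed(truth$seed, 1), {
    maf <- stats::runif(p, truth$maf_range[1], truth$maf_range[2])
    al <- draw_alleles(p)
    gamma <- truth$gamma %||% draw_effects(n_e)
    delta <- truth$delta %||% draw_effects(n_m, 0.15, 0.5)
    pleio <- stats::rnorm(n_e, truth$pleiotropy_mean, truth$pleiotropy_sd)
    list(maf = maf, al = al, gamma = gamma, delta = delta, pleio = pleio)
  })
  meta$effect_allele <- setup$al$effect
  meta$other_allele <- setup$al$other
  gall <- c(setup$gamma, rep(0, n_m))       # effects on X
  dall <- c(rep(0, n_e), setup$delta)        # direct effects on M
  pall <- c(setup$pleio, rep(0, n_m))        # direct effects on Y
  cohorts <- lapply(1:3, function(k) {
    with_seed(derive_seed(truth$seed, 200 + k), {
      ni <- ns[k]
      G <- matrix(stats::rbinom(ni * p, 2L, rep(setup$maf, each = ni)), nrow = ni)
      X <- as.numeric(G %*% gall) + stats::rnorm(ni)
      M <- truth$theta_a * X + as.numeric(G %*% dall) + stats::rnorm(ni)
      Y <- truth$theta_dir * X + truth$theta_b * M + as.numeric(G %*% pall) + stats::rnorm(ni)
      list(G = G, X = X, M = M, Y = Y)
    })
  })
  uni_reg <- function(G, y) {
    n <- length(y)
    gm <- colMeans(G)
    sxx <- colSums(G^2) - n * gm^2
    sxy <- as.numeric(crossprod(G, y)) - n * gm * mean(y)
    beta <- sxy / sxx
    syy <- sum((y - mean(y))^2)
    sse <- pmax(syy - beta * sxy, 0)
    se <- sqrt(sse / (n - 2) / sxx)
    list(beta = beta, se = se, eaf = gm / 2)
  }
  make_tab <- function(co, y, trait, role, n) {
    r <- uni_reg(co$G, y)
    rec <- data.frame(variant_id = meta$variant_id, chrom = meta$chrom, pos = meta$pos,
                      effect_allele = meta$effect_allele, other_allele = meta$other_allele,
                      eaf = r$eaf, beta = r$beta, se = r$se,
                      pval = p_two_sided(r$beta / r$se), n = n,
                      stringsAsFactors = FALSE)
    sumstats(rec, trait_id = trait, trait_role = role, validate = FALSE)
  }
  # 2SLS of M on X instrumented by the exposure SNPs, in the mediator cohort
  c2 <- cohorts[[2]]
  Ge <- c2$G[, seq_len(n_e), drop = FALSE]
  fs <- stats::lm.fit(cbind(1, Ge), c2$X)
  xhat <- fs$fitted.values
  ss <- stats::lm(c2$M ~ xhat)
  tsls <- summary(ss)$coefficients["xhat", 1:2]
  structure(list(
    exposure = make_tab(cohorts[[1]], cohorts[[1]]$X, "exposure", "exposure", ns[1]),
    mediator = make_tab(cohorts[[2]], cohorts[[2]]$M, "mediator", "mediator", ns[2]),
    outcome = make_tab(cohorts[[3]], cohorts[[3]]$Y, "outcome", "outcome", ns[3]),
    ld = ld_identity(meta$variant_id),
    truth = truth,
    oracle = list(tsls_a = unname(tsls[1]), tsls_a_se = unname(tsls[2]))
  ), class = "sim_output")
}

#' Simulate a screening scenario with one planted pathway
#'
#' Builds the trait grid consumed by [screen()]: `n_exposures` exposures,
#' `n_mediators` mediators and one outcome, where only the first
#' exposure-mediator pair carries the causal system described by `truth`
#' and every other trait is null (instrumented, but with no downstream
#' effects). Every mediator and the outcome table covers all SNPs, so
#' harmonization and leg estimation run exactly as in a real screen.
#'
#' @param truth A [sim_truth()] for the planted pathway.
#' @param n_exposures,n_mediators Grid dimensions (defaults 3 and 2).
#' @return A list with `exposures`, `mediators`, `outcomes` (lists of
#'   [sumstats]), `ld`, and `truth`.
#' @export
simulate_screen_scenario <- function(truth, n_exposures = 3, n_mediators = 2) {
  stopifnot(inherits(truth, "sim_truth"), n_exposures >= 1, n_mediators >= 1)
  n_e <- truth$n_snp; n_m <- truth$n_snp_med
  groups <- c(rep(seq_len(n_exposures), each = n_e),
              rep(n_exposures + seq_len(n_mediators), each = n_m))
  n_all <- length(groups)
  meta <- snp_layout(n_all)
  setup <- with_seed(derive_seed(truth$seed, 3), {
    maf <- stats::runif(n_all, truth$maf_range[1], truth$maf_range[2])
    al <- draw_alleles(n_all)
    is_med_snp <- groups > n_exposures
    eff <- ifelse(is_med_snp, draw_effects(n_all, 0.15, 0.5), draw_effects(n_all))
    pleio <- stats::rnorm(n_all, truth$pleiotropy_mean, truth$pleiotropy_sd)
    list(maf = maf, al = al, eff = eff, pleio = pleio)
  })
  if (!is.null(truth$gamma)) setup$eff[groups == 1L] <- truth$gamma
  if (!is.null(truth$delta)) setup$eff[groups == n_exposures + 1L] <- truth$delta
  meta$effect_allele <- setup$al$effect
  meta$other_allele <- setup$al$other
  exp_ids <- sprintf("exposure%02d", seq_len(n_exposures))
  med_ids <- sprintf("mediator%02d", seq_len(n_mediators))
  traits <- c(exp_ids, med_ids, "outcome")
  true_beta <- matrix(0, n_all, length(traits), dimnames = list(NULL, traits))
  for (g in seq_len(n_exposures + n_mediators)) {
    sel <- groups == g
    true_beta[sel, g] <- setup$eff[sel]
  }
  planted_e <- groups == 1L
  planted_m <- groups == n_exposures + 1L
  true_beta[planted_e, n_exposures + 1L] <- truth$theta_a * setup$eff[planted_e]
  true_beta[planted_e, "outcome"] <- truth$total * setup$eff[planted_e] + setup$pleio[planted_e]
  true_beta[planted_m, "outcome"] <- truth$theta_b * setup$eff[planted_m]
  roles <- c(rep("exposure", n_exposures), rep("mediator", n_mediators), "outcome")
  n_by_trait <- c(rep(truth$n_exp, n_exposures), rep(truth$n_med, n_mediators), truth$n_out)
  tabs <- sim_tables(true_beta, setup$maf, n_by_trait, roles, meta, truth$seed)
  list(exposures = tabs[exp_ids], mediators = tabs[med_ids],
       outcomes = tabs["outcome"], ld = ld_identity(meta$variant_id), truth = truth)
}
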