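# fixtures and independent oracles shared across test files

# random harmonized set with n variants; betas/SEs in a realistic range
make_hset <- function(n, seed, slope = 0.3, intercept = 0, noise = 0.02) {
  set.seed(seed)
  harmonized_set(
    variant_id = sprintf("v%03d", seq_len(n)),
    beta_exp = runif(n, 0.05, 0.5) * sample(c(-1, 1), n, replace = TRUE),
    se_exp = runif(n, 0.01, 0.05),
    beta_out = NA, se_out = runif(n, 0.01, 0.08),
    eaf_exp = runif(n, 0.1, 0.9)
  ) -> h
  # outcome generated from an Egger-style model after orienting to
  # non-negative exposure effects, so `intercept` is interpretable
  or <- ifelse(h$beta_exp < 0, -1, 1)
  h$beta_out <- or * (intercept + slope * abs(h$beta_exp) + rnorm(n, 0, noise))
  h
}

# minimal sumstats table builder
make_ss <- function(ids, beta, se, pval = NULL, chrom = "1", pos = NULL,
                    ea = "A", oa = "G", eaf = 0.3, trait = "trait",
                    role = "exposure", n = 10000) {
  k <- length(ids)
  sumstats(data.frame(
    variant_id = ids, chrom = rep_len(chrom, k),
    pos = pos %||% seq(1e6, by = 1000, length.out = k),
    effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
    eaf = rep_len(eaf, k), beta = beta, se = se,
    pval = pval %||% (2 * pnorm(-abs(beta / se))), n = n,
    stringsAsFactors = FALSE
  ), trait_id = trait, trait_role = role)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# harmonized-set payload without bookkeeping attributes, for equality checks
hs_rows <- function(h) {
  d <- as.data.frame(h)
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  d
}

# ---- independent oracles -------------------------------------------------

# WLS through the origin via base lm
oracle_ivw_fixed <- function(h) {
  fit <- lm(beta_out ~ beta_exp + 0, data = as.data.frame(h), weights = se_out^-2)
  unname(coef(fit)[1])
}

# generic weighted regression with intercept via base lm; SEs rescaled to
# the multiplicative-overdispersion-floored-at-1 convention
oracle_egger <- function(h) {
  df <- as.data.frame(h)
  flip <- ifelse(df$beta_exp < 0, -1, 1)
  df$x <- df$beta_exp * flip
  df$y <- df$beta_out * flip
  fit <- lm(y ~ x, data = df, weights = df$se_out^-2)
  sm <- summary(fit)
  sigma <- sm$sigma
  scale <- max(1, sigma) / sigma
  list(slope = unname(coef(fit)["x"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       se_slope = unname(sm$coefficients["x", "Std. Error"]) * scale,
       se_intercept = unname(sm$coefficients["(Intercept)", "Std. Error"]) * scale)
}

# weighted-absolute-deviation minimizer by dense grid search
oracle_wad_median <- function(b, w, grid_n = 20001) {
  grid <- seq(min(b), max(b), length.out = grid_n)
  obj <- vapply(grid, function(x) sum(w * abs(b - x)), numeric(1))
  grid[which.min(obj)]
}

# dense-grid kernel-density mode with the same bandwidth rule
oracle_mode <- function(b, wt, phi = 1, grid_n = 4096) {
  h0 <- 0.9 * min(sd(b), mad(b, constant = 1) / 0.6745) * length(b)^(-1 / 5)
  if (h0 == 0) h0 <- 0.9 * sd(b) * length(b)^(-1 / 5)
  h <- phi * h0
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = grid_n)
  wt <- wt / sum(wt)
  dens <- vapply(grid, function(x) sum(wt * dnorm(x, b, h)), numeric(1))
  grid[which.max(dens)]
}
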