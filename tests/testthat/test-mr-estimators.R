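test_that("Wald ratios follow the first-order construction", {
  h <- harmonized_set("v1", beta_exp = 0.5, se_exp = 0.02, beta_out = 0.1, se_out = 0.05)
  r <- wald_ratios(h)
  expect_equal(r$b, 0.2)
  expect_equal(r$s, 0.1)
  # sign symmetry
  h2 <- harmonized_set("v1", beta_exp = -0.5, se_exp = 0.02, beta_out = -0.1, se_out = 0.05)
  r2 <- wald_ratios(h2)
  expect_equal(r2$b, r$b)
  expect_equal(r2$s, r$s)
  # elementwise against an independent computation
  h3 <- make_hset(3, seed = 31)
  r3 <- wald_ratios(h3)
  expect_equal(r3$b, h3$beta_out / h3$beta_exp)
  expect_equal(r3$s, h3$se_out / abs(h3$beta_exp))
  expect_equal(r3$w, (h3$se_out / abs(h3$beta_exp))^-2)
  # second-order option
  r4 <- wald_ratios(h3, se_order = 2)
  expect_equal(r4$s, sqrt(h3$se_out^2 / h3$beta_exp^2 +
                            h3$beta_out^2 * h3$se_exp^2 / h3$beta_exp^4))
  # beta_exp = 0 rows are dropped with a warning
  h5 <- harmonized_set(c("a", "b"), beta_exp = c(0, 0.5), se_exp = 0.02,
                       beta_out = 0.1, se_out = 0.05)
  expect_warning(r5 <- wald_ratios(h5), "beta_exp = 0")
  expect_equal(nrow(r5), 1L)
})

test_that("IVW equals weighted least squares through the origin", {
  # homogeneous ratios: estimate is the common ratio, Q = 0, random = fixed
  h <- harmonized_set(c("a", "b"), beta_exp = c(0.2, 0.4), se_exp = 0.02,
                      beta_out = c(0.06, 0.12), se_out = c(0.03, 0.05))
  fx <- mr_ivw(h, re_mode = "fixed")
  rd <- mr_ivw(h, re_mode = "multiplicative_random")
  expect_equal(fx$estimate, 0.3)
  expect_equal(rd$se, fx$se)
  # n = 1 falls back to the Wald ratio
  h1 <- harmonized_set("a", beta_exp = 0.5, se_exp = 0.02, beta_out = 0.1, se_out = 0.05)
  w1 <- mr_ivw(h1)
  expect_equal(w1$method, "wald_ratio")
  expect_equal(w1$estimate, 0.2)
  expect_equal(w1$se, 0.1)
  # WLS-through-origin oracle on random sets
  for (s in 1:20) {
    hs <- make_hset(5 + s %% 10, seed = 400 + s)
    expect_equal(mr_ivw(hs, re_mode = "fixed")$estimate, oracle_ivw_fixed(hs),
                 tolerance = 1e-10)
  }
})

test_that("Egger regression matches the generic weighted-regression oracle", {
  # exact line: slope and intercept recovered with zero residual
  h <- make_hset(6, seed = 41, slope = 0.3, intercept = 0.05, noise = 0)
  e <- mr_egger(h)
  expect_equal(e$estimate, 0.3, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0.05, tolerance = 1e-10)
  # line through the origin: intercept 0, slope = IVW fixed estimate
  h0 <- make_hset(6, seed = 42, slope = 0.3, intercept = 0, noise = 0)
  e0 <- mr_egger(h0)
  expect_equal(e0$egger_intercept, 0, tolerance = 1e-10)
  expect_equal(e0$estimate, mr_ivw(h0, re_mode = "fixed")$estimate, tolerance = 1e-10)
  # oracle equality on noisy sets
  for (s in 1:20) {
    hs <- make_hset(6 + s %% 8, seed = 500 + s)
    or <- oracle_egger(hs)
    eg <- mr_egger(hs)
    expect_equal(eg$estimate, or$slope, tolerance = 1e-8)
    expect_equal(eg$egger_intercept, or$intercept, tolerance = 1e-8)
    expect_equal(eg$se, or$se_slope, tolerance = 1e-8)
    expect_equal(eg$egger_intercept_se, or$se_intercept, tolerance = 1e-8)
  }
  expect_error(mr_egger(make_hset(2, seed = 1)),
               class = "mrmediate_insufficient_instruments")
})

test_that("weighted median interpolates standardized cumulative weights", {
  r <- structure(data.frame(variant_id = letters[1:3], b = c(0.1, 0.2, 0.3),
                            s = 1, w = 1), class = c("ratio_estimates", "data.frame"))
  expect_equal(mr_weighted_median(r, n_boot = 50, seed = 1)$estimate, 0.2)
  # documented interpolation: {0,1,2,10} equal weights -> 1.5
  r4 <- structure(data.frame(variant_id = letters[1:4], b = c(0, 1, 2, 10),
                             s = 1, w = 1), class = c("ratio_estimates", "data.frame"))
  expect_equal(mr_weighted_median(r4, n_boot = 50, seed = 1)$estimate, 1.5)
  # grid-search weighted-absolute-deviation oracle: the interpolated
  # median and the WAD minimizer bracket the same half-weight crossing,
  # so at most one ratio can lie strictly between them
  set.seed(55)
  for (s in 1:10) {
    n <- 5 + s
    b <- rnorm(n)
    w <- runif(n, 0.5, 2)
    rr <- structure(data.frame(variant_id = paste0("v", 1:n), b = b, s = w^-0.5, w = w),
                    class = c("ratio_estimates", "data.frame"))
    est <- mr_weighted_median(rr, n_boot = 50, seed = 2)$estimate
    wad <- oracle_wad_median(b, w)
    expect_lte(sum(b > min(est, wad) + 1e-9 & b < max(est, wad) - 1e-9), 1L)
  }
  # degenerate: identical ratios with shrinking spread give a tiny bootstrap SE
  rd <- structure(data.frame(variant_id = letters[1:4], b = 0.25, s = 1e-6, w = 1e12),
                  class = c("ratio_estimates", "data.frame"))
  md <- mr_weighted_median(rd, n_boot = 100, seed = 3)
  expect_equal(md$estimate, 0.25)
  expect_lt(md$se, 1e-5)
})

test_that("mode estimators find the dominant cluster", {
  r <- structure(data.frame(variant_id = letters[1:4], b = c(0.2, 0.2, 0.2, 5),
                            s = 0.1, w = 100), class = c("ratio_estimates", "data.frame"))
  m <- mr_mode(r, weighted = FALSE, n_boot = 50, seed = 1)
  h_bw <- 0.9 * min(sd(r$b), mad(r$b, constant = 1) / 0.6745) * 4^(-1 / 5)
  if (h_bw == 0) h_bw <- 0.9 * sd(r$b) * 4^(-1 / 5) # bandwidth fallback when MAD = 0
  grid_step <- (diff(range(r$b)) + 6 * h_bw) / 511
  expect_lt(abs(m$estimate - 0.2), grid_step + 1e-12)
  # all ratios equal: the estimate is that value exactly
  rd <- structure(data.frame(variant_id = letters[1:3], b = 0.4, s = 0.1, w = 100),
                  class = c("ratio_estimates", "data.frame"))
  expect_equal(mr_mode(rd, n_boot = 50, seed = 1)$estimate, 0.4)
  # dense-grid oracle within one coarse-grid step
  set.seed(66)
  for (s in 1:8) {
    n <- 7
    b <- rnorm(n, 0.3, 0.2)
    w <- runif(n, 0.5, 2)
    rr <- structure(data.frame(variant_id = paste0("v", 1:n), b = b, s = w^-0.5, w = w),
                    class = c("ratio_estimates", "data.frame"))
    for (weighted in c(TRUE, FALSE)) {
      est <- mr_mode(rr, weighted = weighted, phi = 1, n_boot = 50, seed = 2)$estimate
      wt <- if (weighted) w else rep(1, n)
      h_bw <- 0.9 * min(sd(b), mad(b, constant = 1) / 0.6745) * n^(-1 / 5)
      step <- (diff(range(b)) + 6 * h_bw) / 511
      expect_lt(abs(est - oracle_mode(b, wt)), step + 1e-12)
    }
  }
})

test_that("estimators are scale-equivariant and exposure-flip invariant", {
  h <- make_hset(8, seed = 71)
  k <- 2.7
  hk <- harmonized_set(h$variant_id, h$beta_exp, h$se_exp,
                       k * h$beta_out, k * h$se_out)
  hf <- harmonized_set(h$variant_id, -h$beta_exp, h$se_exp,
                       -h$beta_out, h$se_out)
  for (fn in list(function(x) mr_ivw(x),
                  function(x) mr_egger(x),
                  function(x) mr_weighted_median(x, n_boot = 80, seed = 5),
                  function(x) mr_mode(x, n_boot = 80, seed = 5))) {
    base <- fn(h)
    scaled <- fn(hk)
    flipped <- fn(hf)
    expect_equal(scaled$estimate, k * base$estimate, tolerance = 1e-6)
    expect_equal(scaled$se, k * base$se, tolerance = 1e-6)
    expect_equal(flipped$estimate, base$estimate, tolerance = 1e-10)
  }
})

test_that("bootstrap standard errors are reproducible from the seed", {
  h <- make_hset(7, seed = 81)
  a <- mr_weighted_median(h, n_boot = 200, seed = 99)
  b <- mr_weighted_median(h, n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(h, n_boot = 200, seed = 100)
  expect_false(identical(a$se, c$se))
  m1 <- mr_mode(h, n_boot = 200, seed = 99)
  m2 <- mr_mode(h, n_boot = 200, seed = 99)
  expect_identical(m1$se, m2$se)
  expect_error(mr_weighted_median(h, n_boot = 10), class = "mrmediate_config_error")
})

test_that("with strong homogeneous instruments all five estimators agree", {
  set.seed(91)
  n <- 12
  h <- harmonized_set(sprintf("v%d", 1:n),
                      beta_exp = runif(n, 0.2, 0.5) * sample(c(-1, 1), n, TRUE),
                      se_exp = 1e-4, beta_out = NA, se_out = 1e-4)
  h$beta_out <- 0.25 * h$beta_exp + rnorm(n, 0, 1e-5)
  res <- mr_all(h, mr_config(seed = 4, n_boot = 100))
  expect_equal(nrow(res), 5L)
  expect_true(all(abs(res$estimate - 0.25) < 5e-3))
  # CI bounds follow the normal construction
  expect_equal(res$ci_low, res$estimate - qnorm(0.975) * res$se, tolerance = 1e-9)
  expect_equal(res$ci_high, res$estimate + qnorm(0.975) * res$se, tolerance = 1e-9)
})
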