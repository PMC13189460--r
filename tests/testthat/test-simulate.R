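test_that("simulated tables follow the stated SE formula and are seed-reproducible", {
  tr <- sim_truth(n_snp = 15, theta_a = 0.2, theta_b = -0.3, theta_dir = 0.1, seed = 171)
  sim1 <- simulate_summary(tr)
  sim2 <- simulate_summary(tr)
  expect_identical(sim1, sim2)
  for (tab in list(sim1$exposure, sim1$mediator, sim1$outcome)) {
    n <- tab$n[1]
    expect_equal(tab$se, 1 / sqrt(2 * tab$eaf * (1 - tab$eaf) * n), tolerance = 1e-12)
    # z reproduces the p-value
    expect_equal(tab$pval, 2 * pnorm(-abs(tab$beta / tab$se)), tolerance = 1e-12)
  }
  expect_equal(nrow(sim1$exposure), tr$n_snp + tr$n_snp_med)
  # truth bookkeeping
  expect_equal(tr$total, 0.1 + 0.2 * -0.3)
  expect_equal(tr$proportion, 0.2 * -0.3 / tr$total)
  expect_error(sim_truth(maf_range = c(0, 0.6)), class = "mrmediate_validation_error")
})

test_that("estimates converge to the truth as sample sizes grow", {
  tr <- sim_truth(n_snp = 40, theta_a = -0.125, theta_b = -0.223, theta_dir = 0.140125,
                  n_exp = 5e5, n_med = 2e5, n_out = 5e5, seed = 181)
  sim <- simulate_summary(tr)
  cfg <- mr_config(seed = 181)
  ha <- harmonize(select_instruments(sim$exposure, sim$ld), sim$mediator)
  hb <- harmonize(select_instruments(sim$mediator, sim$ld, p_threshold = 5e-8), sim$outcome)
  ht <- harmonize(select_instruments(sim$exposure, sim$ld), sim$outcome)
  expect_equal(mr_ivw(ha)$estimate, tr$theta_a, tolerance = 0.05)
  expect_equal(mr_ivw(hb)$estimate, tr$theta_b, tolerance = 0.05)
  expect_equal(mr_ivw(ht)$estimate, tr$total, tolerance = 0.05)
})

test_that("directional pleiotropy surfaces in the Egger intercept", {
  # positive instrument effects keep constant pleiotropy directional
  # under Egger's orientation convention
  tr <- sim_truth(n_snp = 40, theta_a = 0, theta_b = 0, theta_dir = 0.2,
                  gamma = seq(0.08, 0.3, length.out = 40),
                  pleiotropy_mean = 0.05, pleiotropy_sd = 0.002,
                  n_exp = 2e5, n_out = 2e5, seed = 191)
  sim <- simulate_summary(tr)
  ht <- harmonize(select_instruments(sim$exposure, sim$ld), sim$outcome)
  e <- mr_egger(ht)
  expect_lt(abs(e$egger_intercept - 0.05), 0.01)
})

test_that("balanced pleiotropy inflates Q while IVW stays centred", {
  set.seed(201)
  ests <- numeric(40)
  qrej <- logical(40)
  for (i in 1:40) {
    tr <- sim_truth(n_snp = 25, theta_a = 0, theta_b = 0, theta_dir = 0.15,
                    pleiotropy_mean = 0, pleiotropy_sd = 0.02,
                    n_exp = 1e5, n_out = 1e5, seed = 5000 + i)
    sim <- simulate_summary(tr)
    ht <- harmonize(select_instruments(sim$exposure, sim$ld), sim$outcome)
    ests[i] <- mr_ivw(ht)$estimate
    qrej[i] <- cochran_q(ht)$q_pval < 0.05
  }
  expect_lt(abs(median(ests) - 0.15), 0.02)
  expect_gt(mean(qrej), 0.5) # far above the nominal 5%
})

test_that("individual-level and summary-level estimates agree with the 2SLS oracle", {
  tr <- sim_truth(n_snp = 10, n_snp_med = 5, theta_a = 0.3, theta_b = 0.2,
                  theta_dir = 0.1, gamma = rep(0.25, 10), seed = 211)
  sim <- simulate_individual(tr, n_per_cohort = c(20000, 20000, 20000))
  ha <- harmonize(select_instruments(sim$exposure, sim$ld, p_threshold = 1e-4),
                  sim$mediator)
  ivw_a <- mr_ivw(ha)
  # within 3 combined SEs of the individual-level 2SLS oracle
  tol <- 3 * sqrt(ivw_a$se^2 + sim$oracle$tsls_a_se^2)
  expect_lt(abs(ivw_a$estimate - sim$oracle$tsls_a), tol)
  expect_lt(abs(ivw_a$estimate - tr$theta_a), 0.05)
  # determinism
  sim2 <- simulate_individual(tr, n_per_cohort = c(20000, 20000, 20000))
  expect_identical(sim$exposure, sim2$exposure)
})

test_that("null exposure effects yield no instruments at the suggestive threshold", {
  tr <- sim_truth(n_snp = 12, gamma = rep(0, 12), n_snp_med = 0, seed = 221)
  sim <- simulate_summary(tr)
  inst <- select_instruments(sim$exposure, sim$ld, p_threshold = 5e-6)
  expect_equal(nrow(inst), 0L)
})

test_that("block LD co-locates block members for clumping", {
  tr <- sim_truth(n_snp = 8, n_snp_med = 0, gamma = rep(0.3, 8), seed = 231)
  sim <- simulate_summary(tr, ld_blocks = list(block_size = 4, within_r2 = 0.8))
  inst <- clump(sim$exposure, sim$ld, p_threshold = 0.99, r2_cutoff = 0.1)
  expect_equal(nrow(inst), 2L) # one index per block
})

test_that("the screening scenario plants exactly one causal pathway", {
  tr <- sim_truth(n_snp = 10, theta_a = -0.1, theta_b = -0.3, theta_dir = 0.1,
                  n_exp = 5e4, n_med = 5e4, n_out = 5e4, seed = 241)
  sc <- simulate_screen_scenario(tr, n_exposures = 3, n_mediators = 2)
  expect_length(sc$exposures, 3L)
  expect_length(sc$mediators, 2L)
  # all tables share one variant namespace
  ids <- sc$outcomes$outcome$variant_id
  expect_equal(sort(sc$exposures[[1]]$variant_id), sort(ids))
  expect_equal(sort(sc$mediators[[2]]$variant_id), sort(ids))
  # planted legs carry signal, null legs do not
  h_a <- harmonize(select_instruments(sc$exposures$exposure01, sc$ld), sc$mediators$mediator01)
  expect_lt(mr_ivw(h_a)$pval, 1e-4)
  h_null <- harmonize(select_instruments(sc$exposures$exposure02, sc$ld), sc$outcomes$outcome)
  expect_gt(mr_ivw(h_null)$pval, 0.001)
})
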