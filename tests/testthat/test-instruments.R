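test_that("F-statistic is (beta/se)^2", {
  expect_equal(f_statistic(0.1, 0.05), 4)
  expect_equal(f_statistic(0.5, 0.05), 100)
  expect_equal(f_statistic(0, 0.3), 0)
  expect_error(f_statistic(0.1, 0), class = "mrmediate_validation_error")
})

test_that("clumping keeps one variant per fully linked locus and all unlinked ones", {
  ss <- make_ss(paste0("rs", 1:5), beta = rep(0.3, 5), se = 0.03,
                pval = c(1e-8, 1e-7, 1e-9, 1e-6 / 2, 1e-7),
                pos = seq(1e6, by = 1000, length.out = 5))
  full <- ld_info(ss$variant_id, matrix(1, 5, 5))
  out <- clump(ss, full, p_threshold = 5e-6)
  expect_equal(out$variant_id, "rs3") # smallest p
  none <- ld_identity(ss$variant_id)
  out2 <- clump(ss, none, p_threshold = 5e-6)
  expect_equal(nrow(out2), 5L)
})

test_that("greedy clumping follows the documented trace", {
  # A(1e-8) B(1e-7) C(1e-6) D(1e-3); r2 AB=0.5, AC=0.05, BC=0.3
  ss <- make_ss(c("A", "B", "C", "D"), beta = 0.3, se = 0.03,
                pval = c(1e-8, 1e-7, 1e-6, 1e-3),
                pos = c(1e6, 1.1e6, 1.2e6, 1.3e6))
  r2 <- diag(1, 4)
  dimnames(r2) <- list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  r2["A", "B"] <- r2["B", "A"] <- 0.5
  r2["A", "C"] <- r2["C", "A"] <- 0.05
  r2["B", "C"] <- r2["C", "B"] <- 0.3
  ld <- ld_info(c("A", "B", "C", "D"), r2)
  out <- clump(ss, ld, p_threshold = 5e-6, r2_cutoff = 0.1)
  expect_setequal(out$variant_id, c("A", "C"))
  log <- attr(out, "selection_log")
  expect_equal(log$n_fail_p, 1L)   # D
  expect_equal(log$n_clumped, 1L)  # B clumped to A
})

test_that("clumping respects the window and is order-invariant", {
  # two fully linked variants placed outside the window are both kept
  ss <- make_ss(c("a", "b"), beta = 0.3, se = 0.03, pval = c(1e-9, 1e-8),
                pos = c(1e6, 1e6 + 10000 * 1000 + 1))
  ld <- ld_info(c("a", "b"), matrix(c(1, 1, 1, 1), 2))
  expect_equal(nrow(clump(ss, ld, window_kb = 10000)), 2L)
  # inclusive boundary: exactly window_kb apart is inside
  ss2 <- make_ss(c("a", "b"), beta = 0.3, se = 0.03, pval = c(1e-9, 1e-8),
                 pos = c(1e6, 1e6 + 10000 * 1000))
  expect_equal(nrow(clump(ss2, ld, window_kb = 10000)), 1L)
  # row order never matters
  set.seed(3)
  ss3 <- make_ss(sprintf("s%02d", 1:12), beta = rnorm(12, 0.3, 0.05), se = 0.03,
                 pval = runif(12, 1e-10, 1e-6), pos = seq(1e6, by = 5e5, length.out = 12))
  ld3 <- make_ld_blocks(12, 3, 0.6, variant_ids = ss3$variant_id)
  ref <- clump(ss3, ld3)$variant_id
  shuf <- as.data.frame(ss3)[sample(12), ]
  out <- clump(sumstats(shuf, "trait"), ld3)$variant_id
  expect_equal(out, ref)
})

test_that("equal p-values break ties lexicographically", {
  ss <- make_ss(c("zz", "aa"), beta = 0.3, se = 0.03, pval = c(1e-8, 1e-8),
                pos = c(1e6, 1.1e6))
  ld <- ld_info(c("zz", "aa"), matrix(c(1, 0.9, 0.9, 1), 2))
  expect_equal(clump(ss, ld)$variant_id, "aa")
})

test_that("every clumped-away variant is linked to a retained better variant", {
  set.seed(5)
  n <- 30
  ss <- make_ss(sprintf("s%02d", 1:n), beta = rnorm(n, 0.3, 0.1), se = 0.03,
                pval = runif(n, 1e-12, 1e-6),
                pos = rep(seq(1e6, by = 2e5, length.out = 6), each = 5))
  ld <- make_ld_blocks(n, 5, 0.5, variant_ids = ss$variant_id)
  out <- clump(ss, ld, r2_cutoff = 0.1)
  removed <- setdiff(ss$variant_id, out$variant_id)
  for (v in removed) {
    pr <- ss$pval[ss$variant_id == v]
    linked <- out$variant_id[ld$r2[v, out$variant_id] >= 0.1]
    expect_true(any(ss$pval[ss$variant_id %in% linked] <= pr))
  }
})

test_that("missing LD pairs are kept under the default policy and dropped under 'drop'", {
  ss <- make_ss(c("a", "b"), beta = 0.3, se = 0.03, pval = c(1e-9, 1e-8),
                pos = c(1e6, 1.1e6))
  ld <- ld_identity("a") # b unknown to the LD source
  keep <- clump(ss, ld, missing_ld = "zero")
  expect_setequal(keep$variant_id, c("a", "b"))
  expect_equal(attr(keep, "selection_log")$n_missing_ld_pairs, 1L)
  drop <- clump(ss, ld, missing_ld = "drop")
  expect_equal(drop$variant_id, "a")
})

test_that("empty post-threshold set returns an empty set, not an error", {
  ss <- make_ss(c("a", "b"), beta = 0.01, se = 0.05, pval = c(0.5, 0.9))
  out <- clump(ss, ld_identity(c("a", "b")))
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "selection_log")$n_fail_p, 2L)
  expect_equal(nrow(filter_instruments(out)), 0L)
})

test_that("F filtering matches the brute-force rule on simulated records", {
  set.seed(9)
  beta <- rnorm(100, 0, 0.1)
  ss <- make_ss(sprintf("s%03d", 1:100), beta = beta, se = 0.05, pval = runif(100))
  out <- filter_instruments(ss, min_f = 10)
  expect_equal(nrow(out), sum((beta / 0.05)^2 >= 10))
  expect_equal(nrow(filter_instruments(make_ss("a", 0.1, 0.05), min_f = 10)), 0L)
  expect_equal(nrow(filter_instruments(make_ss("a", 0.5, 0.05), min_f = 10)), 1L)
})

test_that("block LD fixtures drive clumping as constructed", {
  ss <- make_ss(paste0("snp", 1:4), beta = 0.3, se = 0.03,
                pval = c(1e-8, 1e-7, 1e-9, 1e-6 / 5),
                pos = c(1e6, 1.001e6, 2e6, 2.001e6))
  ld <- make_ld_blocks(4, 2, 0.8)
  expect_equal(nrow(clump(ss, ld, r2_cutoff = 0.1)), 2L)
  ld0 <- make_ld_blocks(4, 2, 0)
  expect_equal(nrow(clump(ss, ld0, r2_cutoff = 0.1)), 4L)
  # strictly below the cutoff is retained
  ld9 <- make_ld_blocks(10, 5, 0.09)
  ss10 <- make_ss(paste0("snp", 1:10), beta = 0.3, se = 0.03, pval = rep(1e-8, 10),
                  pos = rep(c(1e6, 2e6), each = 5) + rep(1:5 * 100, 2))
  expect_equal(nrow(clump(ss10, ld9, r2_cutoff = 0.1)), 10L)
  expect_error(make_ld_blocks(4, 5, 0.5), class = "mrmediate_validation_error")
})
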