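test_that("comparative-CT relative expression follows log2 arithmetic", {
  expect_equal(qpcr_relative_expression(24, 24), 1.0)
  expect_equal(qpcr_relative_expression(25, 24), 0.5)
  # a target ~3.32 cycles below the reference is ~10-fold above it
  expect_equal(qpcr_relative_expression(24 - log2(10), 24), 10, tolerance = 1e-12)

  # technical replicates average on the Ct scale within experiment
  r <- qpcr_relative_expression(ct_target = c(24, 24.2, 23.8, 25, 25.1, 24.9),
                                ct_reference = rep(22, 6),
                                experiment = c(1, 1, 1, 2, 2, 2))
  expect_equal(r, 2^(22 - mean(c(24, 25))), tolerance = 1e-12)

  expect_error(qpcr_relative_expression(24, NA_real_), "missing reference")
})

test_that("expression ratio is invariant to a plate shift of both Ct values", {
  set.seed(5)
  ct_t <- rnorm(9, 24, 0.2)
  ct_r <- rnorm(9, 18, 0.2)
  e <- rep(1:3, each = 3)
  expect_equal(qpcr_relative_expression(ct_t + 1.7, ct_r + 1.7, e),
               qpcr_relative_expression(ct_t, ct_r, e), tolerance = 1e-12)
})

test_that("exact Mann-Whitney matches full enumeration at 6 vs 6", {
  x <- 1:6
  y <- 7:12
  res <- mann_whitney_exact(x, y)
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 2 / 924, tolerance = 1e-12)

  # one exceeding pair: U = 1, p = 4/924
  res1 <- mann_whitney_exact(c(1, 2, 3, 4, 5, 6.5), c(6, 7, 8, 9, 10, 11))
  expect_equal(res1$u, 1)
  expect_equal(res1$p_value, 4 / 924, tolerance = 1e-12)

  ident <- mann_whitney_exact(c(3, 3, 3), c(3, 3, 3))
  expect_equal(ident$p_value, 1.0)
})

test_that("exact p equals independent oracles for all group sizes up to 7", {
  set.seed(77)
  for (n1 in 2:7) {
    for (n2 in 2:7) {
      x <- rnorm(n1)
      y <- rnorm(n2, 0.5)
      mine <- mann_whitney_exact(x, y)
      expect_equal(mine$method, "exact")
      # oracle 1: R's exact Wilcoxon (tie-free data)
      ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10,
                   label = sprintf("p at n1=%d n2=%d", n1, n2))
      # oracle 2: direct pair counting for U
      expect_equal(mine$u, count_u(x, y))
    }
  }
})

test_that("ties are handled by mid-ranks within the enumeration", {
  x <- c(1, 2, 2, 3)
  y <- c(2, 3, 3, 4)
  mine <- mann_whitney_exact(x, y)
  expect_equal(mine$u, count_u(x, y))
  # oracle: enumerate labelings, counting U by pairs
  pooled <- c(x, y)
  labelings <- combn(8, 4)
  u_all <- apply(labelings, 2, function(idx) count_u(pooled[idx], pooled[-idx]))
  u_low <- min(mine$u, 16 - mine$u)
  p_oracle <- mean(u_all <= u_low + 1e-9 | u_all >= 16 - u_low - 1e-9)
  expect_equal(mine$p_value, p_oracle, tolerance = 1e-12)
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(88)
  x <- rnorm(10)
  y <- rnorm(10, 0.8)
  mine <- mann_whitney_exact(x, y)
  expect_equal(mine$method, "normal_approximation")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("ChIP enrichment applies the input-fraction correction", {
  expect_equal(chip_fold_enrichment(24, 24, 1), 1.0)
  expect_equal(chip_fold_enrichment(22, 24, 1), 4.0)
  # reserving 10% input adds log2(10) cycles of input correction
  expect_equal(chip_fold_enrichment(24, 24, 0.1), 10, tolerance = 1e-12)
  expect_equal(chip_fold_enrichment(20.68, 24, 0.1),
               2^(-(20.68 - (24 - log2(0.1)))), tolerance = 1e-12)
  expect_error(chip_fold_enrichment(24, 24, 0), "input_fraction")
})

test_that("rate fitting recovers k exactly on noiseless traces", {
  tr <- generate_kinetics_trace(k = 0.1, a0 = 1.0, a_inf = 0.2,
                                times = seq(0, 20, 0.5))
  fit <- fit_first_order_rate(tr, a_inf = 0.2)
  expect_equal(fit$k, 0.1, tolerance = 1e-6)

  # per-mg normalization
  fit2 <- fit_first_order_rate(tr, a_inf = 0.2, protein_mg = 0.5)
  expect_equal(fit2$k, 0.2, tolerance = 1e-6)

  # constant trace above the plateau has zero rate
  flat <- data.frame(time = 0:5, absorbance = rep(1, 6))
  expect_equal(fit_first_order_rate(flat, a_inf = 0.2)$k, 0)

  # points at or below the plateau are dropped; too few left is an error
  short <- data.frame(time = 0:3, absorbance = c(1, 0.19, 0.18, 0.17))
  expect_error(fit_first_order_rate(short, a_inf = 0.2), "fewer than 3")
})

test_that("plateau estimation from the trace tail is reported", {
  tr <- generate_kinetics_trace(k = 0.3, a0 = 1.0, a_inf = 0.2,
                                times = seq(0, 30, 0.25))
  fit <- fit_first_order_rate(tr)
  expect_true(fit$a_inf_estimated)
  expect_lt(abs(fit$a_inf - 0.2), 0.01)
  expect_lt(abs(fit$k - 0.3), 0.02)
})

test_that("estimator bias vanishes as trace noise shrinks", {
  err <- vapply(c(0.01, 0.003, 0.001, 0), function(ns) {
    tr <- generate_kinetics_trace(k = 0.1, a0 = 1, a_inf = 0.2,
                                  noise_sd = ns, times = seq(0, 15, 0.25),
                                  seed = 99)
    abs(fit_first_order_rate(tr, a_inf = 0.2)$k - 0.1)
  }, numeric(1))
  expect_lt(err[4], 1e-9)
  expect_lt(err[3], err[1] + 1e-9)
  expect_lt(max(err), 0.02)
})

test_that("a 60% knockdown in the rate constant is recovered from paired traces", {
  k_ctl <- 0.10
  tr_ctl <- generate_kinetics_trace(k_ctl, 1, 0.2, times = seq(0, 20, 0.5))
  tr_kd <- generate_kinetics_trace(0.6 * k_ctl, 1, 0.2, times = seq(0, 20, 0.5))
  f_ctl <- fit_first_order_rate(tr_ctl, a_inf = 0.2)
  f_kd <- fit_first_order_rate(tr_kd, a_inf = 0.2)
  expect_equal(f_kd$k / f_ctl$k, 0.6, tolerance = 1e-6)
})

test_that("COX/CS normalization is a guarded ratio", {
  expect_equal(cox_cs_ratio(0, 100), 0)
  expect_equal(cox_cs_ratio(0.06, 100), 6e-4)
  expect_equal(cox_cs_ratio(0.06, 50), 2 * cox_cs_ratio(0.06, 100))
  expect_error(cox_cs_ratio(0.06, 0), "cs_activity")
})

test_that("planted 2-fold qPCR effects reach significance with 80% power", {
  hits <- vapply(1:60, function(i) {
    tab <- generate_qpcr_table(n_per_group = 6,
                               gene_effects = c("RTT-FC" = 1),
                               biological_sd = 0.25, seed = 1000 + i)
    res <- qpcr_compare_groups(tab, c("RTT-FC", "CTL-FC"))
    res$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("group comparison reports the four-group layout quantities", {
  tab <- generate_qpcr_table(n_per_group = 6, gene_effects = c("RTT-FC" = 1),
                             seed = 7)
  res <- qpcr_compare_groups(tab, c("RTT-FC", "RTT-OC"))
  expect_gt(res$ratio, 1.4)        # planted 2-fold, attenuated by noise
  expect_lt(res$p_value, 0.05)
  expect_equal(res$method, "exact")
})
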