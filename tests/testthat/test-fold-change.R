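test_that("threshold calibration reproduces the printed criterion pair", {
  cal <- fold_thresholds(0.25)
  expect_identical(cal$up_threshold, 1.5)
  expect_identical(cal$down_threshold, 0.67)

  expect_equal(fold_thresholds(0)$up_threshold, 1.0)

  # hand-computed: sd({1.0,1.1,0.9,1.2,0.8}) = sqrt(0.025)
  cal2 <- calibrate_fold_threshold(c(1.0, 1.1, 0.9, 1.2, 0.8))
  expect_equal(cal2$sigma, sqrt(0.025), tolerance = 1e-12)
  expect_equal(cal2$up_threshold, 1 + 2 * sqrt(0.025), tolerance = 1e-12)
  expect_equal(cal2$up_threshold, 1.316, tolerance = 1e-3)

  expect_error(calibrate_fold_threshold(1.0), "at least 2")
})

test_that("down threshold is the reciprocal within rounding for any sigma", {
  for (sigma in c(0.05, 0.1, 0.25, 0.4, 0.6)) {
    cal <- fold_thresholds(sigma)
    expect_lt(abs(cal$up_threshold * cal$down_threshold - 1),
              0.005 * cal$up_threshold + 1e-9)
  }
})

test_that("dye-swap reconciliation averages sign-reconciled log ratios", {
  expect_equal(reconcile_dye_swap(1, -1), 2.0)
  expect_equal(reconcile_dye_swap(1, 1), 1.0)   # discordant pair cancels
  # algebraic oracle on random pairs
  set.seed(12)
  f <- rnorm(50); s <- rnorm(50)
  expect_equal(reconcile_dye_swap(f, s), 2^((f - s) / 2), tolerance = 1e-12)
  expect_equal(reconcile_dye_swap(f, s),
               2^rowMeans(cbind(f, -s)), tolerance = 1e-12)
  # single-orientation propagation and full missingness
  expect_equal(reconcile_dye_swap(c(1, NA, NA), c(NA, -2, NA)),
               c(2, 4, NA))
})

test_that("consensus calling follows the k-of-6 rule with direction consistency", {
  cal <- fold_thresholds(0.25)
  up5 <- call_de_foldchange(c(2.0, 2.1, 1.9, 2.2, 2.0, 1.0), cal, 5)
  expect_equal(up5$direction, "up")
  expect_equal(up5$support_count, 5L)
  expect_equal(up5$mean_fold_change, mean(c(2.0, 2.1, 1.9, 2.2, 2.0, 1.0)))
  expect_equal(up5$sem, up5$sd / sqrt(6))

  expect_equal(call_de_foldchange(rep(1.4, 6), cal, 5)$direction, "none")

  down <- call_de_foldchange(c(0.5, 0.6, 0.5, 0.4, 0.6, 0.9), cal, 5)
  expect_equal(down$direction, "down")

  # mixed-direction passes never combine into a call
  mixed <- call_de_foldchange(c(2, 2, 2, 0.5, 0.5, 0.5), cal, 3)
  expect_equal(mixed$direction, "none")
  mixed2 <- call_de_foldchange(c(2, 2, 0.5, 0.5, 0.5, 1.0), cal, 3)
  expect_equal(mixed2$direction, "none")
  pure3 <- call_de_foldchange(c(0.5, 0.5, 0.5, 1.0, 1.0, 1.0), cal, 3)
  expect_equal(pure3$direction, "down")

  # too few usable replicates: non-evaluable, distinct from "none"
  sparse <- call_de_foldchange(c(2, 2, NA, NA, NA, NA), cal, 5)
  expect_false(sparse$evaluable)
  expect_true(is.na(sparse$direction))
})

test_that("consensus is exact over the full k-of-n sweep", {
  cal <- fold_thresholds(0.25)
  for (k in 0:6) {
    ratios <- c(rep(2, k), rep(1, 6 - k))
    call <- call_de_foldchange(ratios, cal, min_support = 5)
    expect_equal(call$direction == "up", k >= 5)
  }
  # monotonicity: increasing min_support never converts none into a call
  set.seed(31)
  for (rep_i in 1:20) {
    ratios <- exp(rnorm(6, 0, 0.5))
    prev_called <- TRUE
    for (ms in 1:6) {
      call <- call_de_foldchange(ratios, cal, min_support = ms)
      called <- isTRUE(call$direction %in% c("up", "down"))
      expect_true(prev_called | !called)
      prev_called <- called
    }
  }
})

test_that("default consensus support scales as ceiling(5/6 n)", {
  expect_equal(default_min_support(6), 5L)
  expect_equal(default_min_support(12), 10L)
  expect_equal(default_min_support(4), 4L)
})

test_that("vectorized calling matches the single-gene caller", {
  cal <- fold_thresholds(0.25)
  set.seed(19)
  mat <- matrix(exp(rnorm(60, 0, 0.5)), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), NULL))
  mat[cbind(c(2, 5), c(3, 6))] <- NA
  tab <- call_de_table(mat, cal, min_support = 5)
  for (i in 1:10) {
    single <- call_de_foldchange(mat[i, ], cal, min_support = 5)
    expect_equal(tab$direction[i], single$direction)
    expect_equal(tab$mean_fold_change[i], single$mean_fold_change)
    expect_equal(tab$sd[i], single$sd, tolerance = 1e-12)
    expect_equal(tab$sem[i], single$sem, tolerance = 1e-12)
    expect_equal(tab$evaluable[i], single$evaluable)
  }
})

test_that("fold-change arm recovers planted 2-fold genes on a synthetic study", {
  effects <- c(
    lapply(sprintf("EST%05d", 1:25), planted_effect,
           comparisons_affected = "RTTfc_vs_CONfc", fold_change = 2),
    lapply(sprintf("EST%05d", 26:40), planted_effect,
           comparisons_affected = "RTTfc_vs_CONfc", fold_change = 0.5)
  )
  cfg <- study_config(n_features = 4000, planted_effects = effects, seed = 23)
  study <- generate_study(cfg)
  rs <- comparison_ratio_sets(study$arrays$RTTfc_vs_CONfc)
  cal <- calibrate_fold_threshold(2^normalize_array(generate_self_self(cfg))$ratios$m)
  calls <- call_de_table(rs$ratios, cal)
  planted <- sprintf("EST%05d", 1:40)
  dir_truth <- rep(c("up", "down"), c(25, 15))
  hit <- calls$direction[match(planted, calls$gene_id)] == dir_truth
  expect_gte(mean(hit, na.rm = TRUE), 0.9)
})
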