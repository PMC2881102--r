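test_that("config validation names the offending field", {
  expect_error(study_config(n_features = 0), "n_features")
  expect_error(study_config(flag_rate = 1), "flag_rate")
  expect_error(study_config(self_self_ratio_sd = -0.1), "self_self_ratio_sd")
  expect_error(study_config(comparison_sets = c("a", "b", "c", "d")),
               "comparison_sets")
  expect_error(planted_effect("g", "RTTfc_vs_CONfc", fold_change = -2),
               "fold_change")
  expect_error(planted_effect("g", "nonsense", 2), "comparisons_affected")
})

test_that("planted effect direction follows the fold change", {
  expect_equal(planted_effect("g", "RTTfc_vs_CONfc", 2)$direction, "up")
  expect_equal(planted_effect("g", "RTTfc_vs_CONfc", 0.5)$direction, "down")
})

test_that("study generation is deterministic and matches the configured design", {
  cfg <- tiny_config(n_features = 200, seed = 5)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1, s2)
  expect_named(s1$arrays, comparison_labels())
  for (cmp in comparison_labels()) {
    expect_length(s1$arrays[[cmp]], 6L)
    pair <- s1$arrays[[cmp]][[3L]]
    expect_equal(pair$forward$dye_orientation, "forward")
    expect_equal(pair$swapped$dye_orientation, "swapped")
    expect_equal(nrow(pair$forward$features), 200L)
    expect_equal(nrow(pair$swapped$features), 200L)
  }
})

test_that("a planted 2-fold gene averages near ratio 2 across replicates", {
  eff <- list(planted_effect("EST00007", "RTTfc_vs_CONfc", 2))
  cfg <- tiny_config(n_features = 50, effects = eff, seed = 21, flag_rate = 0)
  study <- generate_study(cfg)
  # brute-force averaging oracle over the generated test/reference ratios
  ratios <- unlist(lapply(study$arrays$RTTfc_vs_CONfc, function(pair) {
    i <- match("EST00007", pair$forward$features$feature_id)
    c(pair$forward$features$f635[i] / pair$forward$features$f532[i],
      pair$swapped$features$f532[i] / pair$swapped$features$f635[i])
  }))
  expect_length(ratios, 12L)
  expect_lt(abs(mean(ratios) - 2), 0.25)
  # and the gene is untouched in the other comparisons
  other <- unlist(lapply(study$arrays$CONfc_vs_CONoc, function(pair) {
    i <- match("EST00007", pair$forward$features$feature_id)
    pair$forward$features$f635[i] / pair$forward$features$f532[i]
  }))
  expect_lt(abs(mean(other) - 1), 0.3)
})

test_that("dye-swap symmetry: noise-free swapped arrays negate the log ratio", {
  eff <- list(planted_effect("EST00003", "RTTfc_vs_CONfc", 2),
              planted_effect("EST00005", "RTTfc_vs_CONfc", 0.5))
  cfg <- tiny_config(n_features = 10, effects = eff, seed = 2,
                     flag_rate = 0, self_self_ratio_sd = 0)
  pair <- generate_study(cfg)$arrays$RTTfc_vs_CONfc[[1L]]
  m_fwd <- log2(pair$forward$features$f635 / pair$forward$features$f532)
  m_swp <- log2(pair$swapped$features$f635 / pair$swapped$features$f532)
  expect_equal(m_fwd, -m_swp, tolerance = 1e-12)
  expect_equal(m_fwd[3L], 1)   # the planted fold, exactly, without noise
  expect_equal(m_fwd[5L], -1)
})

test_that("self-self ratios are centered at 1 with the configured spread", {
  cfg <- study_config(seed = 7)
  ss <- generate_self_self(cfg)
  r <- ss$features$f635 / ss$features$f532
  expect_equal(nrow(ss$features), 19008L)
  expect_lt(abs(stats::median(r) - 1), 0.02)
  expect_lt(abs(sd(r) - 0.25), 0.025)   # within 10% of the calibration value

  cfg0 <- tiny_config(n_features = 40, self_self_ratio_sd = 0, flag_rate = 0)
  r0 <- with(generate_self_self(cfg0)$features, f635 / f532)
  expect_equal(r0, rep(1, 40))

  cfg1 <- study_config(n_features = 10000, self_self_ratio_sd = 0.1,
                       planted_effects = list(), seed = 13)
  r1 <- with(generate_self_self(cfg1)$features, f635 / f532)
  se <- 0.1 / sqrt(2 * 10000)
  expect_lt(abs(sd(r1) - 0.1), 3 * se)
})

test_that("truth registry agrees with independent set algebra", {
  effects <- list(
    planted_effect("gA", c("RTTfc_vs_CONfc", "RTTfc_vs_RTToc"), 2),
    planted_effect("gB", c("RTTfc_vs_CONfc", "RTTfc_vs_RTToc", "CONfc_vs_CONoc"), 2),
    planted_effect("gC", c("RTTfc_vs_RTToc", "CONfc_vs_CONoc"), 0.5),
    planted_effect("gD", "RTTfc_vs_CONfc", 3),
    planted_effect("gE", c("RTTfc_vs_CONfc", "RTTfc_vs_RTToc"), 0.25)
  )
  cfg <- tiny_config(n_features = 20, effects = effects)
  truth <- synthetic_truth(cfg)
  # oracle: brute-force set algebra over the effect declarations
  in_cmp <- function(cmp) {
    vapply(effects, function(e) cmp %in% e$comparisons_affected, logical(1))
  }
  ids <- vapply(effects, function(e) e$gene_id, character(1))
  oracle <- setdiff(intersect(ids[in_cmp("RTTfc_vs_CONfc")],
                              ids[in_cmp("RTTfc_vs_RTToc")]),
                    ids[in_cmp("CONfc_vs_CONoc")])
  expect_setequal(truth$frontal_exclusive, oracle)
  expect_equal(unname(truth$direction[c("gA", "gE")]), c("up", "down"))
  expect_equal(truth$log_ratio$RTTfc_vs_CONfc[["gD"]], log2(3))
})

test_that("null comparisons share the self-self ratio distribution", {
  cfg <- study_config(n_features = 6000, planted_effects = list(),
                      flag_rate = 0, seed = 17)
  pair <- generate_study(cfg)$arrays$RTTfc_vs_CONfc[[1L]]
  r_cmp <- pair$forward$features$f635 / pair$forward$features$f532
  r_ss <- with(generate_self_self(cfg)$features, f635 / f532)
  expect_lt(abs(sd(r_cmp) / sd(r_ss) - 1), 0.05)
})

test_that("qPCR generator encodes planted effects as Ct shifts", {
  tab <- generate_qpcr_table(n_per_group = 6, seed = 3)
  expect_equal(sort(unique(tab$group)), sort(c("RTT-FC", "RTT-OC", "CTL-FC", "CTL-OC")))
  expect_equal(length(unique(tab$sample_id)), 24L)
  expect_equal(nrow(tab), 24L * 3L * 3L)

  # null case: group means equal within noise
  expr <- qpcr_sample_expression(tab)
  means <- tapply(expr$expression, expr$group, mean)
  expect_lt(max(means) / min(means), 1.35)

  # planted 2-fold up in RTT-FC shifts the target Ct by -1 cycle
  tab2 <- generate_qpcr_table(n_per_group = 6,
                              gene_effects = c("RTT-FC" = 1), seed = 3)
  dct <- tapply(tab2$ct_target - tab2$ct_reference, tab2$group, mean)
  shift <- dct[["RTT-FC"]] - mean(dct[c("RTT-OC", "CTL-FC", "CTL-OC")])
  expect_lt(abs(shift - (-1)), 0.35)
})

test_that("kinetics traces follow the first-order closed form", {
  flat <- generate_kinetics_trace(k = 0, a0 = 1, a_inf = 0.2, noise_sd = 0,
                                  times = 0:10)
  expect_equal(flat$absorbance, rep(1, 11))

  tr <- generate_kinetics_trace(k = 0.1, a0 = 1, a_inf = 0.2, noise_sd = 0,
                                times = seq(0, 10, by = 1))
  expect_equal(tr$absorbance[tr$time == 10], 0.2 + 0.8 * exp(-1),
               tolerance = 1e-12)

  expect_error(generate_kinetics_trace(k = 0.1, a0 = 0.2, a_inf = 0.5),
               "a0 must exceed a_inf")
  expect_error(generate_kinetics_trace(k = 0.1, a0 = 1, a_inf = 0,
                                       times = c(0, 1, 1)),
               "strictly increasing")
})
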