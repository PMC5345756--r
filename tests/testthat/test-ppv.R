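test_that("point-mass scenarios give degenerate predictive values", {
  des <- design_small("fixed")

  null_only <- effect_size_scenario("custom", support = 0, weights = 1)
  p0 <- ppv_analysis(des, null_only, n_reps = 4000, seed = 61)
  expect_equal(p0$summary$ppv_any, 0)
  expect_lt(abs(p0$summary$p_significant - 0.05), 0.012) # ~type I error

  big_only <- effect_size_scenario("custom", support = 1, weights = 1)
  p1 <- ppv_analysis(des, big_only, n_reps = 4000, seed = 62)
  expect_equal(p1$summary$ppv_any, 1)
  expect_equal(p1$summary$p_detect_any, p1$summary$p_significant)
  expect_lt(abs(p1$summary$p_significant - analytic_fixed_power(1, 18)), 0.02)
})

test_that("PPV matches the closed-form two-point mixture", {
  des <- design_small("fixed")
  sc <- effect_size_scenario("custom", support = c(0, 1), weights = c(0.8, 0.2))
  pp <- ppv_analysis(des, sc, n_reps = 1e4, seed = 63)

  pw <- analytic_fixed_power(1, 18)
  want <- 0.2 * pw / (0.2 * pw + 0.8 * 0.05)
  s <- pp$summary
  n_sig <- round(s$p_significant * s$n_reps)
  se <- sqrt(want * (1 - want) / n_sig)
  expect_lt(abs(s$ppv_any - want), 3 * se)

  # product identity is exact on the estimates
  expect_equal(s$p_detect_any, s$p_significant * s$ppv_any)
  expect_equal(s$p_detect_ge_half, s$p_significant * s$ppv_ge_half)
  expect_lte(s$ppv_ge_half, s$ppv_any)

  # direct and semi-analytic mixture estimates agree
  expect_lt(abs(s$ppv_any - s$ppv_any_mixture), 0.05)
  expect_lt(abs(s$p_significant - s$p_significant_mixture), 0.02)
})

test_that("shifting prior mass toward real effects never lowers the PPV", {
  des <- design_larger("freq_seq")
  weights0 <- c(0.9, 0.5, 0.1)
  ppvs <- vapply(weights0, function(w0) {
    sc <- effect_size_scenario("custom", support = c(0, 1),
                               weights = c(w0, 1 - w0))
    ppv_analysis(des, sc, n_reps = 4000, seed = 64)$summary$ppv_any_mixture
  }, numeric(1))
  expect_true(all(diff(ppvs) > 0))

  opt <- ppv_analysis(des, effect_size_scenario("optimistic"), 4000, seed = 65)
  pes <- ppv_analysis(des, effect_size_scenario("pessimistic"), 4000, seed = 65)
  expect_gt(opt$summary$ppv_any, pes$summary$ppv_any)
  expect_gt(opt$summary$p_detect_any, pes$summary$p_detect_any)
})

test_that("an all-null prior with unreachable levels flags the undefined PPV", {
  des <- gs_design(stage_schedule(c(6, 12, 18)), rule_freq_seq(rep(1e-10, 3)))
  sc <- effect_size_scenario("custom", support = 0, weights = 1)
  expect_warning(
    pp <- ppv_analysis(des, sc, n_reps = 300, seed = 66),
    class = "preclinseq_empty_result"
  )
  expect_true(is.na(pp$summary$ppv_any))
  expect_true(is.na(pp$summary$p_detect_any))
})
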