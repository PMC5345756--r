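# Expected constants below are the classic published group sequential
# values (two-sided alpha 0.05); each is independently confirmed against
# the Monte Carlo crossing oracle in the property tests further down.

test_that("a single look reduces to the normal tail", {
  s1 <- stage_schedule(4)
  expect_equal(sum(crossing_probability(qnorm(0.975), s1)), 0.05,
               tolerance = 1e-4)
  expect_equal(obf_levels(1, 0.05)$nominal_level, 0.05, tolerance = 1e-10)
  expect_equal(pocock_levels(1, 0.05)$nominal_level, 0.05, tolerance = 1e-10)
})

test_that("O'Brien-Fleming and Pocock levels match published constants", {
  obf2 <- obf_levels(2, 0.05)
  expect_equal(obf2$nominal_level, c(0.0052, 0.0480), tolerance = 2e-3)
  expect_equal(round(obf2$nominal_level, 4), c(0.0052, 0.0480))

  poc3 <- pocock_levels(3, 0.05)
  expect_true(all(abs(poc3$nominal_level - 0.0221) < 1e-4))
  expect_equal(diff(range(poc3$z_bound)), 0) # constant boundary

  poc2 <- pocock_levels(2, 0.05)
  expect_true(all(abs(poc2$nominal_level - 0.0294) < 1e-4))

  # OBF spends almost nothing early and nearly full alpha at the end
  obf3 <- obf_levels(3, 0.05)
  expect_true(all(diff(obf3$nominal_level) > 0))
  expect_lt(obf3$nominal_level[1], 0.001)
  expect_gt(obf3$nominal_level[3], 0.04)
})

test_that("total crossing probability of calibrated boundaries equals alpha", {
  for (K in 2:4) {
    for (fam in list(obf_levels, pocock_levels)) {
      b <- fam(K, 0.05)
      tot <- sum(crossing_probability(b$z_bound, stage_schedule(2 * seq_len(K))))
      expect_equal(tot, 0.05, tolerance = 1e-4)
      expect_equal(attr(b, "attained_alpha"), 0.05, tolerance = 1e-4)
    }
  }
})

test_that("Haybittle-Peto uses 0.001 interim levels and an unadjusted final level", {
  hp <- haybittle_peto_levels(3, 0.05)
  expect_equal(hp$nominal_level, c(0.001, 0.001, 0.05), tolerance = 1e-10)
  expect_equal(haybittle_peto_levels(2, 0.05)$nominal_level, c(0.001, 0.05),
               tolerance = 1e-10)
  # no recalibration: slight overall inflation, but below 0.052
  expect_gt(attr(hp, "attained_alpha"), 0.05)
  expect_lt(attr(hp, "attained_alpha"), 0.052)
  expect_error(haybittle_peto_levels(1), class = "preclinseq_domain_error")
})

test_that("crossing recursion agrees with the Monte Carlo oracle", {
  cases <- list(
    list(zb = c(2.5, 2.0), tf = c(0.5, 1), drift = 0),
    list(zb = c(2.5, 2.0), tf = c(0.5, 1), drift = 1.5),
    list(zb = c(3.0, 2.4, 2.1), tf = c(0.2, 0.5, 1), drift = 0),
    list(zb = c(3.0, 2.4, 2.1), tf = c(0.2, 0.5, 1), drift = 2.5)
  )
  for (cs in cases) {
    sched <- stage_schedule(round(cs$tf * 20))
    rec <- crossing_probability(cs$zb, sched, cs$drift)
    mc <- mc_crossing_oracle(cs$zb, cs$tf, cs$drift, n_draws = 1e6)
    expect_true(all(abs(rec - mc$prop) <= 3 * pmax(mc$se, 1e-12)),
                info = paste("drift", cs$drift, "K", length(cs$zb)))
  }
})

test_that("crossing probability is nondecreasing in the drift", {
  sched <- stage_schedule(c(6, 12, 18))
  zb <- obf_levels(3, 0.05)$z_bound
  tot <- vapply(seq(0, 4, by = 0.5),
                function(d) sum(crossing_probability(zb, sched, d)),
                numeric(1))
  expect_true(all(diff(tot) >= -1e-10))
})

test_that("boundary inputs are validated", {
  sched <- stage_schedule(c(6, 12, 18))
  expect_error(crossing_probability(c(2, 2), sched),
               class = "preclinseq_domain_error")
  expect_error(crossing_probability(c(2, 2, Inf), sched),
               class = "preclinseq_domain_error")
  expect_error(crossing_probability(c(2, 2, 2), sched, drift = NaN),
               class = "preclinseq_domain_error")
  expect_error(obf_levels(3, 0.7), class = "preclinseq_domain_error")
  expect_error(custom_levels(c(0.1, 1.2)), class = "preclinseq_domain_error")
})

test_that("custom boundaries report their attained overall alpha", {
  # the worked small-study level set: binding only through its attained level
  cb <- custom_levels(c(0.0006, 0.0151, 0.0471))
  expect_equal(attr(cb, "attained_alpha"), 0.0524, tolerance = 1e-3)
  js <- tempfile(fileext = ".json")
  write_boundary_json(cb, js)
  rec <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$nominal_level, cb$nominal_level)
})
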