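test_that("trial data generation is seed-deterministic and stage-incremental", {
  sched <- stage_schedule(c(6, 12, 18))
  d1 <- generate_trial_data(sched, 1, seed = 11)
  d2 <- generate_trial_data(sched, 1, seed = 11)
  expect_identical(d1, d2)
  expect_false(identical(d1, generate_trial_data(sched, 1, seed = 12)))

  # the first two stages do not depend on the existence of a third stage
  d12 <- generate_trial_data(stage_schedule(c(6, 12)), 1, seed = 11)
  expect_equal(
    dplyr::filter(d1, stage <= 2) |> dplyr::arrange(group, unit),
    dplyr::filter(d12, stage <= 2) |> dplyr::arrange(group, unit)
  )

  # per-stage cumulative counts match the schedule
  per_stage <- dplyr::count(dplyr::filter(d1, group == "a"), stage)
  expect_equal(cumsum(per_stage$n), sched$cumulative_n_per_group)
})

test_that("generated outcomes have the specified moments and effect size", {
  big <- stage_schedule(5e5)
  dat <- generate_trial_data(big, true_d = 0, seed = 21)
  pooled <- dat$value
  se_mean <- 1 / sqrt(length(pooled))
  expect_lt(abs(mean(pooled)), 4 * se_mean)
  expect_lt(abs(var(pooled) - 1), 0.01)

  datd <- generate_trial_data(big, true_d = 0.7, sd = 2, seed = 22)
  gap <- mean(datd$value[datd$group == "b"]) - mean(datd$value[datd$group == "a"])
  expect_equal(gap / 2, 0.7, tolerance = 0.02) # standardized difference
})

test_that("the null stage t statistic follows Student's t with 2n-2 df", {
  des <- gs_design(stage_schedule(6), rule_fixed(0.05))
  tr <- simulate_trials(des, true_d = 0, n_reps = 5e4, seed = 31)
  ks <- suppressWarnings(stats::ks.test(tr$t_value, function(q) pt(q, 10)))
  expect_gt(ks$p.value, 0.001)
})

test_that("the effect estimate carries only the analytic small-sample bias", {
  # E[d_hat] = d * sqrt(df/2) * gamma((df-1)/2) / gamma(df/2); df = 34
  df <- 34
  bias_factor <- sqrt(df / 2) * exp(lgamma((df - 1) / 2) - lgamma(df / 2))
  tr <- simulate_trials(design_small("fixed"), true_d = 1, n_reps = 2e4, seed = 41)
  se <- sd(tr$d_est) / sqrt(nrow(tr))
  expect_lt(abs(mean(tr$d_est) - bias_factor), 4 * se)
  expect_equal(mean(tr$d_est), 1.02, tolerance = 0.02)
})

test_that("effect-size scenarios validate and sample with the right frequencies", {
  expect_error(effect_size_scenario("custom", support = numeric(0), weights = numeric(0)),
               class = "preclinseq_domain_error")
  expect_error(effect_size_scenario("custom", support = c(0, 0), weights = c(0.5, 0.5)),
               class = "preclinseq_domain_error")
  expect_error(effect_size_scenario("custom", support = c(0, 1), weights = c(0.7, 0.7)),
               class = "preclinseq_domain_error")

  # point mass
  pm <- effect_size_scenario("custom", support = 1, weights = 1)
  expect_true(all(sample_true_effect(pm, 50, seed = 1) == 1))

  # 50/50 concentration
  half <- effect_size_scenario("custom", support = c(0, 1), weights = c(0.5, 0.5))
  draws <- sample_true_effect(half, 1e5, seed = 2)
  expect_gt(mean(draws == 0), 0.49)
  expect_lt(mean(draws == 0), 0.51)
  expect_identical(sample_true_effect(half, 100, seed = 3),
                   sample_true_effect(half, 100, seed = 3))

  # chi-square goodness of fit on both presets
  for (lab in c("optimistic", "pessimistic")) {
    sc <- effect_size_scenario(lab)
    dr <- sample_true_effect(sc, 1e5, seed = 4)
    obs <- vapply(sc$d, function(v) sum(dr == v), numeric(1))
    expect_gt(stats::chisq.test(obs, p = sc$weight)$p.value, 0.001)
  }
})
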