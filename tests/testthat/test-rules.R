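stats_with_p <- function(p, n = 6) {
  # construct a valid stage-statistics row with an exact two-sided p value
  df <- 2 * n - 2
  tv <- qt(1 - p / 2, df)
  tibble::tibble(
    n_a = n, n_b = n, mean_diff = tv * sqrt(2 / n), pooled_sd = 1,
    t_value = tv, df = df, p_two_sided = p,
    d_hat = tv * sqrt(2 / n)
  )
}

test_that("rule constructors validate their thresholds", {
  expect_error(rule_freq_seq(c(0.05, 1.2)), class = "preclinseq_domain_error")
  expect_error(rule_fixed(0), class = "preclinseq_domain_error")
  expect_error(rule_bayes_factor(-1), class = "preclinseq_domain_error")
  expect_error(rule_bayes_factor(2, bf_futility = 3),
               class = "preclinseq_domain_error")
  expect_error(rule_credible_interval(c(0.95, 0)),
               class = "preclinseq_domain_error")
  expect_error(gs_design(stage_schedule(c(6, 12)), rule_freq_seq(rep(0.02, 3))),
               class = "preclinseq_domain_error")
})

test_that("frequentist sequential decisions follow the stage thresholds", {
  small <- rule_freq_seq(c(0.0006, 0.0151, 0.0471))
  expect_equal(decide_freq_seq(stats_with_p(0.0001), small, 1, 3)$action,
               "stop_efficacy")
  expect_equal(decide_freq_seq(stats_with_p(0.03), small, 2, 3)$action,
               "continue")
  expect_equal(decide_freq_seq(stats_with_p(0.06), small, 3, 3)$action,
               "final_nonsignificant")

  larger <- rule_freq_seq(c(0.0065, 0.0525), futility_alpha = 0.5)
  expect_equal(decide_freq_seq(stats_with_p(0.6, n = 18), larger, 1, 2)$action,
               "stop_futility")
  expect_equal(decide_freq_seq(stats_with_p(0.2, n = 18), larger, 1, 2)$action,
               "continue")
  # futility never applies at the final stage
  expect_equal(decide_freq_seq(stats_with_p(0.9, n = 36), larger, 2, 2)$action,
               "final_nonsignificant")

  expect_error(decide_freq_seq(stats_with_p(0.5), small, 4, 3),
               class = "preclinseq_domain_error")
})

test_that("Bayes factor decisions respect success and futility thresholds", {
  r <- rule_bayes_factor(bf_success = 3)
  expect_equal(decide_bayes_factor(3.5, r, 1, 3)$action, "stop_efficacy")
  expect_equal(decide_bayes_factor(1.0, r, 1, 3)$action, "continue")
  expect_equal(decide_bayes_factor(1.0, r, 3, 3)$action, "final_nonsignificant")

  rf <- rule_bayes_factor(bf_success = 2, bf_futility = 0.5)
  expect_equal(decide_bayes_factor(0.4, rf, 1, 2)$action, "stop_futility")
  expect_equal(decide_bayes_factor(1.0, rf, 1, 2)$action, "continue")
  expect_equal(decide_bayes_factor(0.4, rf, 2, 2)$action, "final_nonsignificant")
})

test_that("credible-interval decisions mirror the implied t-test levels", {
  small <- rule_credible_interval(c(0.998, 0.968, 0.968))
  # p = 0.001 < 1 - 0.998 -> the 99.8% interval excludes zero
  expect_equal(decide_credible_interval(stats_with_p(0.001), small, 1, 3)$action,
               "stop_efficacy")
  # p = 0.01 < 1 - 0.968 = 0.032 at stage 2
  expect_equal(decide_credible_interval(stats_with_p(0.01), small, 2, 3)$action,
               "stop_efficacy")
  # p = 0.049: the 95% interval would exclude zero but the 96.8% does not
  expect_equal(decide_credible_interval(stats_with_p(0.049), small, 3, 3)$action,
               "final_nonsignificant")

  larger <- rule_credible_interval(c(0.99, 0.95), futility_level = 0.5)
  expect_equal(decide_credible_interval(stats_with_p(0.6, 18), larger, 1, 2)$action,
               "stop_futility")
  expect_equal(decide_credible_interval(stats_with_p(0.2, 18), larger, 1, 2)$action,
               "continue")
})

test_that("design configs round-trip through JSON and YAML", {
  designs <- list(
    design_small("freq_seq"), design_larger("bayes_factor"),
    design_larger("credible_interval"), design_small("fixed")
  )
  for (d in designs) {
    for (ext in c(".json", ".yaml")) {
      path <- tempfile(fileext = ext)
      write_design_config(d, path)
      back <- read_design_config(path)
      # YAML serializes numerics at ~9 significant digits
      expect_equal(design_to_list(back), design_to_list(d), tolerance = 1e-7)
    }
  }
  expect_error(read_design_config(tempfile(fileext = ".csv")),
               class = "preclinseq_config_error")
  expect_error(design_from_list(list(rule = list())),
               class = "preclinseq_config_error")
})
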