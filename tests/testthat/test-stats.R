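test_that("pooled t statistics match the reference implementation", {
  for (seed in 1:20) {
    g <- random_groups(seed)
    st <- two_sample_t(g$a, g$b)
    ref <- stats::t.test(g$b, g$a, var.equal = TRUE)
    expect_equal(st$t_value, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(st$p_two_sided, ref$p.value, tolerance = 1e-12)
    expect_equal(st$df, unname(ref$parameter))
    expect_equal(st$d_hat, st$t_value * sqrt(1 / st$n_a + 1 / st$n_b),
                 tolerance = 1e-12)
  }
})

test_that("identical groups give t = 0, p = 1; label swap negates t and d_hat", {
  st <- two_sample_t(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(st$t_value, 0)
  expect_equal(st$p_two_sided, 1)
  expect_equal(st$d_hat, 0)

  g <- random_groups(7)
  ab <- two_sample_t(g$a, g$b)
  ba <- two_sample_t(g$b, g$a)
  expect_equal(ba$t_value, -ab$t_value, tolerance = 1e-12)
  expect_equal(ba$d_hat, -ab$d_hat, tolerance = 1e-12)
  expect_equal(ba$p_two_sided, ab$p_two_sided, tolerance = 1e-12)

  expect_error(two_sample_t(c(1, 1, 1), c(1, 1, 1)),
               class = "preclinseq_degenerate_error")
  expect_error(two_sample_t(1, c(1, 2)), class = "preclinseq_domain_error")
})

test_that("the default Bayes factor favours the null at t = 0 and grows with |t|", {
  for (n in c(4, 9, 18)) {
    expect_lt(jzs_bayes_factor(0, n, n), 1)
  }
  tt <- seq(0, 6, by = 0.5)
  bf <- jzs_bayes_factor(tt, 9, 9)
  expect_true(all(diff(bf) > 0))
  expect_equal(jzs_bayes_factor(-2.5, 9, 9), jzs_bayes_factor(2.5, 9, 9),
               tolerance = 1e-8)
})

test_that("Bayes factor quadrature matches a dense Riemann-sum oracle", {
  set.seed(5)
  cases <- data.frame(
    t = runif(20, -6, 6),
    n_a = sample(3:20, 20, replace = TRUE),
    n_b = sample(3:20, 20, replace = TRUE)
  )
  for (i in seq_len(nrow(cases))) {
    got <- jzs_bayes_factor(cases$t[i], cases$n_a[i], cases$n_b[i])
    want <- bf_riemann_oracle(cases$t[i], cases$n_a[i], cases$n_b[i])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("the critical |t| inverts the Bayes factor threshold", {
  for (thr in c(0.5, 2, 3)) {
    for (n in c(6, 18)) {
      ct <- preclinseq:::bf_critical_t(thr, n, n)
      expect_equal(jzs_bayes_factor(ct, n, n), thr, tolerance = 1e-6)
    }
  }
})

test_that("credible intervals are the scaled t intervals of the Jeffreys posterior", {
  # decision equivalence: 0 outside the level-L interval <=> p < 1 - L
  for (seed in 1:15) {
    g <- random_groups(seed + 100)
    st <- two_sample_t(g$a, g$b)
    for (lv in c(0.5, 0.95, 0.968, 0.998)) {
      ci <- credible_interval(st, lv)
      excl <- ci[["lower"]] > 0 || ci[["upper"]] < 0
      expect_identical(excl, st$p_two_sided < 1 - lv)
    }
  }

  # identical groups: symmetric about 0 and containing 0
  st0 <- two_sample_t(c(0, 0, 1, 1), c(0, 0, 1, 1))
  ci0 <- credible_interval(st0, 0.95)
  expect_equal(ci0[["lower"]], -ci0[["upper"]], tolerance = 1e-12)
  expect_true(ci0[["lower"]] < 0 && ci0[["upper"]] > 0)

  expect_error(credible_interval(st0, 1.2), class = "preclinseq_domain_error")
})

test_that("credible intervals match a posterior-sampling oracle", {
  for (seed in c(3, 8, 13)) {
    g <- random_groups(seed + 200, n_a = 8, n_b = 8)
    st <- two_sample_t(g$a, g$b)
    for (lv in c(0.5, 0.95)) {
      ci <- credible_interval(st, lv)
      orc <- cri_sampling_oracle(g$a, g$b, lv, n_draws = 2e5)
      expect_equal(unname(ci), orc, tolerance = 0.02)
    }
  }
})
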