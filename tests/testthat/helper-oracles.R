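# Independent brute-force oracles used to freeze expected values.

# Monte Carlo first-crossing oracle for a two-sided group sequential
# boundary: simulates the score process directly from independent normal
# increments (no recursion involved).
mc_crossing_oracle <- function(z_bounds, tfrac, drift = 0, n_draws = 1e6,
                               seed = 123) {
  set.seed(seed)
  K <- length(z_bounds)
  b <- z_bounds * sqrt(tfrac)
  s <- numeric(n_draws)
  stopped <- rep(0L, n_draws)
  prev_t <- 0
  for (k in seq_len(K)) {
    dt_k <- tfrac[k] - prev_t
    s <- s + rnorm(n_draws, mean = drift * dt_k, sd = sqrt(dt_k))
    cross <- stopped == 0L & abs(s) >= b[k]
    stopped[cross] <- k
    prev_t <- tfrac[k]
  }
  prop <- vapply(seq_len(K), function(k) mean(stopped == k), numeric(1))
  se <- sqrt(prop * (1 - prop) / n_draws)
  list(prop = prop, se = se)
}

# dense Riemann-sum oracle for the JZS Bayes factor
bf_riemann_oracle <- function(t_value, n_a, n_b, prior_scale = sqrt(2) / 2,
                              lim = 50, step = 5e-4) {
  df <- n_a + n_b - 2
  n_eff <- n_a * n_b / (n_a + n_b)
  d <- seq(-lim, lim, by = step)
  num <- sum(suppressWarnings(
    dt(t_value, df, ncp = d * sqrt(n_eff))
  ) * dcauchy(d, 0, prior_scale)) * step
  num / dt(t_value, df)
}

# posterior-sampling oracle for the Jeffreys-prior credible interval on the
# d scale: draws from the normal-inverse-chi-square posterior of the two
# group means and common variance
cri_sampling_oracle <- function(a, b, level, n_draws = 2e5, seed = 99) {
  set.seed(seed)
  n_a <- length(a)
  n_b <- length(b)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * var(a) + (n_b - 1) * var(b)) / df
  md <- mean(b) - mean(a)
  sigma2 <- df * sp2 / rchisq(n_draws, df)
  mu_diff <- rnorm(n_draws, md, sqrt(sigma2 * (1 / n_a + 1 / n_b)))
  unname(quantile(mu_diff, c((1 - level) / 2, (1 + level) / 2)) / sqrt(sp2))
}

# small random two-group datasets for parameterised cases
random_groups <- function(seed, n_a = sample(3:12, 1), n_b = sample(3:12, 1)) {
  set.seed(seed)
  list(a = rnorm(n_a, 0, exp(runif(1, -0.5, 0.5))),
       b = rnorm(n_b, runif(1, -1.5, 1.5), exp(runif(1, -0.5, 0.5))))
}
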