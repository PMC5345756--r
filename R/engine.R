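# Vectorized Monte Carlo engine.
#
# Trials are generated one by one from per-trial seeds (so each simulated
# experiment can be reproduced in isolation with run_trial()), but all
# stage statistics and stop/continue decisions are evaluated vectorized
# across trials.  For the Bayes factor rule the per-stage decision
# BF10 >= threshold is applied through the equivalent critical |t| value
# (BF10 is strictly increasing in |t| at fixed sample sizes), so no
# quadrature is needed inside the simulation loop.

# stage statistics for a block of trials: returns matrices (n_trials x K)
# of t values, p values and d_hat, generated from per-trial seeds
sim_stats_stream <- function(schedule, true_d, trial_seeds, sd = 1) {
  cum_n <- schedule$cumulative_n_per_group
  K <- schedule$n_stages
  N <- cum_n[K]
  n_tr <- length(trial_seeds)

  A <- matrix(0, n_tr, N)
  B <- matrix(0, n_tr, N)
  for (i in seq_len(n_tr)) {
    dat <- r_stage_batches(schedule, true_d, sd, trial_seeds[i])
    A[i, ] <- dat$a
    B[i, ] <- dat$b
  }

  Tm <- matrix(0, n_tr, K)
  Pm <- matrix(0, n_tr, K)
  Dm <- matrix(0, n_tr, K)
  sA <- sA2 <- sB <- sB2 <- numeric(n_tr)
  prev <- 0L
  for (k in seq_len(K)) {
    idx <- (prev + 1L):cum_n[k]
    Ak <- A[, idx, drop = FALSE]
    Bk <- B[, idx, drop = FALSE]
    sA <- sA + rowSums(Ak)
    sA2 <- sA2 + rowSums(Ak^2)
    sB <- sB + rowSums(Bk)
    sB2 <- sB2 + rowSums(Bk^2)
    prev <- cum_n[k]

    n <- cum_n[k]
    df <- 2L * n - 2L
    va <- (sA2 - sA^2 / n) / (n - 1)
    vb <- (sB2 - sB^2 / n) / (n - 1)
    sp <- sqrt((va + vb) / 2) # equal group sizes by construction
    md <- sB / n - sA / n
    tv <- md / (sp * sqrt(2 / n))
    Tm[, k] <- tv
    Pm[, k] <- 2 * pt(abs(tv), df, lower.tail = FALSE)
    Dm[, k] <- md / sp
  }
  list(t = Tm, p = Pm, d_hat = Dm, cum_n = cum_n, K = K)
}

# per-stage efficacy/futility thresholds on the p (or |t|) scale.
# NA means "no test of that kind at that stage".  Futility entries are
# interim-only by construction.
rule_thresholds <- function(rule, schedule) {
  K <- schedule$n_stages
  cum_n <- schedule$cumulative_n_per_group
  eff_p <- rep(NA_real_, K)
  fut_p <- rep(NA_real_, K)
  eff_t <- rep(NA_real_, K)
  fut_t <- rep(NA_real_, K)
  scale <- "p"
  switch(rule$kind,
    fixed = {
      eff_p[K] <- rule$alpha
    },
    freq_seq = {
      eff_p <- rule$stage_alphas
      if (!is.null(rule$futility_alpha) && K > 1L) {
        fut_p[seq_len(K - 1L)] <- rule$futility_alpha
      }
    },
    credible_interval = {
      eff_p <- 1 - rule$levels
      if (!is.null(rule$futility_level) && K > 1L) {
        fut_p[seq_len(K - 1L)] <- 1 - rule$futility_level
      }
    },
    bayes_factor = {
      scale <- "t"
      for (k in seq_len(K)) {
        eff_t[k] <- bf_critical_t(rule$bf_success, cum_n[k], cum_n[k],
                                  rule$prior_scale)
        if (!is.null(rule$bf_futility) && k < K) {
          fut_t[k] <- bf_critical_t(rule$bf_futility, cum_n[k], cum_n[k],
                                    rule$prior_scale)
        }
      }
    }
  )
  list(scale = scale, eff_p = eff_p, fut_p = fut_p, eff_t = eff_t, fut_t = fut_t)
}

# first-crossing decisions for a whole stream; returns per-trial records
decide_stream <- function(stream, thr) {
  K <- stream$K
  n_tr <- nrow(stream$p)
  stop_stage <- rep(K, n_tr)
  decision <- rep("nonsignificant", n_tr)
  active <- rep(TRUE, n_tr)
  for (k in seq_len(K)) {
    if (thr$scale == "p") {
      eff <- if (is.na(thr$eff_p[k])) rep(FALSE, n_tr) else stream$p[, k] < thr$eff_p[k]
      fut <- if (is.na(thr$fut_p[k])) rep(FALSE, n_tr) else stream$p[, k] > thr$fut_p[k]
    } else {
      abst <- abs(stream$t[, k])
      eff <- if (is.na(thr$eff_t[k])) rep(FALSE, n_tr) else abst >= thr$eff_t[k]
      fut <- if (is.na(thr$fut_t[k])) rep(FALSE, n_tr) else abst <= thr$fut_t[k]
    }
    sig_k <- active & eff
    fut_k <- active & !eff & fut
    decision[sig_k] <- "significant"
    decision[fut_k] <- "futile"
    stop_stage[sig_k | fut_k] <- k
    active <- active & !sig_k & !fut_k
  }
  idx <- cbind(seq_len(n_tr), stop_stage)
  tibble::tibble(
    decision = decision,
    stop_stage = stop_stage,
    animals_used = 2L * stream$cum_n[stop_stage],
    d_est = stream$d_hat[idx],
    t_value = stream$t[idx],
    p_two_sided = stream$p[idx]
  )
}

sim_engine <- function(design, true_d, trial_seeds, sd = 1) {
  stream <- sim_stats_stream(design$schedule, true_d, trial_seeds, sd)
  thr <- rule_thresholds(design$rule, design$schedule)
  decide_stream(stream, thr) |>
    dplyr::mutate(
      label = design$label,
      true_d = true_d,
      seed = as.integer(trial_seeds),
      .before = 1
    )
}

#' Simulate many independent trials under a design
#'
#' Runs `n_reps` independent staged experiments.  Per-trial seeds are
#' derived from the master `seed` (see [derive_seeds()]), so any single
#' trial record can be reproduced with
#' `run_trial(design, true_d, seed = <its seed>)`.
#'
#' @param design A [gs_design()].
#' @param true_d True standardized effect size.
#' @param n_reps Number of simulated trials.
#' @param seed Master integer seed.
#' @param sd Common outcome SD.
#' @return Tibble with one row per trial; columns as in [run_trial()].
#' @examples
#' simulate_trials(design_small("freq_seq"), true_d = 1, n_reps = 100, seed = 1)
#' @export
simulate_trials <- function(design, true_d, n_reps = 10000, seed = 1, sd = 1) {
  stopifnot(inherits(design, "gs_design"), n_reps >= 1)
  sim_engine(design, true_d, derive_seeds(seed, n_reps), sd)
}
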