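# Simulation-based calibration of one free rule threshold to a target
# type I error, using common random numbers: the same simulated null trial
# stream is reused for every candidate threshold, which makes the achieved
# rate a monotone step function of the threshold and turns the noisy root
# search into a clean bisection.

# interpolated BF10 as a function of |t| for one stage (decisions in the
# calibration search need BF values for the whole stream; a monotone
# spline on a |t| grid reproduces the quadrature to ~1e-6 relative error)
bf_interpolator <- function(n_a, n_b, prior_scale, t_max) {
  grid <- seq(0, max(t_max, 1) + 0.5, length.out = 400L)
  splinefun(grid, log(jzs_bayes_factor(grid, n_a, n_b, prior_scale)),
            method = "hyman")
}

# apply a candidate threshold value to the rule
update_free_param <- function(rule, theta, free_stages, K) {
  switch(rule$kind,
    fixed = rule_fixed(theta),
    freq_seq = rule_freq_seq(pmin(rule$stage_alphas * theta, 1 - 1e-12),
                             rule$futility_alpha),
    bayes_factor = rule_bayes_factor(theta, rule$bf_futility, rule$prior_scale),
    credible_interval = {
      lv <- rule$levels
      lv[free_stages] <- theta
      rule_credible_interval(lv, rule$futility_level)
    }
  )
}

#' Calibrate a stopping rule to a target type I error
#'
#' Tunes one free threshold parameter of a design's stopping rule so that
#' the simulated type I error (true d = 0) matches `target_alpha`.  The
#' free parameter depends on the rule kind:
#'
#' * `fixed`: the significance level itself;
#' * `freq_seq`: a common multiplier on the stage alphas (the boundary
#'   shape, i.e. the ratios between stage levels, is held fixed);
#' * `bayes_factor`: the efficacy threshold `bf_success`;
#' * `credible_interval`: a shared credibility level for `free_stages`
#'   (default: all stages after the first, mirroring designs that fix a
#'   stringent first-stage level and tune the later ones).
#'
#' A single stream of `n_reps` null trials is simulated once and reused
#' across all candidate thresholds (common random numbers), so the
#' achieved rate is a monotone step function of the parameter; bisection
#' stops when the achieved rate is within `tolerance` of the target or the
#' bracketing interval collapses.
#'
#' @param design A [gs_design()].
#' @param target_alpha Target overall type I error (default 0.05).
#' @param tolerance Acceptable |achieved - target| (default 0.0025; keep it
#'   above the Monte Carlo SE `sqrt(alpha (1 - alpha) / n_reps)`).
#' @param n_reps Null trials in the calibration stream.
#' @param seed Master seed for the stream.
#' @param interval Search interval for the free parameter; a rule-specific
#'   default is used when `NULL`.
#' @param free_stages For `credible_interval` rules: stages whose level is
#'   tuned.
#' @param sd Common outcome SD of the simulated null data.
#' @return A `gs_calibration` object with the calibrated `design`, the
#'   tuned parameter `theta`, `achieved` type I error, its `mc_se`, the
#'   bisection `trace` (via `tidy()`) and a `converged` flag.
#' @examples
#' calibrate_design(design_small("fixed"), n_reps = 2000, seed = 1)
#' @export
calibrate_design <- function(design, target_alpha = 0.05, tolerance = 0.0025,
                             n_reps = 1e5, seed = 1, interval = NULL,
                             free_stages = NULL, sd = 1) {
  stopifnot(inherits(design, "gs_design"))
  rule <- design$rule
  K <- design$schedule$n_stages
  if (is.null(free_stages)) {
    free_stages <- if (K > 1L) 2:K else 1L
  }
  if (is.null(interval)) {
    interval <- switch(rule$kind,
      fixed = c(1e-4, 0.4),
      freq_seq = c(0.01, 20),
      bayes_factor = c(1.01, 50),
      credible_interval = c(0.5, 1 - 1e-5)
    )
  }

  stream <- sim_stats_stream(design$schedule, 0, derive_seeds(seed, n_reps), sd)
  cum_n <- design$schedule$cumulative_n_per_group

  # decisions over the fixed stream for a candidate theta
  if (rule$kind == "bayes_factor") {
    # precompute the BF matrix once; thresholding it is then instant
    logbf <- matrix(0, n_reps, K)
    for (k in seq_len(K)) {
      f <- bf_interpolator(cum_n[k], cum_n[k], rule$prior_scale,
                           max(abs(stream$t[, k])))
      logbf[, k] <- f(abs(stream$t[, k]))
    }
    rate <- function(theta) {
      active <- rep(TRUE, n_reps)
      hit <- rep(FALSE, n_reps)
      for (k in seq_len(K)) {
        eff <- logbf[, k] >= log(theta)
        fut <- if (!is.null(rule$bf_futility) && k < K) {
          logbf[, k] <= log(rule$bf_futility)
        } else rep(FALSE, n_reps)
        hit <- hit | (active & eff)
        active <- active & !eff & !fut
      }
      mean(hit)
    }
  } else {
    rate <- function(theta) {
      cand <- update_free_param(rule, theta, free_stages, K)
      thr <- rule_thresholds(cand, design$schedule)
      mean(decide_stream(stream, thr)$decision == "significant")
    }
  }

  lo <- interval[1]
  hi <- interval[2]
  r_lo <- rate(lo)
  r_hi <- rate(hi)
  if ((r_lo - target_alpha) * (r_hi - target_alpha) > 0) {
    abort_calibration(
      "The search interval does not bracket the target type I error.",
      data = list(interval = interval, rate_lo = r_lo, rate_hi = r_hi,
                  target = target_alpha)
    )
  }
  increasing <- r_hi > r_lo

  trace <- list(
    tibble::tibble(iteration = 0L, theta = lo, achieved = r_lo),
    tibble::tibble(iteration = 0L, theta = hi, achieved = r_hi)
  )
  theta <- (lo + hi) / 2
  achieved <- rate(theta)
  iter <- 0L
  while (abs(achieved - target_alpha) > tolerance &&
         (hi - lo) > 1e-8 * max(1, abs(hi)) && iter < 60L) {
    iter <- iter + 1L
    trace[[length(trace) + 1L]] <-
      tibble::tibble(iteration = iter, theta = theta, achieved = achieved)
    go_up <- xor(achieved > target_alpha, increasing)
    if (go_up) lo <- theta else hi <- theta
    theta <- (lo + hi) / 2
    achieved <- rate(theta)
  }
  trace[[length(trace) + 1L]] <-
    tibble::tibble(iteration = iter + 1L, theta = theta, achieved = achieved)

  calibrated <- gs_design(design$schedule,
                          update_free_param(rule, theta, free_stages, K),
                          paste0(design$label, "_calibrated"))
  structure(
    list(
      design = calibrated,
      theta = theta,
      achieved = achieved,
      mc_se = sqrt(achieved * (1 - achieved) / n_reps),
      target_alpha = target_alpha,
      tolerance = tolerance,
      n_reps = n_reps,
      converged = abs(achieved - target_alpha) <= tolerance,
      trace = dplyr::bind_rows(trace)
    ),
    class = "gs_calibration"
  )
}

#' @export
print.gs_calibration <- function(x, ...) {
  cat("<gs_calibration> ", x$design$label, "\n", sep = "")
  cat("  free parameter: ", signif(x$theta, 5),
      "; achieved type I error: ", signif(x$achieved, 4),
      " (MC SE ", signif(x$mc_se, 2), ", target ", x$target_alpha, ")\n",
      sep = "")
  cat("  converged: ", x$converged, " in ", max(x$trace$iteration),
      " bisection steps, ", x$n_reps, " null trials\n", sep = "")
  invisible(x)
}

#' @method tidy gs_calibration
#' @export
tidy.gs_calibration <- function(x, ...) x$trace

#' @method glance gs_calibration
#' @export
glance.gs_calibration <- function(x, ...) {
  tibble::tibble(
    label = x$design$label,
    theta = x$theta,
    achieved = x$achieved,
    mc_se = x$mc_se,
    target_alpha = x$target_alpha,
    tolerance = x$tolerance,
    n_reps = x$n_reps,
    converged = x$converged
  )
}
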