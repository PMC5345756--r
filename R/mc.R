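# Monte Carlo operating characteristics and analytic cross-checks.

#' Operating characteristics from simulated trial records
#'
#' Aggregates a tibble of trial records (from [simulate_trials()]) into the
#' design's operating characteristics: cumulative percentage of significant
#' trials by stage, per-stage futility percentages, overall significance
#' rate (power when the true d is nonzero, type I error when it is 0),
#' mean animal consumption ("cost"), and the median estimated effect size
#' among significant trials (the winner's-curse summary).
#'
#' @param trials Tibble of trial records.
#' @param design The [gs_design()] that produced them.
#' @return A `gs_oc` object; `tidy()` gives the per-stage table, `glance()`
#'   the one-row summary.
#' @examples
#' simulate_trials(design_small("freq_seq"), 1, 500, seed = 1) |>
#'   operating_characteristics(design_small("freq_seq"))
#' @export
operating_characteristics <- function(trials, design) {
  stopifnot(inherits(design, "gs_design"))
  K <- design$schedule$n_stages
  cum_n <- design$schedule$cumulative_n_per_group
  n <- nrow(trials)
  sig <- trials$decision == "significant"
  fut <- trials$decision == "futile"

  stages <- tibble::tibble(
    stage = seq_len(K),
    n_per_group = cum_n,
    cum_significant_pct = vapply(
      seq_len(K), function(k) 100 * mean(sig & trials$stop_stage <= k), numeric(1)
    ),
    futility_pct = vapply(
      seq_len(K), function(k) 100 * mean(fut & trials$stop_stage == k), numeric(1)
    ),
    stop_pct = vapply(
      seq_len(K), function(k) 100 * mean(trials$stop_stage == k), numeric(1)
    )
  )

  p_hat <- mean(sig)
  summary <- tibble::tibble(
    label = design$label,
    true_d = if (length(unique(trials$true_d)) == 1L) trials$true_d[1] else NA_real_,
    n_reps = n,
    overall_significant_pct = 100 * p_hat,
    mean_cost = mean(trials$animals_used),
    median_d_est_significant = if (any(sig)) median(trials$d_est[sig]) else NA_real_,
    mc_se_pct = 100 * sqrt(p_hat * (1 - p_hat) / n)
  )

  structure(list(stages = stages, summary = summary, design = design),
            class = "gs_oc")
}

#' Estimate a design's operating characteristics by simulation
#'
#' Convenience wrapper: simulates `n_reps` trials and aggregates them with
#' [operating_characteristics()].
#'
#' @inheritParams simulate_trials
#' @return A `gs_oc` object.
#' @examples
#' estimate_operating_characteristics(design_small("freq_seq"), 1,
#'                                    n_reps = 500, seed = 1)
#' @export
estimate_operating_characteristics <- function(design, true_d,
                                               n_reps = 10000, seed = 1,
                                               sd = 1) {
  simulate_trials(design, true_d, n_reps, seed, sd) |>
    operating_characteristics(design)
}

#' @export
print.gs_oc <- function(x, ...) {
  s <- x$summary
  cat("<gs_oc> ", s$label, " (true d = ", s$true_d, ", ", s$n_reps, " reps)\n",
      sep = "")
  cat("  overall significant: ", round(s$overall_significant_pct, 1),
      "% (MC SE ", round(s$mc_se_pct, 2), ")\n", sep = "")
  cat("  mean cost: ", round(s$mean_cost, 1), " animals; median d_est | significant: ",
      round(s$median_d_est_significant, 2), "\n", sep = "")
  print(x$stages)
  invisible(x)
}

#' @method tidy gs_oc
#' @export
tidy.gs_oc <- function(x, ...) x$stages

#' @method glance gs_oc
#' @export
glance.gs_oc <- function(x, ...) x$summary

#' Exact power of the fixed two-group design
#'
#' Power of the two-sided pooled two-sample t test via the noncentral t
#' distribution: noncentrality `d * sqrt(n / 2)`, `2n - 2` degrees of
#' freedom.  With `true_d = 0` this returns `alpha` exactly.
#'
#' @param true_d Standardized effect size.
#' @param n_per_group Per-group sample size (>= 2).
#' @param alpha Two-sided significance level.
#' @return Rejection probability.
#' @examples
#' analytic_fixed_power(1, 18)   # ~0.83
#' analytic_fixed_power(0.5, 36) # ~0.55
#' @export
analytic_fixed_power <- function(true_d, n_per_group, alpha = 0.05) {
  stopifnot(n_per_group >= 2, is_probability(alpha))
  df <- 2 * n_per_group - 2
  q <- qt(1 - alpha / 2, df)
  if (true_d == 0) {
    return(alpha)
  }
  ncp <- true_d * sqrt(n_per_group / 2)
  pt(q, df, ncp = ncp, lower.tail = FALSE) + pt(-q, df, ncp = ncp)
}

#' Winner's-curse summary of simulated trials
#'
#' Median estimated effect size restricted to trials that ended
#' significant.  Because significance selects for overestimated effects
#' (especially in underpowered settings and with early stopping), this
#' median exceeds the true effect whenever power is well below 100%.
#'
#' @param trials Tibble of trial records from [simulate_trials()].
#' @return One-row tibble with `n_significant`, `median_d_est_significant`,
#'   `median_d_est_all`.  If no trial is significant the median is `NA`
#'   and a warning of class `preclinseq_empty_result` is raised.
#' @export
winners_curse_summary <- function(trials) {
  sig <- trials$decision == "significant"
  if (!any(sig)) {
    warn("No significant trials: the winner's-curse median is undefined.",
         class = "preclinseq_empty_result")
  }
  tibble::tibble(
    n_significant = sum(sig),
    median_d_est_significant = if (any(sig)) median(trials$d_est[sig]) else NA_real_,
    median_d_est_all = median(trials$d_est)
  )
}
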