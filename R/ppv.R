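# Predictive value of significant findings under effect-size priors.

#' Positive predictive value of a design under an effect-size prior
#'
#' Emulates a research field in which the true standardized effect behind
#' each experiment is drawn from a discrete prior scenario.  For each of
#' `n_reps` simulated experiments a true d is drawn from `scenario`, the
#' staged trial is run under `design`, and the pair (true d, decision) is
#' recorded.  Estimates:
#'
#' * `p_significant`: probability of a significant result;
#' * `ppv_any`: P(true d > 0 | significant);
#' * `ppv_ge_half`: P(true d >= 0.5 | significant);
#' * `p_detect_any`, `p_detect_ge_half`: the products
#'   `p_significant * ppv_*`, the overall probability that an experiment
#'   yields a significant result that reflects a true effect.
#'
#' Classification uses the true drawn d, not the estimate.  A semi-analytic
#' composition is also returned: per-d Monte Carlo power estimates combined
#' with the scenario weights, `p = sum_d w_d * power(d)` (and the
#' corresponding mixture PPVs), which should agree with the direct
#' estimates up to Monte Carlo error.
#'
#' @param design A [gs_design()].
#' @param scenario An [effect_size_scenario()].
#' @param n_reps Number of simulated experiments.
#' @param seed Master seed.
#' @param sd Common outcome SD.
#' @return A `gs_ppv` object; `glance()` gives the one-row summary,
#'   `tidy()` the per-d power table.  If no trial is significant the PPVs
#'   are `NA` and a warning of class `preclinseq_empty_result` is raised.
#' @examples
#' ppv_analysis(design_small("freq_seq"), effect_size_scenario("pessimistic"),
#'              n_reps = 500, seed = 1)
#' @export
ppv_analysis <- function(design, scenario, n_reps = 10000, seed = 1, sd = 1) {
  stopifnot(inherits(design, "gs_design"), inherits(scenario, "gs_scenario"))
  set.seed(as.integer(seed))
  trial_seeds <- sample.int(2147483646L, n_reps)
  d_draws <- scenario$d[
    sample.int(nrow(scenario), n_reps, replace = TRUE, prob = scenario$weight)
  ]

  trials <- purrr::map(unique(d_draws), function(dd) {
    idx <- which(d_draws == dd)
    sim_engine(design, dd, trial_seeds[idx], sd) |>
      dplyr::mutate(trial = idx)
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$trial)

  sig <- trials$decision == "significant"
  n_sig <- sum(sig)
  if (n_sig == 0L) {
    warn("No significant trials: positive predictive values are undefined.",
         class = "preclinseq_empty_result")
  }
  p_sig <- mean(sig)
  ppv_any <- if (n_sig > 0) mean(trials$true_d[sig] > 0) else NA_real_
  ppv_half <- if (n_sig > 0) mean(trials$true_d[sig] >= 0.5) else NA_real_

  per_d <- trials |>
    dplyr::group_by(d = .data$true_d) |>
    dplyr::summarise(
      n = dplyr::n(),
      power_hat = mean(.data$decision == "significant"),
      mean_cost = mean(.data$animals_used),
      .groups = "drop"
    ) |>
    dplyr::left_join(tibble::as_tibble(scenario), by = "d") |>
    dplyr::arrange(.data$d)

  # semi-analytic mixture composition from per-d power estimates
  p_sig_mix <- sum(per_d$weight * per_d$power_hat)
  ppv_any_mix <- sum(per_d$weight * per_d$power_hat * (per_d$d > 0)) / p_sig_mix
  ppv_half_mix <- sum(per_d$weight * per_d$power_hat * (per_d$d >= 0.5)) / p_sig_mix

  summary <- tibble::tibble(
    label = design$label,
    scenario = attr(scenario, "label"),
    n_reps = n_reps,
    p_significant = p_sig,
    ppv_any = ppv_any,
    ppv_ge_half = ppv_half,
    p_detect_any = p_sig * ppv_any,
    p_detect_ge_half = p_sig * ppv_half,
    p_significant_mixture = p_sig_mix,
    ppv_any_mixture = ppv_any_mix,
    ppv_ge_half_mixture = ppv_half_mix,
    mean_cost = mean(trials$animals_used)
  )

  structure(list(summary = summary, per_d = per_d, trials = trials),
            class = "gs_ppv")
}

#' @export
print.gs_ppv <- function(x, ...) {
  s <- x$summary
  cat("<gs_ppv> ", s$label, " under '", s$scenario, "' scenario (",
      s$n_reps, " reps)\n", sep = "")
  cat("  P(significant) = ", round(s$p_significant, 3),
      "; PPV(d > 0) = ", round(s$ppv_any, 3),
      "; PPV(d >= 0.5) = ", round(s$ppv_ge_half, 3), "\n", sep = "")
  cat("  P(detect true effect): any = ", round(s$p_detect_any, 3),
      ", d >= 0.5 = ", round(s$p_detect_ge_half, 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy gs_ppv
#' @export
tidy.gs_ppv <- function(x, ...) x$per_d

#' @method glance gs_ppv
#' @export
glance.gs_ppv <- function(x, ...) x$summary
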