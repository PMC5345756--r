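# Run a single staged experiment under a design.

decision_label <- function(action) {
  switch(action,
    stop_efficacy = "significant",
    stop_futility = "futile",
    final_nonsignificant = "nonsignificant"
  )
}

#' Run one staged experiment on supplied data
#'
#' Applies a design's stopping rule stage by stage to pre-generated
#' per-group outcome vectors (useful for testing decision logic with
#' injected data).  The first `n_k` values of each vector are the
#' cumulative data at stage k.
#'
#' @param design A [gs_design()].
#' @param a,b Control and treated outcome vectors, each at least as long as
#'   the final per-group sample size.
#' @return One-row tibble; see [run_trial()].
#' @export
run_trial_data <- function(design, a, b) {
  stopifnot(inherits(design, "gs_design"))
  cum_n <- design$schedule$cumulative_n_per_group
  K <- design$schedule$n_stages
  if (length(a) < max(cum_n) || length(b) < max(cum_n)) {
    abort_domain("`a` and `b` must cover the final per-group sample size.")
  }
  for (k in seq_len(K)) {
    n_k <- cum_n[k]
    stats <- two_sample_t(a[seq_len(n_k)], b[seq_len(n_k)])
    dec <- apply_rule(design$rule, stats, k, K)
    if (dec$action != "continue") {
      return(tibble::tibble(
        label = design$label,
        decision = decision_label(dec$action),
        stop_stage = k,
        animals_used = 2L * n_k,
        d_est = stats$d_hat,
        t_value = stats$t_value,
        p_two_sided = stats$p_two_sided
      ))
    }
  }
  # unreachable: the final stage never returns "continue"
  abort_numerical("Internal error: no terminal decision at the final stage.")
}

#' Simulate one trial under a design
#'
#' Generates one staged experiment's data (see [generate_trial_data()]) and
#' applies the design's stopping rule at each preplanned analysis,
#' stopping at the first efficacy or futility decision.  The effect-size
#' estimate `d_est` is the Cohen's d of the analysis at the stopping stage
#' (not re-estimated on any later data), which is what makes early stopping
#' inflate effect estimates among significant trials.
#'
#' @param design A [gs_design()].
#' @param true_d True standardized effect size.
#' @param sd Common outcome SD.
#' @param seed Integer seed; the trial is fully reproducible from it.
#' @return One-row tibble with columns `label`, `true_d`, `decision`
#'   (`"significant"`, `"futile"`, `"nonsignificant"`), `stop_stage`,
#'   `animals_used` (both groups combined), `d_est`, `t_value`,
#'   `p_two_sided`, `seed`.
#' @examples
#' run_trial(design_small("freq_seq"), true_d = 1, seed = 42)
#' @export
run_trial <- function(design, true_d, sd = 1, seed = NULL) {
  stopifnot(inherits(design, "gs_design"))
  dat <- r_stage_batches(design$schedule, true_d, sd, seed)
  run_trial_data(design, dat$a, dat$b) |>
    dplyr::mutate(
      true_d = true_d,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      .after = "label"
    )
}
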