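# Synthetic staged two-group data and effect-size prior scenarios.
#
# The outcome model throughout is normal with common unit SD: control
# outcomes ~ N(0, sd), treated outcomes ~ N(true_d * sd, sd), so the
# standardized mean difference is Cohen's d = true_d.  Data accrue in
# per-stage batches given by the stage schedule, and stage k + 1 always
# extends (never modifies) the stage k data.

# draw the full per-group outcome vectors for one trial, batch by batch in
# stage order (control batch first, then treated batch, per stage)
r_stage_batches <- function(schedule, true_d, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cum_n <- schedule$cumulative_n_per_group
  batch <- diff(c(0L, cum_n))
  a <- numeric(0)
  b <- numeric(0)
  for (k in seq_along(batch)) {
    a <- c(a, rnorm(batch[k], mean = 0, sd = sd))
    b <- c(b, rnorm(batch[k], mean = true_d * sd, sd = sd))
  }
  list(a = a, b = b)
}

#' Generate staged two-group outcome data
#'
#' Simulates one staged experiment's raw data: per-stage batches of normal
#' outcomes with unit (or specified) SD and standardized mean difference
#' `true_d` between the treated and control group.  Generation is
#' deterministic given `seed` and stage-incremental: the data of the first
#' k stages do not depend on how many later stages the schedule has.
#'
#' @param schedule A [stage_schedule()].
#' @param true_d True standardized effect size (Cohen's d).
#' @param sd Common outcome standard deviation (> 0).
#' @param seed Optional integer seed.
#' @return Tibble with columns `stage`, `group` (`"a"` control /
#'   `"b"` treated), `unit` (cumulative index within group) and `value`.
#' @examples
#' generate_trial_data(stage_schedule(c(6, 12, 18)), true_d = 1, seed = 1)
#' @export
generate_trial_data <- function(schedule, true_d, sd = 1, seed = NULL) {
  schedule <- as_schedule(schedule)
  if (!is.numeric(true_d) || length(true_d) != 1L || !is.finite(true_d)) {
    abort_domain("`true_d` must be a single finite number.")
  }
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    abort_domain("`sd` must be a single positive number.")
  }
  dat <- r_stage_batches(schedule, true_d, sd, seed)
  cum_n <- schedule$cumulative_n_per_group
  stage_of <- rep(seq_len(schedule$n_stages), diff(c(0L, cum_n)))
  tibble::tibble(
    stage = rep(stage_of, 2L),
    group = rep(c("a", "b"), each = cum_n[length(cum_n)]),
    unit = rep(seq_len(cum_n[length(cum_n)]), 2L),
    value = c(dat$a, dat$b)
  ) |>
    dplyr::arrange(.data$stage, .data$group, .data$unit)
}

#' Discrete prior scenarios for the true effect size
#'
#' A scenario is a discrete distribution over candidate true standardized
#' effect sizes, used to emulate a research field in which the true effect
#' behind each experiment is unknown.  Two illustrative presets are
#' provided: `"optimistic"` (mass 0.3, 0.3, 0.4 on d = 0, 0.5, 1) puts most
#' weight on real effects, `"pessimistic"` (mass 0.8, 0.15, 0.05) on null
#' effects.  The presets are conventional placeholders, not estimates of
#' any specific field, and can be overridden via `support`/`weights`.
#'
#' @param label `"optimistic"`, `"pessimistic"`, or `"custom"`.
#' @param support Candidate true d values (nonnegative, distinct); required
#'   for `"custom"`.
#' @param weights Probabilities attached to `support`, summing to 1.
#' @return A `gs_scenario`: tibble with columns `d` and `weight` (sorted by
#'   `d`) and a `label` attribute.
#' @examples
#' effect_size_scenario("pessimistic")
#' effect_size_scenario("custom", support = c(0, 1), weights = c(0.8, 0.2))
#' @export
effect_size_scenario <- function(label = c("optimistic", "pessimistic", "custom"),
                                 support = NULL, weights = NULL) {
  label <- match.arg(label)
  if (label != "custom") {
    preset <- list(
      optimistic = list(support = c(0, 0.5, 1), weights = c(0.3, 0.3, 0.4)),
      pessimistic = list(support = c(0, 0.5, 1), weights = c(0.8, 0.15, 0.05))
    )[[label]]
    if (is.null(support)) support <- preset$support
    if (is.null(weights)) weights <- preset$weights
  }
  if (is.null(support) || length(support) == 0L) {
    abort_domain("Scenario `support` must be a nonempty vector of candidate d values.")
  }
  if (!is.numeric(support) || any(!is.finite(support)) || any(support < 0)) {
    abort_domain("Scenario `support` values must be finite and nonnegative.")
  }
  if (anyDuplicated(support)) {
    abort_domain("Scenario `support` values must be distinct.")
  }
  if (is.null(weights) || length(weights) != length(support) ||
      !is.numeric(weights) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    abort_domain("`weights` must be nonnegative, match `support` in length and sum to 1.")
  }
  ord <- order(support)
  out <- tibble::tibble(d = support[ord], weight = weights[ord])
  structure(out, class = c("gs_scenario", class(out)), label = label)
}

#' Sample true effect sizes from a scenario
#'
#' @param scenario A [effect_size_scenario()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` true d values.
#' @examples
#' sample_true_effect(effect_size_scenario("optimistic"), 5, seed = 1)
#' @export
sample_true_effect <- function(scenario, n = 1, seed = NULL) {
  stopifnot(inherits(scenario, "gs_scenario"))
  if (!is.null(seed)) set.seed(seed)
  scenario$d[sample.int(nrow(scenario), n, replace = TRUE, prob = scenario$weight)]
}
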