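# A design couples a stage schedule with a stopping rule.

#' Define a group sequential design
#'
#' @param schedule A [stage_schedule()] (or cumulative per-group n vector).
#' @param rule A stopping rule from [rule_fixed()], [rule_freq_seq()],
#'   [rule_bayes_factor()] or [rule_credible_interval()].  Stage-indexed
#'   rules must match the schedule's number of stages.
#' @param label Optional text label used in outputs.
#' @return An object of class `gs_design`.
#' @examples
#' gs_design(stage_schedule(c(6, 12, 18)),
#'           rule_freq_seq(c(0.0006, 0.0151, 0.0471)))
#' @export
gs_design <- function(schedule, rule, label = NULL) {
  schedule <- as_schedule(schedule)
  if (!inherits(rule, "gs_rule")) {
    abort_domain("`rule` must be a `gs_rule`.")
  }
  k_rule <- rule_n_stages(rule)
  if (!is.na(k_rule) && k_rule != schedule$n_stages) {
    abort_domain("The rule defines thresholds for a different number of stages than the schedule.")
  }
  structure(
    list(
      schedule = schedule,
      rule = rule,
      label = label %||% paste0(rule$kind, "_K", schedule$n_stages)
    ),
    class = "gs_design"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.gs_design <- function(x, ...) {
  cat("<gs_design> ", x$label, "\n", sep = "")
  print(x$schedule)
  print(x$rule)
  invisible(x)
}

#' Worked example designs for typical preclinical study sizes
#'
#' Ready-made designs for two study sizes common in preclinical two-group
#' experiments, with thresholds calibrated (by simulation) to an overall
#' type I error of about 5%:
#'
#' `design_small()` - 18 animals per group analysed in three equal stages
#' (6/12/18 per group), stopping for efficacy only:
#' * `"fixed"`: single final t test at alpha = 0.05;
#' * `"freq_seq"`: classic O'Brien-Fleming nominal levels
#'   0.0006 / 0.0151 / 0.0471 (the tabulated constants of the original
#'   O'Brien-Fleming publication);
#' * `"bayes_factor"`: BF10 >= 3 at each stage;
#' * `"credible_interval"`: 99.8% interval at stage 1, 96.8% at stages 2-3.
#'
#' `design_larger()` - 36 animals per group analysed in two equal stages
#' (18/36 per group), stopping for efficacy or (binding) futility:
#' * `"fixed"`: single final t test at alpha = 0.05;
#' * `"freq_seq"`: stage levels 0.0065 / 0.0525 with interim futility at
#'   p > 0.5 (the final level may exceed 0.05 because the binding futility
#'   stop gives back type I error);
#' * `"bayes_factor"`: BF10 >= 2 for efficacy, <= 0.5 for interim futility;
#' * `"credible_interval"`: 99% interval at stage 1, 95% at stage 2;
#'   interim futility when zero is inside the 50% interval.
#'
#' @param approach One of `"fixed"`, `"freq_seq"`, `"bayes_factor"`,
#'   `"credible_interval"`.
#' @return A [gs_design()].
#' @examples
#' design_small("freq_seq")
#' design_larger("bayes_factor")
#' @export
design_small <- function(approach = c("fixed", "freq_seq", "bayes_factor",
                                      "credible_interval")) {
  approach <- match.arg(approach)
  if (approach == "fixed") {
    return(gs_design(stage_schedule(18L), rule_fixed(0.05), "small_fixed"))
  }
  sched <- stage_schedule(c(6L, 12L, 18L))
  rule <- switch(approach,
    freq_seq = rule_freq_seq(c(0.0006, 0.0151, 0.0471)),
    bayes_factor = rule_bayes_factor(bf_success = 3),
    credible_interval = rule_credible_interval(c(0.998, 0.968, 0.968))
  )
  gs_design(sched, rule, paste0("small_", approach))
}

#' @rdname design_small
#' @export
design_larger <- function(approach = c("fixed", "freq_seq", "bayes_factor",
                                       "credible_interval")) {
  approach <- match.arg(approach)
  if (approach == "fixed") {
    return(gs_design(stage_schedule(36L), rule_fixed(0.05), "larger_fixed"))
  }
  sched <- stage_schedule(c(18L, 36L))
  rule <- switch(approach,
    freq_seq = rule_freq_seq(c(0.0065, 0.0525), futility_alpha = 0.5),
    bayes_factor = rule_bayes_factor(bf_success = 2, bf_futility = 0.5),
    credible_interval = rule_credible_interval(c(0.99, 0.95),
                                               futility_level = 0.5)
  )
  gs_design(sched, rule, paste0("larger_", approach))
}
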