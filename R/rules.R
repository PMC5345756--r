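# Stopping rules: the four per-stage decision procedures.
#
# A rule is a tagged list of kind "fixed", "freq_seq", "bayes_factor" or
# "credible_interval" holding exactly the thresholds of its kind.  Futility
# thresholds apply at interim stages only and are binding: a trial stopped
# for futility is never re-analysed.

new_rule <- function(kind, fields) {
  structure(c(list(kind = kind), fields), class = "gs_rule")
}

#' @rdname stopping_rules
#' @export
rule_fixed <- function(alpha = 0.05) {
  if (!is_probability(alpha) || length(alpha) != 1L) {
    abort_domain("`alpha` must be a single probability in (0, 1).")
  }
  new_rule("fixed", list(alpha = alpha))
}

#' Stopping rules for staged two-group experiments
#'
#' Constructors for the four analysis approaches applied at each interim or
#' final analysis of a group sequential experiment:
#'
#' * `rule_fixed()`: classical block design; a single two-sided t test at
#'   the final analysis at level `alpha`.
#' * `rule_freq_seq()`: frequentist sequential testing; stop for efficacy at
#'   stage k when the stage p value falls below `stage_alphas[k]` (e.g. the
#'   nominal levels of an O'Brien-Fleming or Pocock boundary), and, when
#'   `futility_alpha` is set, stop for futility at an interim stage when the
#'   p value exceeds it.
#' * `rule_bayes_factor()`: stop for efficacy when the default two-sample
#'   Bayes factor BF10 (see [jzs_bayes_factor()]) reaches `bf_success`;
#'   stop for futility at interim stages when it drops to `bf_futility`.
#' * `rule_credible_interval()`: stop for efficacy when the central
#'   credible interval at the stage-specific level excludes zero; stop for
#'   futility at interim stages when zero is still inside the (narrow)
#'   `futility_level` interval.
#'
#' @param alpha Final-analysis two-sided significance level.
#' @param stage_alphas Per-stage nominal significance levels (length = number
#'   of stages).
#' @param futility_alpha Optional interim futility bound on the p value.
#' @param bf_success Efficacy threshold on BF10.
#' @param bf_futility Optional interim futility threshold on BF10.
#' @param prior_scale Cauchy prior scale of the default Bayes factor.
#' @param levels Per-stage credibility levels (length = number of stages).
#' @param futility_level Optional credibility level of the interim futility
#'   interval (zero inside this interval stops the trial).
#' @return An object of class `gs_rule`.
#' @name stopping_rules
#' @examples
#' rule_freq_seq(c(0.0006, 0.0151, 0.0471))
#' rule_bayes_factor(bf_success = 3)
#' rule_credible_interval(c(0.998, 0.968, 0.968))
NULL

#' @rdname stopping_rules
#' @export
rule_freq_seq <- function(stage_alphas, futility_alpha = NULL) {
  if (!is_probability(stage_alphas)) {
    abort_domain("`stage_alphas` must all lie in (0, 1).")
  }
  if (!is.null(futility_alpha) &&
      (!is_probability(futility_alpha) || length(futility_alpha) != 1L)) {
    abort_domain("`futility_alpha` must be NULL or a single probability in (0, 1).")
  }
  new_rule("freq_seq", list(stage_alphas = stage_alphas,
                            futility_alpha = futility_alpha))
}

#' @rdname stopping_rules
#' @export
rule_bayes_factor <- function(bf_success = 3, bf_futility = NULL,
                              prior_scale = sqrt(2) / 2) {
  if (!is.numeric(bf_success) || bf_success <= 0 || !is.finite(bf_success)) {
    abort_domain("`bf_success` must be a positive number.")
  }
  if (!is.null(bf_futility) &&
      (!is.numeric(bf_futility) || bf_futility <= 0 || bf_futility >= bf_success)) {
    abort_domain("`bf_futility` must be NULL or positive and below `bf_success`.")
  }
  if (!is.numeric(prior_scale) || prior_scale <= 0) {
    abort_domain("`prior_scale` must be positive.")
  }
  new_rule("bayes_factor", list(bf_success = bf_success,
                                bf_futility = bf_futility,
                                prior_scale = prior_scale))
}

#' @rdname stopping_rules
#' @export
rule_credible_interval <- function(levels, futility_level = NULL) {
  if (!is_probability(levels)) {
    abort_domain("`levels` must all lie in (0, 1).")
  }
  if (!is.null(futility_level) &&
      (!is_probability(futility_level) || length(futility_level) != 1L)) {
    abort_domain("`futility_level` must be NULL or a single probability in (0, 1).")
  }
  new_rule("credible_interval", list(levels = levels,
                                     futility_level = futility_level))
}

rule_n_stages <- function(rule) {
  switch(rule$kind,
    fixed = NA_integer_,
    freq_seq = length(rule$stage_alphas),
    bayes_factor = NA_integer_,
    credible_interval = length(rule$levels)
  )
}

#' @export
print.gs_rule <- function(x, ...) {
  cat("<gs_rule> kind = ", x$kind, "\n", sep = "")
  flds <- x[setdiff(names(x), "kind")]
  for (nm in names(flds)) {
    if (!is.null(flds[[nm]])) {
      cat("  ", nm, ": ", paste(signif(flds[[nm]], 5), collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

check_stage <- function(stage, K) {
  if (!is.numeric(stage) || length(stage) != 1L || stage < 1L || stage > K) {
    abort_domain("`stage` must lie between 1 and the number of stages K.")
  }
}

new_decision <- function(action, stage) {
  structure(list(action = action, stage_index = as.integer(stage)),
            class = "gs_decision")
}

#' Stage decisions under the four stopping rules
#'
#' Apply one stage's analysis result to a stopping rule, returning a
#' decision with `action` one of `"stop_efficacy"`, `"stop_futility"`,
#' `"continue"` or `"final_nonsignificant"`.  Futility stops are only taken
#' at interim stages; the final stage never returns `"continue"`.
#'
#' @param stats One-row tibble from [two_sample_t()] (for
#'   `decide_freq_seq()` and `decide_credible_interval()`).
#' @param bf10 Bayes factor from [jzs_bayes_factor()].
#' @param rule A `gs_rule` of matching kind.
#' @param stage Current stage index.
#' @param K Total number of stages.
#' @return A `gs_decision` with fields `action` and `stage_index`.
#' @name stage_decisions
NULL

#' @rdname stage_decisions
#' @export
decide_freq_seq <- function(stats, rule, stage, K) {
  stopifnot(rule$kind == "freq_seq")
  check_stage(stage, K)
  if (length(rule$stage_alphas) != K) {
    abort_domain("`stage_alphas` length must equal the number of stages K.")
  }
  p <- stats$p_two_sided
  if (p < rule$stage_alphas[stage]) {
    return(new_decision("stop_efficacy", stage))
  }
  if (stage < K && !is.null(rule$futility_alpha) && p > rule$futility_alpha) {
    return(new_decision("stop_futility", stage))
  }
  new_decision(if (stage < K) "continue" else "final_nonsignificant", stage)
}

#' @rdname stage_decisions
#' @export
decide_bayes_factor <- function(bf10, rule, stage, K) {
  stopifnot(rule$kind == "bayes_factor")
  check_stage(stage, K)
  if (bf10 >= rule$bf_success) {
    return(new_decision("stop_efficacy", stage))
  }
  if (stage < K && !is.null(rule$bf_futility) && bf10 <= rule$bf_futility) {
    return(new_decision("stop_futility", stage))
  }
  new_decision(if (stage < K) "continue" else "final_nonsignificant", stage)
}

#' @rdname stage_decisions
#' @export
decide_credible_interval <- function(stats, rule, stage, K) {
  stopifnot(rule$kind == "credible_interval")
  check_stage(stage, K)
  if (length(rule$levels) != K) {
    abort_domain("`levels` length must equal the number of stages K.")
  }
  ci <- credible_interval(stats, rule$levels[stage])
  if (ci[["lower"]] > 0 || ci[["upper"]] < 0) {
    return(new_decision("stop_efficacy", stage))
  }
  if (stage < K && !is.null(rule$futility_level)) {
    fut <- credible_interval(stats, rule$futility_level)
    if (fut[["lower"]] <= 0 && fut[["upper"]] >= 0) {
      return(new_decision("stop_futility", stage))
    }
  }
  new_decision(if (stage < K) "continue" else "final_nonsignificant", stage)
}

# dispatch one stage analysis through a rule
apply_rule <- function(rule, stats, stage, K) {
  switch(rule$kind,
    fixed = {
      check_stage(stage, K)
      if (stage < K) {
        new_decision("continue", stage)
      } else if (stats$p_two_sided < rule$alpha) {
        new_decision("stop_efficacy", stage)
      } else {
        new_decision("final_nonsignificant", stage)
      }
    },
    freq_seq = decide_freq_seq(stats, rule, stage, K),
    bayes_factor = decide_bayes_factor(
      jzs_bayes_factor(stats$t_value, stats$n_a, stats$n_b, rule$prior_scale),
      rule, stage, K
    ),
    credible_interval = decide_credible_interval(stats, rule, stage, K)
  )
}
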