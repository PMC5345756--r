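#' Define a stage schedule for a group sequential experiment
#'
#' A stage schedule fixes the preplanned interim analysis points of a staged
#' two-group experiment as cumulative per-group sample sizes.  Information
#' fractions are derived as `cumulative_n / final_n`; the final fraction is
#' always exactly 1.
#'
#' @param n_per_group Strictly increasing vector of positive integers: the
#'   cumulative number of experimental units per group at each analysis.
#'   For example `c(6, 12, 18)` is a three-stage study analysed after 6, 12
#'   and 18 animals per group.
#' @return An object of class `gs_schedule` with fields `n_stages`,
#'   `cumulative_n_per_group` and `information_fractions`.
#' @examples
#' stage_schedule(c(6, 12, 18))
#' @export
stage_schedule <- function(n_per_group) {
  if (!is.numeric(n_per_group) || length(n_per_group) < 1L ||
      any(!is.finite(n_per_group))) {
    abort_schedule("`n_per_group` must be a vector of finite positive integers.")
  }
  n <- as.integer(round(n_per_group))
  if (any(n != n_per_group) || any(n < 2L)) {
    abort_schedule("`n_per_group` must be whole numbers >= 2 (at least two units per group are needed for a stage analysis).")
  }
  if (length(n) > 1L && any(diff(n) <= 0L)) {
    abort_schedule("`n_per_group` must be strictly increasing across stages.")
  }
  structure(
    list(
      n_stages = length(n),
      cumulative_n_per_group = n,
      information_fractions = n / n[length(n)]
    ),
    class = "gs_schedule"
  )
}

is_gs_schedule <- function(x) inherits(x, "gs_schedule")

as_schedule <- function(x) {
  if (is_gs_schedule(x)) return(x)
  if (is.numeric(x)) return(stage_schedule(x))
  abort_schedule("Expected a `gs_schedule` or a numeric vector of cumulative per-group sample sizes.")
}

#' @export
print.gs_schedule <- function(x, ...) {
  cat("<gs_schedule> ", x$n_stages, " stage(s)\n", sep = "")
  cat("  cumulative n per group: ", paste(x$cumulative_n_per_group, collapse = ", "), "\n", sep = "")
  cat("  information fractions:  ",
      paste(format(round(x$information_fractions, 3)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy gs_schedule
#' @export
tidy.gs_schedule <- function(x, ...) {
  tibble::tibble(
    stage = seq_len(x$n_stages),
    n_per_group = x$cumulative_n_per_group,
    information_fraction = x$information_fractions
  )
}
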