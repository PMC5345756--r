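# internal validation / error helpers -----------------------------------

abort_schedule <- function(msg) abort(msg, class = "preclinseq_schedule_error")
abort_domain <- function(msg) abort(msg, class = "preclinseq_domain_error")
abort_numerical <- function(msg) abort(msg, class = "preclinseq_numerical_error")
abort_degenerate <- function(msg) abort(msg, class = "preclinseq_degenerate_error")
abort_calibration <- function(msg, data = NULL) {
  abort(msg, class = "preclinseq_calibration_error", diagnostics = data)
}
abort_config <- function(msg) abort(msg, class = "preclinseq_config_error")

is_probability <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x > 0) && all(x < 1)
}

#' Derive independent per-trial seeds from a master seed
#'
#' Trials are individually reproducible: trial `i` of a run is fully
#' determined by `derive_seeds(master, n)[i]`, so any single simulated
#' experiment can be regenerated in isolation with [run_trial()].
#'
#' @param master Integer master seed.
#' @param n Number of seeds to derive.
#' @return Integer vector of length `n`, all below 2^31 - 1.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master))
  sample.int(2147483646L, n)
}
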