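# Serialize designs to plain lists / JSON / YAML and back.

#' Serialize a design to a plain list
#'
#' The list mirrors the design definition: cumulative per-group sample
#' sizes, rule kind and the thresholds of that kind.  Round-trips through
#' [design_from_list()] and through JSON/YAML files via
#' [write_design_config()] / [read_design_config()].
#'
#' @param design A [gs_design()].
#' @return A named list.
#' @export
design_to_list <- function(design) {
  stopifnot(inherits(design, "gs_design"))
  rule <- design$rule
  fields <- rule[setdiff(names(rule), "kind")]
  fields <- fields[!vapply(fields, is.null, logical(1))]
  list(
    label = design$label,
    n_per_group = design$schedule$cumulative_n_per_group,
    rule = c(list(kind = rule$kind), fields)
  )
}

#' @rdname design_to_list
#' @param x A list as produced by `design_to_list()`.
#' @export
design_from_list <- function(x) {
  if (!is.list(x) || is.null(x$n_per_group) || is.null(x$rule$kind)) {
    abort_config("A design config needs `n_per_group` and `rule$kind`.")
  }
  r <- x$rule
  rule <- switch(as.character(r$kind),
    fixed = rule_fixed(r$alpha %||% 0.05),
    freq_seq = rule_freq_seq(unlist(r$stage_alphas), r$futility_alpha),
    bayes_factor = rule_bayes_factor(r$bf_success %||% 3, r$bf_futility,
                                     r$prior_scale %||% (sqrt(2) / 2)),
    credible_interval = rule_credible_interval(unlist(r$levels),
                                               r$futility_level),
    abort_config(paste0("Unknown rule kind: ", r$kind))
  )
  gs_design(stage_schedule(unlist(x$n_per_group)), rule, x$label)
}

#' Read or write a design configuration file
#'
#' The format is chosen by the file extension: `.json` (jsonlite) or
#' `.yaml`/`.yml` (yaml).
#'
#' @param design A [gs_design()].
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_design_config()` returns `path` invisibly;
#'   `read_design_config()` returns a [gs_design()].
#' @export
write_design_config <- function(design, path) {
  x <- design_to_list(design)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    abort_config("Unsupported config extension; use .json, .yaml or .yml.")
  }
  invisible(path)
}

#' @rdname write_design_config
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("No such config file: ", path))
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    abort_config("Unsupported config extension; use .json, .yaml or .yml.")
  }
  design_from_list(x)
}
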