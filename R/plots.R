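# ggplot2 autoplot methods for the main result types.

#' Plot a stopping boundary
#'
#' Z-scale boundary (and its mirror image) against the information
#' fraction, annotated with the per-stage nominal significance levels.
#'
#' @param object A `gs_boundary`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot gs_boundary
#' @export
autoplot.gs_boundary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  both <- dplyr::bind_rows(
    dplyr::mutate(df, side = "upper"),
    dplyr::mutate(df, z_bound = -.data$z_bound, side = "lower")
  )
  ggplot2::ggplot(both, ggplot2::aes(.data$information_fraction, .data$z_bound,
                                     group = .data$side)) +
    ggplot2::geom_line(linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(
      data = dplyr::filter(both, .data$side == "upper"),
      ggplot2::aes(label = signif(.data$nominal_level, 2)),
      vjust = -1, size = 3
    ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::labs(
      x = "information fraction",
      y = "boundary (z scale)",
      title = paste0(attr(object, "family"), " boundary, overall alpha ",
                     attr(object, "overall_alpha"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot stagewise stopping behaviour
#'
#' Cumulative percentage of significant trials and per-stage futility
#' percentage by analysis stage.
#'
#' @param object A `gs_oc` from [operating_characteristics()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot gs_oc
#' @export
autoplot.gs_oc <- function(object, ...) {
  long <- object$stages |>
    dplyr::select("stage", significant = "cum_significant_pct",
                  futility = "futility_pct") |>
    tidyr::pivot_longer(-"stage", names_to = "outcome", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$stage), .data$pct,
                                     fill = .data$outcome)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "stage", y = "% of trials",
      title = paste0(object$summary$label, ", true d = ", object$summary$true_d),
      subtitle = paste0("overall significant: ",
                        round(object$summary$overall_significant_pct, 1),
                        "%, mean cost ", round(object$summary$mean_cost, 1),
                        " animals"),
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot predictive-value composition
#'
#' Bar chart of P(significant), the positive predictive values and their
#' products for the two true-effect classifications (d > 0, d >= 0.5).
#'
#' @param object A `gs_ppv` from [ppv_analysis()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot gs_ppv
#' @export
autoplot.gs_ppv <- function(object, ...) {
  s <- object$summary
  df <- tibble::tibble(
    classification = rep(c("d > 0", "d >= 0.5"), each = 3L),
    quantity = factor(
      rep(c("P(significant)", "PPV", "P(detect true effect)"), 2L),
      levels = c("P(significant)", "PPV", "P(detect true effect)")
    ),
    value = c(s$p_significant, s$ppv_any, s$p_detect_any,
              s$p_significant, s$ppv_ge_half, s$p_detect_ge_half)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$quantity, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~.data$classification) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = NULL, y = "probability",
      title = paste0(s$label, " under '", s$scenario, "' effect-size scenario")
    ) +
    ggplot2::theme_minimal()
}
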