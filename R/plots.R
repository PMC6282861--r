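# ggplot2 displays for sweep assessments and stopping boundaries.

#' Plot a prevalence-sweep assessment
#'
#' Standardized bias, standardized root-MSE and cell proportions against the
#' subgroup-1 prevalence, one line per conditioning situation, faceted by
#' population and measure — the standard display for how selection and
#' reporting bias of the naive MLE vary with prevalence.
#'
#' @param object An `enrich_sweep` tibble from [run_scenario()].
#' @param stage Stage scope to display (default `"overall"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrich_sweep
#' @export
autoplot.enrich_sweep <- function(object, stage = "overall", ...) {
  df <- dplyr::filter(object, .data$stage == !!stage)
  long <- tidyr::pivot_longer(
    df, c("bias_over_se", "rmse_over_se", "proportion_pct"),
    names_to = "measure", values_to = "value"
  )
  long$measure <- factor(long$measure,
                         levels = c("bias_over_se", "rmse_over_se",
                                    "proportion_pct"),
                         labels = c("bias / SE", "sqrt(MSE) / SE",
                                    "proportion (%)"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$prevalence1, y = .data$value,
                               colour = .data$conditioning)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(ggplot2::vars(.data$measure),
                        ggplot2::vars(.data$population), scales = "free_y") +
    ggplot2::labs(x = "prevalence of subgroup 1", y = NULL,
                  colour = "conditioning") +
    ggplot2::theme_minimal()
}

#' Plot stopping boundaries
#'
#' Upper (efficacy) and lower (futility) bounds against the stage index.
#'
#' @param object A `boundaries` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot boundaries
#' @export
autoplot.boundaries <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("upper", "lower"),
                            names_to = "bound", values_to = "value")
  df <- dplyr::filter(df, is.finite(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$value,
                                   linetype = .data$bound)) +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(df$stage)) +
    ggplot2::labs(x = "stage", y = "standardized statistic",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}
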