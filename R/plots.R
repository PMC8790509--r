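#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot item parameter estimates from a calibration
#'
#' Discrimination against difficulty (first boundary for graded items),
#' testlet items coloured by testlet.
#'
#' @param object A `trt_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trt_fit
#' @export
autoplot.trt_fit <- function(object, ...) {
  d <- object$items
  d$difficulty <- if ("b" %in% names(d)) d$b else d$b1
  d$testlet <- ifelse(is.na(d$testlet_id), "independent", d$testlet_id)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$difficulty, y = .data$a,
                                  colour = .data$testlet)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "difficulty (b or b1)", y = "discrimination (a)",
                  title = paste(object$model, "item estimates")) +
    ggplot2::theme_minimal()
}

#' Truth-versus-estimate recovery plot for a condition run
#'
#' Per-item mean estimate across replications against the generating
#' truth, faceted by parameter, coloured by fitted model, with the
#' identity line. Systematic displacement from the diagonal is the
#' equating bias pattern.
#'
#' @param object A `condition_run` from [run_condition()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot condition_run
#' @export
autoplot.condition_run <- function(object, ...) {
  d <- object$item_estimates |>
    dplyr::group_by(.data$model, .data$param, .data$item_id) |>
    dplyr::summarise(truth = .data$truth[1],
                     estimate = mean(.data$estimate), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$truth, y = .data$estimate,
                                  colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$param), scales = "free") +
    ggplot2::labs(x = "true value", y = "mean estimate") +
    ggplot2::theme_minimal()
}

#' Plot equating error across study conditions
#'
#' One line per fitted model and sample size, error metric against
#' testlet-effect level, faceted by parameter family and testlet length.
#'
#' @param summaries The `summaries` tibble of a [run_study()] result.
#' @param metric `"rmse"`, `"bias"` or `"see"`.
#' @return A ggplot.
#' @export
plot_study_summary <- function(summaries, metric = c("rmse", "bias", "see")) {
  metric <- match.arg(metric)
  d <- dplyr::mutate(
    summaries,
    testlet_effect = factor(.data$testlet_effect,
                            levels = c("low", "moderate", "high")),
    n = factor(.data$sample_size)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$testlet_effect,
                                  y = .data[[metric]],
                                  colour = .data$model,
                                  linetype = .data$n,
                                  group = interaction(.data$model, .data$n))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(ggplot2::vars(.data$param),
                        ggplot2::vars(.data$testlet_length),
                        scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "testlet effect", y = toupper(metric)) +
    ggplot2::theme_minimal()
}
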