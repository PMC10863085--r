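#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Overview plot of all growth curves in a dataset
#'
#' Raw traces, one line per sample, replicates sharing a colour. With
#' `grouped = TRUE` the per-group mean trace is drawn with a +/- 1 sd
#' ribbon instead.
#'
#' @param dataset A [growth_dataset].
#' @param grouped Plot replicate-group means with sd bands instead of
#'   individual traces.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(dataset, grouped = FALSE) {
  df <- as_tibble(dataset)
  if (grouped) {
    df <- df |>
      dplyr::group_by(.data$name, .data$time) |>
      dplyr::summarise(mean = mean(.data$value),
                       sd = stats::sd(.data$value), .groups = "drop")
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$mean,
                                       colour = .data$name,
                                       fill = .data$name)) +
        ggplot2::geom_ribbon(
          ggplot2::aes(ymin = .data$mean - .data$sd,
                       ymax = .data$mean + .data$sd),
          alpha = 0.2, colour = NA) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "Time (h)", y = dataset$unit,
                      colour = "Sample", fill = "Sample") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   group = .data$id,
                                   colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = dataset$unit, colour = "Sample") +
    ggplot2::theme_minimal()
}

#' Plot a fitted growth curve on the log scale
#'
#' Valid data points of the log trace with the fitted model curve (for
#' parametric fits) or the fitted line over the winning window (Easy
#' Linear / manual), and dashed guides at the exponential-phase
#' boundaries.
#'
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.growth_fit <- function(object, ...) {
  df <- as_tibble(object$trace)
  g <- ggplot2::ggplot(dplyr::filter(df, .data$valid),
                       ggplot2::aes(.data$time, .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "Time (h)", y = "ln(N / N0)") +
    ggplot2::theme_minimal()
  if (!isTRUE(object$converged)) {
    return(g + ggplot2::ggtitle(sprintf("%s: not converged", object$method)))
  }
  if (object$method %in% c("logistic", "gompertz")) {
    grid <- seq(min(df$time), max(df$time), length.out = 400)
    fitdf <- tibble::tibble(time = grid,
                            y = model_y(object$params, grid))
    g <- g + ggplot2::geom_line(data = fitdf, colour = "orange")
    bounds <- exp_phase_bounds(object$params, object$lag_definition)
  } else {
    idx <- object$window
    seg <- df[seq(idx[1], idx[2]), ]
    fit <- ols_line(seg$time[seg$valid], seg$y[seg$valid])
    segdf <- tibble::tibble(
      time = range(seg$time),
      y = fit$intercept + fit$slope * range(seg$time))
    g <- g + ggplot2::geom_line(data = segdf, colour = "orange")
    bounds <- c(t_start = object$trace$times[idx[1]],
                t_end = object$trace$times[idx[2]])
  }
  g +
    ggplot2::geom_vline(xintercept = unname(bounds), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::ggtitle(sprintf("%s fit: mu_max = %.3g /h", object$method,
                             object$mu_max))
}

#' Plot a synthetic-validation report
#'
#' Bar chart of the median relative recovery error per growth parameter.
#'
#' @param object A `validation_report` from [run_validation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$parameter, .data$median_rel_error)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$model)) +
    ggplot2::labs(x = NULL, y = "Median relative error") +
    ggplot2::theme_minimal()
}
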