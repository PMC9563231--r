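#' Plot an evolutionary training curve
#'
#' Min/mean/max iteration fitness over training.
#'
#' @param object An `evol_log` tibble (from `run_evol()$log`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evol_log <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = "iteration", y = "fitness (steps/episode)",
                  title = "Evolutionary-strategy training") +
    ggplot2::theme_minimal()
}

#' Plot an STDP-RL episode log
#'
#' Per-episode steps with the trailing 100-episode moving average.
#'
#' @param object An `stdp_log` tibble (from `run_stdp_training()$episodes`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stdp_log <- function(object, ...) {
  df <- tibble::tibble(episode = object$episode, steps = object$steps,
                       avg100 = moving_average(object$steps, 100))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$episode)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$steps), alpha = 0.3, size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$avg100), colour = "darkgreen") +
    ggplot2::labs(x = "episode", y = "steps survived",
                  title = "STDP-RL training") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
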