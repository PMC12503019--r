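# Plot methods.

#' Plot monitored waveforms
#'
#' Pressure (kPa) and flow (mL/s) over one cardiac period at each
#' monitoring position.
#'
#' @param object A `pw_result` from [pw_run()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pw_result <- function(object, ...) {
  wf <- object$waveforms
  long <- tidyr::pivot_longer(
    dplyr::mutate(wf,
      `pressure [kPa]` = .data$pressure_Pa / 1e3,
      `flow [mL/s]` = .data$flow_m3s * 1e6
    ),
    cols = c("pressure [kPa]", "flow [mL/s]"),
    names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
    colour = .data$position)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = "time [s]", y = NULL,
      title = paste0("Pulse waveforms: ", object$case$name)
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.pw_result <- function(x, ...) print(autoplot(x, ...))

#' Plot an inflow waveform
#'
#' @param inflow Tibble with `time`/`flow` columns (see [pw_inflow()]).
#' @return A ggplot object.
#' @export
plot_inflow <- function(inflow) {
  ggplot2::ggplot(inflow, ggplot2::aes(.data$time, .data$flow * 1e6)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "inflow [mL/s]") +
    ggplot2::theme_minimal()
}
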