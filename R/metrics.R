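# Waveform validation error metrics.

#' Waveform error metrics
#'
#' Computes the four validation errors between a model waveform and a
#' reference waveform over one period: RMS, maximum, systolic (error of the
#' maxima) and diastolic (error of the minima). Pressure errors are
#' normalized pointwise by the reference pressure; flow errors are
#' normalized by the maximum of the reference flow over the period —
#' including the diastolic flow error — because reference flows cross zero.
#'
#' \deqn{\varepsilon^{rms}_p = \sqrt{\frac1n \sum_i
#'   \left(\frac{p^m_i - p^{ref}_i}{p^{ref}_i}\right)^2}, \quad
#'   \varepsilon^{rms}_q = \sqrt{\frac1n \sum_i
#'   \left(\frac{q^m_i - q^{ref}_i}{\max q^{ref}}\right)^2}}
#'
#' Systolic and diastolic errors are signed.
#'
#' @param model,reference Numeric vectors of equal length: aligned samples
#'   over one period.
#' @param kind `"pressure"` or `"flow"` (selects the normalization).
#' @return A tibble with columns `metric` (`rms`, `max`, `sys`, `dia`) and
#'   `error_pct` (percent).
#' @export
pw_error_metrics <- function(model, reference,
                             kind = c("pressure", "flow")) {
  kind <- match.arg(kind)
  stopifnot(length(model) == length(reference), length(model) >= 2)
  if (kind == "pressure") {
    if (any(reference == 0) || min(reference) == 0) {
      stop("zero reference pressure: pointwise normalization undefined",
        call. = FALSE)
    }
    rel <- (model - reference) / reference
    sys <- (max(model) - max(reference)) / max(reference)
    dia <- (min(model) - min(reference)) / min(reference)
  } else {
    qmax <- max(reference)
    if (qmax == 0) {
      stop("zero maximum reference flow: normalization undefined",
        call. = FALSE)
    }
    rel <- (model - reference) / qmax
    sys <- (max(model) - max(reference)) / qmax
    dia <- (min(model) - min(reference)) / qmax
  }
  tibble::tibble(
    metric = c("rms", "max", "sys", "dia"),
    error_pct = 100 * c(sqrt(mean(rel^2)), max(abs(rel)), sys, dia)
  )
}

#' Compare monitored waveform tables
#'
#' Applies [pw_error_metrics()] per monitoring position and quantity to two
#' tidy waveform tables as produced by [pw_waveforms()] (columns `time`,
#' `position`, `pressure_Pa`, `flow_m3s`), yielding an error table in the
#' layout used for benchmark validation.
#'
#' @param model,reference Waveform tibbles with matching positions and
#'   aligned time grids.
#' @return Tibble with columns `position`, `quantity`, `metric`,
#'   `error_pct`.
#' @export
pw_compare <- function(model, reference) {
  pos <- unique(reference$position)
  if (!setequal(unique(model$position), pos)) {
    stop("model and reference monitor positions differ", call. = FALSE)
  }
  purrr::map_dfr(pos, function(p) {
    m <- dplyr::filter(model, .data$position == p)
    r <- dplyr::filter(reference, .data$position == p)
    if (nrow(m) != nrow(r)) {
      stop("mismatched sample grids at position ", p, call. = FALSE)
    }
    dplyr::bind_rows(
      dplyr::mutate(
        pw_error_metrics(m$pressure_Pa, r$pressure_Pa, "pressure"),
        position = p, quantity = "pressure", .before = 1
      ),
      dplyr::mutate(
        pw_error_metrics(m$flow_m3s, r$flow_m3s, "flow"),
        position = p, quantity = "flow", .before = 1
      )
    )
  })
}
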