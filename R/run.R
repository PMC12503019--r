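# End-to-end runner: case/config + inflow -> solved waveforms.

#' Run a simulation case end to end
#'
#' Builds the network from a `pw_case` (or a config file path), decomposes
#' the inflow waveform into harmonics, solves the network (with nonlinear
#' iteration when loss elements are present) and synthesizes pressure and
#' flow at the case's monitoring positions.
#'
#' @param case A `pw_case` (see [pw_case()], [pw_read_config()]) or a path
#'   to a YAML config file.
#' @param inflow Optional inflow override: a tibble with `time`/`flow`
#'   columns, a preset name for [pw_inflow()], or a CSV path. Defaults to
#'   the case's inflow preset.
#' @param nh,n_time Harmonic count and samples per period; default to the
#'   case's simulation block.
#' @param mean_radius_iter Enable the outer mean-radius iteration (uses the
#'   case's diastolic pressure).
#' @param ... Passed on to [pw_solve()].
#' @return A `pw_result`: list with `waveforms` (tidy tibble), `solution`
#'   (`pw_solution`), `case`, and a `log` list (iterations, worst condition
#'   number, worst linear residual). Supports `tidy()`, `glance()` and
#'   [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' res <- pw_run(pw_case_carotid(severity = 75))
#' glance(res)
#' }
#' @export
pw_run <- function(case, inflow = NULL, nh = NULL, n_time = NULL,
                   mean_radius_iter = FALSE, ...) {
  if (is.character(case)) case <- pw_read_config(case)
  stopifnot(inherits(case, "pw_case"))
  nh <- nh %||% case$sim$nh
  n_time <- n_time %||% case$sim$n_time
  inflow <- inflow %||% case$inflow_preset
  if (is.character(inflow)) {
    inflow <- if (file.exists(inflow)) {
      pw_read_waveform(inflow)
    } else {
      pw_inflow(preset = inflow)
    }
  }
  net <- pw_network(case$elements, case$nodes, case$fluid)
  sol <- pw_solve(net, inflow,
    nh = nh, tol = case$sim$tol %||% 1e-6,
    mean_radius_iter = mean_radius_iter, pd = case$pd, ...
  )
  wf <- if (nrow(case$monitors)) {
    pw_waveforms(sol, case$monitors, n_time = n_time)
  } else {
    tibble::tibble(time = numeric(), position = character(),
      pressure_Pa = numeric(), flow_m3s = numeric())
  }
  structure(
    list(
      waveforms = wf, solution = sol, case = case,
      log = list(
        iterations = sol$iterations,
        converged = sol$converged,
        max_condition = max(sol$conds),
        max_residual = max(sol$resids)
      )
    ),
    class = "pw_result"
  )
}

#' @export
print.pw_result <- function(x, ...) {
  cat("<pw_result> ", x$case$name, ": ", x$log$iterations,
    " iteration(s), max residual ", format(x$log$max_residual, digits = 3),
    "\n", sep = "")
  invisible(x)
}

#' @rdname pw_result_tidiers
#' @export
tidy.pw_result <- function(x, ...) x$waveforms

#' Tidiers for simulation results
#'
#' `tidy()` returns the monitored waveform table; `glance()` a one-row run
#' summary.
#'
#' @param x A `pw_result`.
#' @param ... Unused.
#' @name pw_result_tidiers
#' @export
glance.pw_result <- function(x, ...) {
  dplyr::mutate(glance(x$solution), case = x$case$name, .before = 1)
}

#' Export result waveforms and manifest
#'
#' Writes the tidy waveform table to `<dir>/waveforms.csv` and a JSON-free
#' plain YAML run manifest (`<dir>/run.yaml`) with the solver log.
#'
#' @param result A `pw_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
pw_export <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$waveforms, file.path(dir, "waveforms.csv"))
  yaml::write_yaml(
    list(
      case = result$case$name,
      iterations = result$log$iterations,
      converged = result$log$converged,
      max_condition = result$log$max_condition,
      max_residual = result$log$max_residual
    ),
    file.path(dir, "run.yaml")
  )
  invisible(dir)
}
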