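# Harmonic analysis of periodic waveforms and the parameterized inflow
# generator.
#
# Convention: the spectrum of a T-periodic real signal is the one-sided set
# of complex amplitudes x_n (n = 0..Nh) defined by the analysis kernel
# exp(-i n w0 t) and reconstructed as
#   x(t) = x_0 + sum_{n>=1} Re[ x_n exp(+i n w0 t) ].
# Under this pair the element phase factor exp(-i kappa x) propagates toward
# +x as time advances and the Windkessel capacitor admittance is +i w C.

#' Decompose a periodic waveform into harmonics
#'
#' Computes the one-sided complex harmonic amplitudes of a uniformly sampled
#' periodic signal (one period, endpoint excluded).
#'
#' @param x A data frame with columns `time` (s) and a value column (`flow`
#'   or `value`), or a numeric vector with `period` supplied.
#' @param nh Number of harmonics above DC to keep.
#' @param period Signal period (s); inferred from the time column when `x`
#'   is a data frame (samples assumed to cover exactly one period).
#' @return A `pw_spectrum`: list with fundamental `f0` (Hz) and complex
#'   amplitudes `x` of length `nh + 1` (index 1 = DC mean, real).
#' @export
pw_decompose <- function(x, nh = 15, period = NULL) {
  if (is.data.frame(x)) {
    vcol <- intersect(c("flow", "value", "pressure"), names(x))[1]
    if (is.na(vcol) || !"time" %in% names(x)) {
      stop("waveform data frame needs columns time and flow/value",
        call. = FALSE)
    }
    dt <- diff(x$time)
    if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
      stop("waveform samples must be uniformly spaced", call. = FALSE)
    }
    period <- dt[1] * nrow(x)
    v <- x[[vcol]]
  } else {
    v <- as.numeric(x)
    if (is.null(period)) stop("period required for a bare vector",
      call. = FALSE)
  }
  n <- length(v)
  if (n < 2 * nh + 1) {
    stop("need at least 2*nh + 1 = ", 2 * nh + 1, " samples per period",
      call. = FALSE)
  }
  ft <- stats::fft(v) / n # kernel exp(-2 pi i k n / N): analysis convention
  amps <- c(Re(ft[1]) + 0i, 2 * ft[seq_len(nh) + 1])
  structure(list(f0 = 1 / period, x = amps, nh = nh), class = "pw_spectrum")
}

# Reconstruct samples from one-sided harmonic amplitudes.
synthesize_harmonics <- function(amps, f0, t_grid) {
  w0 <- 2 * pi * f0
  out <- rep(Re(amps[1]), length(t_grid))
  for (n in seq_len(length(amps) - 1)) {
    out <- out + Re(amps[n + 1] * exp(1i * n * w0 * t_grid))
  }
  out
}

#' Synthesize a waveform from a harmonic spectrum
#'
#' Inverse of [pw_decompose()]: evaluates
#' `x(t) = x0 + sum Re[x_n exp(+i n w0 t)]` on a time grid.
#'
#' @param spectrum A `pw_spectrum`.
#' @param t_grid Time points (s); default one period at 1000 samples.
#' @return Tibble with columns `time` and `value`.
#' @export
pw_synthesize <- function(spectrum, t_grid = NULL) {
  stopifnot(inherits(spectrum, "pw_spectrum"))
  if (is.null(t_grid)) {
    t_grid <- seq(0, 1 / spectrum$f0, length.out = 1001)[1:1000]
  }
  tibble::tibble(
    time = t_grid,
    value = synthesize_harmonics(spectrum$x, spectrum$f0, t_grid)
  )
}

#' @export
print.pw_spectrum <- function(x, ...) {
  cat("<pw_spectrum> f0 =", signif(x$f0, 4), "Hz, harmonics 0..",
    length(x$x) - 1, "; mean =", signif(Re(x$x[1]), 4), "\n")
  invisible(x)
}

#' Parameterized synthetic inflow pulse
#'
#' Generates a smooth single-pulse periodic inflow: a raised-cosine systolic
#' ejection over a diastolic baseline. The baseline is set so that the mean
#' over the period equals `mean_flow` exactly. Presets approximate the
#' inflow conditions of the built-in benchmark cases (the published inflows
#' exist only as figures, so these are parameterized stand-ins chosen from
#' physiology; see the package vignette).
#'
#' @param mean_flow Period-averaged flow (m^3/s).
#' @param peak_flow Peak systolic flow (m^3/s), must exceed `mean_flow`.
#' @param systole_fraction Fraction of the period occupied by the ejection
#'   pulse, in (0, 1).
#' @param period Cardiac period (s).
#' @param n Samples per period.
#' @param preset One of `"aortic_bifurcation"`, `"carotid"`, `"aorta"`; when
#'   given, all other parameters are ignored. The carotid preset yields a
#'   first-harmonic to mean ratio of about 1/4.
#' @return Tibble with columns `time` (s) and `flow` (m^3/s).
#' @export
pw_inflow <- function(mean_flow = NULL, peak_flow = NULL,
                      systole_fraction = 0.35, period = 1,
                      n = 1000, preset = NULL) {
  if (!is.null(preset)) {
    p <- switch(preset,
      aortic_bifurcation = list(mean = 7.8e-6, peak = 4.5e-5,
        fs = 0.34, T = 1.1),
      carotid = list(mean = 6.0e-6, peak = 9.33e-6, fs = 0.40, T = 1.1),
      aorta = list(mean = 9.2e-5, peak = 4.6e-4, fs = 0.36, T = 1.0),
      stop("unknown preset ", preset, call. = FALSE)
    )
    return(pw_inflow(p$mean, p$peak, p$fs, p$T, n = n))
  }
  stopifnot(
    systole_fraction > 0, systole_fraction < 1,
    mean_flow > 0
  )
  ts <- systole_fraction * period
  # pulse p(t) = (1 - cos(2 pi t/ts))/2 on [0, ts); mean of pulse = ts/(2T)
  amp_gain <- 1 - ts / (2 * period)
  if (peak_flow <= mean_flow) {
    stop("inconsistent mean/peak: peak_flow must exceed mean_flow",
      call. = FALSE)
  }
  A <- (peak_flow - mean_flow) / amp_gain
  base <- mean_flow - A * ts / (2 * period)
  t <- seq(0, period, length.out = n + 1)[seq_len(n)]
  pulse <- ifelse(t < ts, (1 - cos(2 * pi * t / ts)) / 2, 0)
  tibble::tibble(time = t, flow = base + A * pulse)
}

#' Read / write a waveform CSV
#'
#' Plain two-column CSV interchange format: `time` (s) and one value column
#' in SI units, covering exactly one period, header required.
#'
#' @param path File path.
#' @return `pw_read_waveform()`: a tibble with the file's columns.
#' @export
pw_read_waveform <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time" %in% names(out) || ncol(out) < 2) {
    stop("waveform CSV must have a header with a time column and a value ",
      "column", call. = FALSE)
  }
  out
}

#' @rdname pw_read_waveform
#' @param x Data frame to write.
#' @export
pw_write_waveform <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
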