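# Vessel element descriptors and their per-frequency matrix builders.

#' Describe a vascular defect (stenosis or aneurysm)
#'
#' A defect replaces the middle section of a vessel element by a segment of
#' different lumen area with quasi-steady Borda-Carnot losses lumped at its
#' inlet and outlet (abrupt mode) or distributed as conical transitions with
#' a single lumped loss in the throat (conical mode).
#'
#' @param kind `"stenosis"` or `"aneurysm"`.
#' @param severity Relative size in percent, `(1 - As/A0) * 100` for a
#'   stenosis. Give either `severity` or `area`.
#' @param area Defect lumen area `As` (m^2).
#' @param length Defect (throat) length (m), must be shorter than the vessel.
#' @param position Distance from the element inlet to the start of the
#'   defect (m); default centres the defect.
#' @param cl_in,cl_out Loss coefficients at the defect inlet/outlet. Defaults
#'   are the sudden contraction + expansion pair 0.52 / 1 for a stenosis
#'   (total 1.52); they are swapped for an aneurysm.
#' @param mode `"abrupt"` (sudden area changes) or `"conical"` (conical
#'   reduction and expansion with one lumped loss carrying the total CL).
#' @return A `pw_defect` specification list.
#' @export
pw_defect <- function(kind = c("stenosis", "aneurysm"), severity = NULL,
                      area = NULL, length, position = NULL,
                      cl_in = NULL, cl_out = NULL,
                      mode = c("abrupt", "conical")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (is.null(severity) && is.null(area)) {
    stop("pw_defect(): give either severity (%) or area (m^2)", call. = FALSE)
  }
  if (!is.null(severity)) {
    if (kind == "stenosis" && (severity <= 0 || severity >= 100)) {
      stop("pw_defect(): stenosis severity must lie in (0, 100)",
        call. = FALSE
      )
    }
  }
  if (is.null(cl_in)) cl_in <- if (kind == "stenosis") 0.52 else 1
  if (is.null(cl_out)) cl_out <- if (kind == "stenosis") 1 else 0.52
  structure(
    list(
      kind = kind, severity = severity, area = area, length = length,
      position = position, cl_in = cl_in, cl_out = cl_out, mode = mode
    ),
    class = "pw_defect"
  )
}

# Resolve defect absolute area against the parent lumen area.
defect_area <- function(defect, area0) {
  a <- defect$area
  if (is.null(a)) a <- (1 - defect$severity / 100) * area0
  if (defect$kind == "stenosis" && a >= area0) {
    stop("stenosis area must be smaller than the parent lumen", call. = FALSE)
  }
  if (defect$kind == "aneurysm" && a <= area0) {
    stop("aneurysm area must exceed the parent lumen", call. = FALSE)
  }
  a
}

# Borda-Carnot DC resistances for the two loss sites of a defect.
# Reference area and contraction ratio follow the classical convention:
# referenced to the smaller lumen on each side of the jump.
defect_loss_resistances <- function(defect, area0, q0, rho, n = 0) {
  as_ <- defect_area(defect, area0)
  if (defect$kind == "stenosis") {
    a_ref <- as_
    sigma <- as_ / area0
  } else {
    a_ref <- area0
    sigma <- area0 / as_
  }
  c(
    borda_carnot_resistance(q0, defect$cl_in, a_ref, sigma, rho, n),
    borda_carnot_resistance(q0, defect$cl_out, a_ref, sigma, rho, n)
  )
}

# ---- per-frequency builders -------------------------------------------------

# Single straight homogeneous span at omega (>= 0). radius_d/radius_mean/E/h
# constant; theta applies the taper speed correction for discretized cones.
straight_span <- function(omega, len, radius_d, radius_mean, E, h, fluid,
                          poisson = 0.5, theta = 0) {
  z_ref <- inviscid_impedance(radius_d, radius_mean, E, h, fluid, poisson)
  if (omega == 0) {
    span_piece(len,
      kappa = NA, z0 = NA,
      r_per_len = dc_resistance(fluid$viscosity, 1, radius_mean),
      z_ref = z_ref
    )
  } else {
    ws <- wave_state(omega, radius_d, radius_mean, E, h, fluid,
      poisson = poisson, theta = theta
    )
    span_piece(len,
      kappa = ws$kappa, z0 = ws$z0,
      r_per_len = dc_resistance(fluid$viscosity, 1, radius_mean),
      z_ref = z_ref
    )
  }
}

# Uniform vessel element matrices at omega.
uniform_vessel <- function(omega, len, radius_d, radius_mean, E, h, fluid,
                           poisson = 0.5) {
  pieces_to_matrices(list(
    straight_span(omega, len, radius_d, radius_mean, E, h, fluid, poisson)
  ))
}

# Linearly tapered vessel: discretized into n_seg straight spans with the
# cos(theta)/cos(theta/2) wave-speed correction. Segment count follows the
# lambda/5 rule at omega_max and is kept identical across frequencies.
taper_segment_count <- function(len, radius_d_in, radius_d_out, E, h, fluid,
                                omega_max, poisson = 0.5) {
  c_lo <- min(
    Re(wave_speed(E, h, fluid$density, radius_d_in, radius_d_in, poisson)),
    Re(wave_speed(E, h, fluid$density, radius_d_out, radius_d_out, poisson))
  )
  lambda_min <- 2 * pi * c_lo / max(omega_max, 1e-9)
  max(2L, as.integer(ceiling(len / (lambda_min / 5))))
}

tapered_vessel <- function(omega, len, radius_d_in, radius_d_out, E, h, fluid,
                           n_seg, poisson = 0.5,
                           radius_mean_in = radius_d_in,
                           radius_mean_out = radius_d_out) {
  stopifnot(radius_d_in > 0, radius_d_out > 0, n_seg >= 1)
  theta <- atan((radius_d_in - radius_d_out) / len)
  xs <- (seq_len(n_seg) - 0.5) / n_seg
  # anchor the end segments at the exact port radii: keeps the port
  # characteristic impedances exact and the discretization second order
  if (n_seg >= 2) {
    xs[1] <- 0
    xs[n_seg] <- 1
  }
  pieces <- lapply(xs, function(x) {
    rd <- radius_d_in + x * (radius_d_out - radius_d_in)
    rm <- radius_mean_in + x * (radius_mean_out - radius_mean_in)
    straight_span(omega, len / n_seg, rd, rm, E, h, fluid, poisson, theta)
  })
  pieces_to_matrices(pieces)
}

# Defect vessel: parent spans around a constricted/dilated throat with
# Borda-Carnot lumps. q0 is the current steady-flow iterate; n is the
# harmonic index selecting the delta_n factor.
defect_vessel <- function(omega, len, radius_d, radius_mean, E, h, fluid,
                          defect, q0 = 0, n = 0, omega_max = omega,
                          poisson = 0.5) {
  if (defect$length >= len) {
    stop("defect length must be smaller than the vessel length", call. = FALSE)
  }
  area0 <- pi * radius_mean^2
  as_ <- defect_area(defect, area0)
  rs <- sqrt(as_ / pi)
  pos <- defect$position
  if (is.null(pos)) pos <- (len - defect$length) / 2
  l1 <- pos
  l3 <- len - pos - defect$length
  stopifnot(l1 >= 0, l3 >= 0)
  r_nl <- defect_loss_resistances(defect, area0, q0, fluid$density, n)
  # stress-free defect wall assumed: diastolic radius scales with the lumen
  rd_s <- radius_d * rs / radius_mean
  if (defect$mode == "abrupt") {
    pieces <- list(
      straight_span(omega, l1, radius_d, radius_mean, E, h, fluid, poisson),
      lump_piece(r_nl[1]),
      straight_span(omega, defect$length, rd_s, rs, E, h, fluid, poisson),
      lump_piece(r_nl[2]),
      straight_span(omega, l3, radius_d, radius_mean, E, h, fluid, poisson)
    )
    pieces <- Filter(function(p) p$type == "lump" || p$len > 0, pieces)
    pieces_to_matrices(pieces)
  } else {
    # conical reduction and expansion over each half of the defect length,
    # one lumped loss carrying the total CL in the throat middle
    lc <- defect$length / 2
    n_seg <- taper_segment_count(lc, radius_d, rd_s, E, h, fluid, omega_max,
      poisson
    )
    cone_in <- lapply(seq_len(n_seg), function(i) {
      x <- (i - 0.5) / n_seg
      rd <- radius_d + x * (rd_s - radius_d)
      rm <- radius_mean + x * (rs - radius_mean)
      straight_span(omega, lc / n_seg, rd, rm, E, h, fluid, poisson,
        theta = atan((radius_d - rd_s) / lc)
      )
    })
    cone_out <- lapply(seq_len(n_seg), function(i) {
      x <- (i - 0.5) / n_seg
      rd <- rd_s + x * (radius_d - rd_s)
      rm <- rs + x * (radius_mean - rs)
      straight_span(omega, lc / n_seg, rd, rm, E, h, fluid, poisson,
        theta = atan((radius_d - rd_s) / lc)
      )
    })
    r_tot <- sum(defect_loss_resistances(
      pw_defect(defect$kind,
        area = as_, length = defect$length,
        cl_in = defect$cl_in, cl_out = defect$cl_out
      ),
      area0, q0, fluid$density, n
    ))
    pieces <- c(
      if (l1 > 0) list(straight_span(omega, l1, radius_d, radius_mean, E, h,
        fluid, poisson)),
      cone_in,
      list(lump_piece(r_tot)),
      cone_out,
      if (l3 > 0) list(straight_span(omega, l3, radius_d, radius_mean, E, h,
        fluid, poisson))
    )
    pieces_to_matrices(pieces)
  }
}

# Dispatch: element descriptor row -> per-frequency matrices.
# `elem` is the internal descriptor list created by pw_network().
elem_matrices <- function(elem, fluid, omega, omega_max, q0 = 0, n = 0) {
  if (!is.null(elem$defect)) {
    defect_vessel(omega, elem$length, elem$radius_d, elem$radius_mean,
      elem$modulus, elem$thickness, fluid, elem$defect,
      q0 = q0, n = n, omega_max = omega_max, poisson = elem$poisson
    )
  } else if (!is.null(elem$taper)) {
    n_seg <- taper_segment_count(
      elem$length, elem$taper$radius_d_in, elem$taper$radius_d_out,
      elem$modulus, elem$thickness, fluid, omega_max, elem$poisson
    )
    tapered_vessel(omega, elem$length,
      elem$taper$radius_d_in, elem$taper$radius_d_out,
      elem$modulus, elem$thickness, fluid, n_seg, elem$poisson,
      radius_mean_in = elem$taper$radius_mean_in %||% elem$taper$radius_d_in,
      radius_mean_out = elem$taper$radius_mean_out %||% elem$taper$radius_d_out
    )
  } else {
    uniform_vessel(omega, elem$length, elem$radius_d, elem$radius_mean,
      elem$modulus, elem$thickness, fluid, elem$poisson
    )
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
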