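# Two-port element machinery.
#
# Every vessel-like element is represented per frequency by
#   * a backward transfer matrix T: (p, q) at port 2 -> (p, q) at port 1,
#   * a scattering matrix S: incident wave amplitudes (p1+, p2+) ->
#     outgoing amplitudes (p1-, p2-),
#   * the characteristic impedances z0 = (Z_port1, Z_port2) defining the
#     wave decomposition p = p+ + p-, q1 = (p1+ - p1-)/Z1,
#     q2 = (p2- - p2+)/Z2 (flow positive in the 1 -> 2 direction),
#   * a source vector (zero for all passive elements built here).
#
# At 0 Hz the transfer matrix is the Poiseuille resistive ladder and the wave
# decomposition uses the element's inviscid characteristic impedance as the
# reference; any consistent positive reference yields the same physical
# (p, q) solution.

#' Convert a transfer matrix to a scattering matrix
#'
#' Uses the port wave relations `p = p+ + p-`, `q1 = (p1+ - p1-)/Z1`,
#' `q2 = (p2- - p2+)/Z2` (flow positive from port 1 to port 2) to convert the
#' backward transfer matrix `T` (port-2 state to port-1 state) into the
#' scattering matrix mapping incident to outgoing wave amplitudes.
#'
#' @param T_mat 2x2 complex transfer matrix.
#' @param z1,z2 Characteristic impedances at ports 1 and 2 (Pa s/m^3).
#' @return 2x2 complex scattering matrix.
#' @seealso [scattering_to_transfer()]
#' @export
transfer_to_scattering <- function(T_mat, z1, z2) {
  A <- T_mat[1, 1]; B <- T_mat[1, 2]
  C <- T_mat[2, 1]; D <- T_mat[2, 2]
  m_out <- matrix(c(
    1, -(A + B / z2),
    -1 / z1, -(C + D / z2)
  ), 2, 2, byrow = TRUE)
  m_in <- matrix(c(
    -1, A - B / z2,
    -1 / z1, C - D / z2
  ), 2, 2, byrow = TRUE)
  d <- m_out[1, 1] * m_out[2, 2] - m_out[1, 2] * m_out[2, 1]
  if (Mod(d) < 1e-290) {
    stop("transfer_to_scattering(): singular port-wave conversion matrix",
      call. = FALSE
    )
  }
  solve(m_out, m_in)
}

#' Convert a scattering matrix to a transfer matrix
#'
#' Inverse of [transfer_to_scattering()]: reconstructs the backward transfer
#' matrix from the scattering matrix and the port impedances by exciting the
#' two-port with each incident wave in turn and matching port states.
#'
#' @inheritParams transfer_to_scattering
#' @param S_mat 2x2 complex scattering matrix.
#' @return 2x2 complex transfer matrix (det = 1 for reciprocal elements).
#' @export
scattering_to_transfer <- function(S_mat, z1, z2) {
  # excitation 1: (p1+, p2+) = (1, 0); excitation 2: (0, 1)
  out <- S_mat %*% diag(2)
  state1 <- matrix(c(
    1 + out[1, 1], S_mat[1, 2],
    (1 - out[1, 1]) / z1, -S_mat[1, 2] / z1
  ), 2, 2, byrow = TRUE)
  state2 <- matrix(c(
    out[2, 1], 1 + S_mat[2, 2],
    out[2, 1] / z2, (S_mat[2, 2] - 1) / z2
  ), 2, 2, byrow = TRUE)
  d <- state2[1, 1] * state2[2, 2] - state2[1, 2] * state2[2, 1]
  if (Mod(d) < 1e-290) {
    stop("scattering_to_transfer(): singular port-2 state matrix",
      call. = FALSE
    )
  }
  state1 %*% solve(state2)
}

#' Cascade transfer matrices
#'
#' Multiplies the backward transfer matrices of elements connected in series,
#' inlet-to-outlet order: `T = T1 T2 ... TN`.
#'
#' @param T_list Non-empty list of 2x2 complex matrices.
#' @return The 2x2 product matrix.
#' @export
cascade <- function(T_list) {
  if (length(T_list) == 0) {
    stop("cascade(): empty transfer-matrix list", call. = FALSE)
  }
  Reduce(`%*%`, T_list)
}

#' Lumped nonlinear loss two-port
#'
#' Series pressure-drop element `T = [[1, Rnl], [0, 1]]`: flow is continuous
#' and the pressure drops by `Rnl * q` across the (zero-length) jump.
#'
#' @param r_nl Resistance (Pa s/m^3), >= 0 (0 gives the identity).
#' @return 2x2 transfer matrix.
#' @export
nonlinear_twoport <- function(r_nl) {
  stopifnot(Re(r_nl) >= 0)
  matrix(c(1, r_nl, 0, 1), 2, 2, byrow = TRUE)
}

#' Quasi-steady Borda-Carnot loss resistance
#'
#' Stagnation-pressure loss resistance at a sudden area change,
#' \eqn{R_{nl} = \delta_n \rho_0 |q_0| C_L (1-\sigma)^2 / (2 A_{ref}^2)},
#' where `q0` is the steady (0 Hz) flow through the constriction, `A_ref` the
#' reference (smaller) lumen area and `sigma` the area contraction ratio.
#' The harmonic factor \eqn{\delta_n} is 1 for the steady component (n = 0)
#' and exactly 2 for every oscillating harmonic, from linearizing the squared
#' instantaneous flow about its dominant steady part.
#'
#' @param q0 Steady volume flow (m^3/s); its magnitude is used, losses oppose
#'   flow in either direction.
#' @param cl Loss coefficient (dimensionless), from handbooks or the built-in
#'   stenosis defaults.
#' @param area_ref Reference cross-sectional area (m^2): the stenosis lumen
#'   area for a stenosis, the parent-vessel area for an aneurysm or a
#'   junction branch.
#' @param sigma Area contraction ratio (dimensionless): `As/A0` for a
#'   stenosis, `A0/As` for an aneurysm, 0 when there is no area change.
#' @param rho Fluid density (kg/m^3).
#' @param n Harmonic index (0 = steady).
#' @return Resistance (Pa s/m^3).
#' @export
borda_carnot_resistance <- function(q0, cl, area_ref, sigma, rho, n = 0) {
  stopifnot(area_ref > 0, is.finite(q0))
  delta <- if (n == 0) 1 else 2
  delta * rho * abs(q0) * cl * (1 - sigma)^2 / (2 * area_ref^2)
}

#' Three-element Windkessel impedance
#'
#' \eqn{Z_{wk}(\omega) = Z_c + (i\omega C + 1/R)^{-1}} under the package's
#' `exp(+i omega t)` harmonic convention: the capacitor is open at DC
#' (`Zwk(0) = Zc + R = Rt`) and shorts at high frequency (`Zwk -> Zc`).
#'
#' @param zc Characteristic (proximal) resistance (Pa s/m^3).
#' @param r Peripheral resistance (Pa s/m^3), `R = Rt - Zc`.
#' @param c_wk Vascular-bed compliance (m^3/Pa).
#' @param omega Angular frequency (rad/s), >= 0.
#' @return Complex impedance (Pa s/m^3).
#' @export
wk3_impedance <- function(zc, r, c_wk, omega) {
  stopifnot(r > 0, c_wk > 0)
  if (omega == 0) {
    zc + r + 0i
  } else {
    zc + 1 / (1i * omega * c_wk + 1 / r)
  }
}

#' Windkessel reflection coefficient
#'
#' \eqn{R_{wk} = (Z_{wk} - Z_0)/(Z_{wk} + Z_0)} for a one-port termination
#' seen from a vessel of characteristic impedance `z0`. With `Zc = Re(Z0)`
#' the boundary becomes reflection-free at high frequency.
#'
#' @param zwk Windkessel impedance at the frequency of interest.
#' @param z0 Characteristic impedance of the terminal vessel segment.
#' @return Complex reflection coefficient.
#' @export
wk3_reflection <- function(zwk, z0) {
  if (Mod(zwk + z0) < 1e-290) {
    stop("wk3_reflection(): Zwk + Z0 = 0 is non-physical", call. = FALSE)
  }
  (zwk - z0) / (zwk + z0)
}

#' Active heart source one-port
#'
#' The heart is an active one-port node `p+ = Rs p- + p+s` with
#' \eqn{R_s = (Z_s - Z_0)/(Z_s + Z_0)} and source amplitude
#' \eqn{\hat p^{+s} = Z_s Z_0 \hat q_s/(Z_s + Z_0)}. With a very high source
#' impedance (`zs = 1e30` by default elsewhere) this prescribes the volume
#' flow `qs` exactly (`Rs -> 1`, constant-flow source).
#'
#' @param zs Source impedance (Pa s/m^3).
#' @param z0 Characteristic impedance of the attached vessel port.
#' @param qs Prescribed volume-flow amplitude at this frequency (m^3/s).
#' @return List with reflection coefficient `rs` and source amplitude `ps`.
#' @export
source_oneport <- function(zs, z0, qs) {
  stopifnot(Re(zs) > 0)
  list(
    rs = (zs - z0) / (zs + z0),
    ps = zs * z0 * qs / (zs + z0)
  )
}

# ---- per-frequency segment pieces ------------------------------------------

# A "span" is a straight homogeneous piece with positive length; a "lump" is
# a zero-length series resistance. Both carry enough data to form full or
# partial transfer matrices at the frequency they were built for.
span_piece <- function(len, kappa, z0, r_per_len, z_ref) {
  list(type = "span", len = len, kappa = kappa, z0 = z0,
       r_per_len = r_per_len, z_ref = z_ref)
}

lump_piece <- function(r) list(type = "lump", r = r)

# Transfer matrix of a piece over length x (ignored for lumps). kappa = NA
# marks the DC case (resistive ladder).
piece_T <- function(piece, x = NULL) {
  if (piece$type == "lump") {
    return(nonlinear_twoport(piece$r))
  }
  if (is.null(x)) x <- piece$len
  if (is.na(piece$kappa[1])) {
    matrix(c(1, piece$r_per_len * x, 0, 1), 2, 2, byrow = TRUE)
  } else {
    kl <- piece$kappa * x
    matrix(c(
      cos(kl), 1i * piece$z0 * sin(kl),
      1i * sin(kl) / piece$z0, cos(kl)
    ), 2, 2, byrow = TRUE)
  }
}

# Apply the inverse of a 2x2 matrix to a state vector explicitly (the
# transfer matrices here are unimodular but can be badly scaled, which makes
# solve()'s rcond guard fire spuriously).
solve2 <- function(T_mat, v) {
  d <- T_mat[1, 1] * T_mat[2, 2] - T_mat[1, 2] * T_mat[2, 1]
  if (Mod(d) < 1e-290) stop("singular 2x2 transfer matrix", call. = FALSE)
  c(
    (T_mat[2, 2] * v[1] - T_mat[1, 2] * v[2]) / d,
    (-T_mat[2, 1] * v[1] + T_mat[1, 1] * v[2]) / d
  )
}

# Port characteristic impedance of a span at its build frequency (reference
# impedance at DC).
piece_z0 <- function(piece) {
  if (is.na(piece$kappa[1])) piece$z_ref else piece$z0
}

# Build the per-frequency representation of an element from its piece list.
pieces_to_matrices <- function(pieces) {
  spans <- Filter(function(p) p$type == "span", pieces)
  stopifnot(length(spans) >= 1)
  T_mat <- cascade(lapply(pieces, piece_T))
  z1 <- piece_z0(spans[[1]])
  z2 <- piece_z0(spans[[length(spans)]])
  list(
    T = T_mat,
    S = transfer_to_scattering(T_mat, z1, z2),
    z0 = c(z1, z2),
    src = c(0 + 0i, 0 + 0i),
    pieces = pieces
  )
}
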