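#' Blood (fluid) properties
#'
#' Bundles the fluid constants used throughout the wave model. Setting
#' `viscosity = 0` selects the inviscid (lossless) limit everywhere.
#'
#' @param density Fluid density \eqn{\rho_0} (kg/m^3).
#' @param viscosity Dynamic viscosity \eqn{\mu} (Pa s).
#'
#' @return A list with `density`, `viscosity` and the derived kinematic
#'   viscosity `nu` (m^2/s), of class `pw_fluid`.
#' @examples
#' pw_fluid() # default: blood
#' @export
pw_fluid <- function(density = 1060, viscosity = 4e-3) {
  stopifnot(density > 0, viscosity >= 0)
  structure(
    list(density = density, viscosity = viscosity, nu = viscosity / density),
    class = "pw_fluid"
  )
}

#' Womersley number
#'
#' \eqn{\alpha = R \sqrt{\omega/\nu}}: the ratio of oscillatory inertia to
#' viscous forces that governs the pulsatile velocity profile. A complex
#' kinematic viscosity is accepted as a hook for Maxwellian fluids.
#'
#' @param radius Lumen radius (m).
#' @param omega Angular frequency (rad/s), must be positive (the 0 Hz limit
#'   is handled by the dedicated Poiseuille path, see [dc_resistance()]).
#' @param nu Kinematic viscosity (m^2/s), possibly complex.
#'
#' @return Dimensionless Womersley number (complex if `nu` is complex).
#' @export
womersley_alpha <- function(radius, omega, nu) {
  stopifnot(radius > 0)
  if (omega <= 0) {
    stop("womersley_alpha(): omega must be > 0; use the DC path at 0 Hz",
      call. = FALSE
    )
  }
  if (is.numeric(nu) && nu <= 0) {
    stop("womersley_alpha(): invalid fluid, nu must be positive", call. = FALSE)
  }
  radius * sqrt(omega / nu)
}

#' Womersley friction function F
#'
#' \eqn{F(\alpha) = 2 J_1(\alpha i^{3/2}) / (\alpha i^{3/2} J_0(\alpha i^{3/2}))}
#' with \eqn{i^{3/2} = e^{i 3\pi/4}} (principal branch). F encodes the
#' deviation of oscillatory viscous flow from plug flow: F -> 1 as alpha -> 0
#' (Poiseuille regime) and F -> 0 as alpha -> infinity (inviscid plug flow).
#'
#' @param alpha Womersley number (dimensionless, possibly complex), nonzero.
#' @return Complex F value.
#' @export
womersley_F <- function(alpha) {
  stopifnot(Mod(alpha) > 0)
  z <- alpha * exp(1i * 3 * pi / 4)
  2 * bessel_j1_over_j0(z) / z
}

#' Pulse wave speed of an elastic vessel
#'
#' Moens-Korteweg-type speed \eqn{c_0 = \sqrt{E h / (2 (1-\nu^2) \rho_0 R)}}
#' for a thin elastic wall, evaluated with the effective radius
#' \eqn{R_d^2/R_0} (diastolic radius squared over time-averaged radius). For
#' tapered segments the speed is corrected by \eqn{\cos\theta/\cos(\theta/2)}
#' where `theta` is the local tangent (taper) angle.
#'
#' @param E Young's modulus of the wall (Pa); may be complex (viscoelastic
#'   hook, no constitutive model supplied).
#' @param h Wall thickness (m).
#' @param rho Fluid density (kg/m^3).
#' @param radius_d Diastolic radius \eqn{R_d} (m).
#' @param radius_mean Time-averaged radius \eqn{R_0} (m); defaults to
#'   `radius_d`.
#' @param poisson Wall Poisson ratio, default 0.5 (incompressible wall).
#' @param theta Taper angle (rad), 0 for a uniform vessel.
#'
#' @return Wave speed (m/s), complex if `E` is complex.
#' @export
wave_speed <- function(E, h, rho, radius_d, radius_mean = radius_d,
                       poisson = 0.5, theta = 0) {
  stopifnot(h > 0, rho > 0, radius_d > 0, radius_mean > 0,
            poisson >= 0, poisson < 1, Re(E) > 0)
  r_eff <- radius_d^2 / radius_mean
  c0 <- sqrt(E * h / (2 * (1 - poisson^2) * rho * r_eff))
  if (theta != 0) c0 <- c0 * cos(theta) / cos(theta / 2)
  c0
}

#' Complex wave number
#'
#' \eqn{\kappa = (\omega/c_0) / \sqrt{1 - F}}, with the branch fixed so that
#' the forward wave `exp(-i kappa x)` decays (Re kappa > 0, Im kappa <= 0
#' under the package's `exp(+i omega t)` synthesis convention). In the
#' inviscid limit F = 0 this reduces to the real wave number omega/c0.
#'
#' @param omega Angular frequency (rad/s), > 0.
#' @param c0 Wave speed (m/s).
#' @param F_visc Womersley friction function value at this frequency.
#' @return Complex wave number (1/m).
#' @export
wave_number <- function(omega, c0, F_visc) {
  stopifnot(omega > 0)
  if (Mod(1 - F_visc) < 1e-14) {
    stop("wave_number(): F = 1 (alpha -> 0); use the DC path", call. = FALSE)
  }
  k <- (omega / c0) / sqrt(1 - F_visc)
  if (Re(k) < 0) k <- -k
  if (Im(k) > 1e-12 * Mod(k)) {
    stop("wave_number(): branch violation, forward wave would amplify",
      call. = FALSE
    )
  }
  k
}

#' Characteristic impedance of a vessel segment
#'
#' \eqn{Z_0 = \rho_0 c_0 / (\pi R^2 \sqrt{1 - F})}, the complex ratio of
#' pressure to volume flow for a single travelling wave, with the square-root
#' branch tied to [wave_number()] so that \eqn{\hat p^\pm = \pm Z_0 \hat
#' q^\pm} holds for decaying free waves. The lumen radius is the
#' time-averaged radius \eqn{R_0}.
#'
#' @param rho Fluid density (kg/m^3).
#' @param c0 Wave speed (m/s).
#' @param radius Lumen radius (m), time-averaged.
#' @param F_visc Womersley friction function value.
#' @return Complex characteristic impedance (Pa s/m^3), Re(Z0) > 0.
#' @export
char_impedance <- function(rho, c0, radius, F_visc) {
  stopifnot(rho > 0, radius > 0)
  if (Mod(1 - F_visc) < 1e-14) {
    stop("char_impedance(): F = 1 (alpha -> 0); use the DC path",
      call. = FALSE
    )
  }
  rho * c0 / (pi * radius^2 * sqrt(1 - F_visc))
}

#' Poiseuille (0 Hz) viscous resistance
#'
#' Hagen-Poiseuille resistance \eqn{8 \mu L / (\pi R^4)} of a straight
#' segment, used as the steady-flow limit of the vessel transfer matrix.
#'
#' @param mu Dynamic viscosity (Pa s).
#' @param L Segment length (m).
#' @param radius Lumen radius (m).
#' @return Resistance (Pa s/m^3).
#' @export
dc_resistance <- function(mu, L, radius) {
  stopifnot(radius > 0, L >= 0, mu >= 0)
  8 * mu * L / (pi * radius^4)
}

#' Update the time-averaged radius from the steady pressure
#'
#' With the diastolic state taken as stress-free, the time-averaged radius is
#' \eqn{R_0 = R_d + (\hat p_0 - p_d)/K} with wall stiffness
#' \eqn{K = E h / ((1-\nu^2) R_d^2)}. Used by the optional outer iteration of
#' the network solver.
#'
#' @param radius_d Diastolic radius (m).
#' @param p0 Time-averaged (0 Hz) pressure (Pa).
#' @param pd Diastolic pressure (Pa).
#' @param E,h Wall Young's modulus (Pa) and thickness (m).
#' @param poisson Wall Poisson ratio, default 0.5.
#' @return Updated mean radius (m).
#' @export
mean_radius_update <- function(radius_d, p0, pd, E, h, poisson = 0.5) {
  K <- Re(E) * h / ((1 - poisson^2) * radius_d^2)
  stopifnot(K > 0)
  r0 <- radius_d + (p0 - pd) / K
  if (r0 <= 0) {
    stop("mean_radius_update(): non-physical negative radius", call. = FALSE)
  }
  r0
}

# All per-frequency wave quantities for a straight segment.
# Returns list(alpha, F, c0, kappa, z0). mu = 0 gives the inviscid limit
# exactly (F = 0). Only valid for omega > 0.
wave_state <- function(omega, radius_d, radius_mean, E, h, fluid,
                       poisson = 0.5, theta = 0) {
  c0 <- wave_speed(E, h, fluid$density, radius_d, radius_mean,
    poisson = poisson, theta = theta
  )
  if (fluid$viscosity == 0) {
    alpha <- Inf
    Fv <- 0 + 0i
  } else {
    alpha <- womersley_alpha(radius_mean, omega, fluid$nu)
    Fv <- womersley_F(alpha)
  }
  kappa <- wave_number(omega, c0, Fv)
  z0 <- char_impedance(fluid$density, c0, radius_mean, Fv)
  list(alpha = alpha, F = Fv, c0 = c0, kappa = kappa, z0 = z0)
}

# Inviscid (real) characteristic impedance, also used as the DC reference
# impedance for wave decomposition at 0 Hz.
inviscid_impedance <- function(radius_d, radius_mean, E, h, fluid,
                               poisson = 0.5) {
  c0 <- wave_speed(E, h, fluid$density, radius_d, radius_mean,
    poisson = poisson
  )
  Re(fluid$density * c0 / (pi * radius_mean^2))
}
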