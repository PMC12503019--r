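# Two-port element construction: vessels, conversions, cascades, defects,
# boundary one-ports.

uv <- function(omega, L = 0.1, rd = 6e-3, fluid = blood) {
  pulsenet:::uniform_vessel(omega, L, rd, rd, 700e3, 0.72e-3, fluid)
}

test_that("uniform vessel: scattering form, zero length, lossless modulus", {
  omega <- 2 * pi * 1.2
  em <- uv(omega)
  # no reflection, transmission exp(-i kappa L) on both paths
  expect_equal(em$S[1, 1], 0 + 0i, tolerance = 1e-12)
  expect_equal(em$S[2, 2], 0 + 0i, tolerance = 1e-12)
  expect_equal(em$S[2, 1], em$S[1, 2], tolerance = 1e-14)
  expect_lt(Mod(em$S[2, 1]), 1) # viscous attenuation
  # lossless: |T21| = 1
  em0 <- uv(omega, fluid = inviscid)
  expect_equal(Mod(em0$S[2, 1]), 1, tolerance = 1e-12)
  # L -> 0: S -> antidiagonal exchange, T -> identity (off-diagonal T
  # entries scale with Z0, compare them on that scale)
  tiny <- uv(omega, L = 1e-12)
  expect_equal(tiny$S, matrix(c(0, 1, 1, 0), 2, 2) + 0i, tolerance = 1e-9)
  expect_lt(Mod(tiny$T[1, 1] - 1), 1e-10)
  expect_lt(Mod(tiny$T[2, 2] - 1), 1e-10)
  expect_lt(Mod(tiny$T[1, 2]) / Mod(tiny$z0[1]), 1e-10)
  expect_lt(Mod(tiny$T[2, 1]) * Mod(tiny$z0[1]), 1e-10)
})

test_that("det T = 1 for every element type at every frequency", {
  det2 <- function(m) m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  for (f in c(0, 1, 5, 15)) {
    w <- 2 * pi * f
    expect_lt(Mod(det2(uv(w)$T) - 1), 1e-10)
    tp <- pulsenet:::tapered_vessel(w, 0.1, 8e-3, 6.4e-3, 5e5, 8e-4, blood, 9)
    expect_lt(Mod(det2(tp$T) - 1), 1e-10)
    df <- pulsenet:::defect_vessel(
      w, 0.126, 3e-3, 3e-3, 7e5, 3e-4, blood,
      pw_defect("stenosis", severity = 75, length = 48e-3), q0 = 6e-6,
      n = round(f)
    )
    expect_lt(Mod(det2(df$T) - 1), 1e-10)
  }
  expect_lt(Mod(det2(nonlinear_twoport(5e7)) - 1), 1e-14)
})

test_that("lossless scattering matrices are unitary", {
  for (f in c(0.7, 3, 11)) {
    em <- uv(2 * pi * f, fluid = inviscid)
    U <- Conj(t(em$S)) %*% em$S
    expect_lt(max(Mod(U - diag(2))), 1e-10)
  }
})

test_that("transfer <-> scattering round trip on randomized two-ports", {
  set.seed(42)
  for (i in 1:20) {
    # random passive-ish two-port with unit determinant and distinct ports
    a <- complex(real = runif(1, 0.5, 1.5), imaginary = runif(1, -0.3, 0.3))
    b <- complex(real = runif(1, -0.5, 0.5), imaginary = runif(1, -0.5, 0.5))
    cc <- complex(real = runif(1, -0.5, 0.5), imaginary = runif(1, -0.5, 0.5))
    d <- (1 + b * cc) / a # det = 1
    T0 <- matrix(c(a, b * 1e8, cc * 1e-8, d), 2, 2, byrow = TRUE)
    z1 <- complex(real = runif(1, 5e7, 5e8), imaginary = runif(1, -1e7, 1e7))
    z2 <- complex(real = runif(1, 5e7, 5e8), imaginary = runif(1, -1e7, 1e7))
    S <- transfer_to_scattering(T0, z1, z2)
    T1 <- scattering_to_transfer(S, z1, z2)
    expect_lt(max(Mod(T1 - T0) / pmax(Mod(T0), 1e-8)), 1e-11)
  }
  # uniform vessel: converting the analytic T reproduces the analytic S
  w <- 2 * pi * 2
  ws <- pulsenet:::wave_state(w, 6e-3, 6e-3, 700e3, 0.72e-3, blood)
  kl <- ws$kappa * 0.1
  T_analytic <- matrix(c(
    cos(kl), 1i * ws$z0 * sin(kl),
    1i * sin(kl) / ws$z0, cos(kl)
  ), 2, 2, byrow = TRUE)
  S <- transfer_to_scattering(T_analytic, ws$z0, ws$z0)
  e <- exp(-1i * kl)
  expect_equal(S, matrix(c(0, e, e, 0), 2, 2) + 0i, tolerance = 1e-12)
})

test_that("cascade: additivity, singleton, determinant", {
  w <- 2 * pi * 3
  half <- uv(w, L = 0.05)$T
  full <- uv(w, L = 0.1)$T
  expect_lt(max(Mod(cascade(list(half, half)) - full) /
    pmax(Mod(full), 1)), 1e-12)
  expect_identical(cascade(list(full)), full)
  expect_error(cascade(list()), "empty")
})

test_that("tapered vessel: constant profile equals uniform, halving rule", {
  w <- 2 * pi * 10
  for (n_seg in c(3, 9, 24)) {
    tc <- pulsenet:::tapered_vessel(w, 0.1, 6e-3, 6e-3, 5e5, 8e-4, blood,
      n_seg
    )
    uu <- uv(w, L = 0.1, rd = 6e-3)
    uu <- pulsenet:::uniform_vessel(w, 0.1, 6e-3, 6e-3, 5e5, 8e-4, blood)
    expect_lt(max(Mod(tc$T - uu$T) / pmax(Mod(uu$T), 1)), 1e-12)
  }
  # 20% linear taper: halving the segment length moves T21 by < 0.1%
  t1 <- pulsenet:::tapered_vessel(w, 0.1, 8e-3, 6.4e-3, 5e5, 8e-4, blood, 20)
  t2 <- pulsenet:::tapered_vessel(w, 0.1, 8e-3, 6.4e-3, 5e5, 8e-4, blood, 40)
  expect_lt(Mod(t1$S[2, 1] - t2$S[2, 1]) / Mod(t2$S[2, 1]), 1e-3)
  expect_error(
    pulsenet:::tapered_vessel(w, 0.1, -1e-3, 6e-3, 5e5, 8e-4, blood, 5),
    "radius"
  )
})

test_that("borda_carnot_resistance: frozen value, harmonic doubling, zero", {
  A0 <- pi * (3e-3)^2
  As <- 0.25 * A0
  # 75% stenosis, CL = 1, q0 = 6 mL/s (direct arithmetic oracle, frozen)
  expect_equal(borda_carnot_resistance(6e-6, 1, As, 0.25, 1060, 0),
    3.5797e7,
    tolerance = 1e-4
  )
  expect_identical(borda_carnot_resistance(0, 1, As, 0.25, 1060, 0), 0)
  # delta_n rule: AC resistance exactly twice the DC one
  expect_identical(
    borda_carnot_resistance(6e-6, 1, As, 0.25, 1060, 1),
    2 * borda_carnot_resistance(6e-6, 1, As, 0.25, 1060, 0)
  )
  expect_identical(
    borda_carnot_resistance(6e-6, 1, As, 0.25, 1060, 7),
    borda_carnot_resistance(6e-6, 1, As, 0.25, 1060, 1)
  )
  # sign of q0 irrelevant
  expect_identical(
    borda_carnot_resistance(-6e-6, 1, As, 0.25, 1060, 0),
    borda_carnot_resistance(6e-6, 1, As, 0.25, 1060, 0)
  )
})

test_that("nonlinear twoport: identity at zero, series addition", {
  expect_equal(nonlinear_twoport(0), diag(2))
  Ta <- nonlinear_twoport(3e7)
  Tb <- nonlinear_twoport(4e7)
  expect_equal(Ta %*% Tb, nonlinear_twoport(7e7), tolerance = 1e-14)
})

test_that("defect vessel: healthy limit and DC circuit algebra", {
  w <- 2 * pi * 2
  # severity ~ 0 and no losses: equals the uniform vessel
  d0 <- pw_defect("stenosis",
    area = pi * (3e-3)^2 * (1 - 1e-12),
    length = 48e-3, cl_in = 0, cl_out = 0
  )
  em_d <- pulsenet:::defect_vessel(w, 0.126, 3e-3, 3e-3, 7e5, 3e-4, blood,
    d0,
    q0 = 0
  )
  em_u <- pulsenet:::uniform_vessel(w, 0.126, 3e-3, 3e-3, 7e5, 3e-4, blood)
  expect_lt(max(Mod(em_d$T - em_u$T) / pmax(Mod(em_u$T), 1)), 1e-6)
  # DC pressure drop = (viscous resistances + both loss lumps) * q0
  q0 <- 6e-6
  def <- pw_defect("stenosis", severity = 75, length = 48e-3)
  em_dc <- pulsenet:::defect_vessel(0, 0.126, 3e-3, 3e-3, 7e5, 3e-4, blood,
    def,
    q0 = q0, n = 0
  )
  rs <- sqrt(0.25) * 3e-3
  r_visc <- dc_resistance(4e-3, 0.126 - 48e-3, 3e-3) +
    dc_resistance(4e-3, 48e-3, rs)
  r_nl <- sum(pulsenet:::defect_loss_resistances(def, pi * (3e-3)^2,
    q0, 1060,
    n = 0
  ))
  expect_equal(Re(em_dc$T[1, 2]), r_visc + r_nl, tolerance = 1e-12)
  expect_error(
    pulsenet:::defect_vessel(w, 0.04, 3e-3, 3e-3, 7e5, 3e-4, blood, def),
    "smaller than the vessel"
  )
})

test_that("conical defect mode builds a valid unimodular element", {
  det2 <- function(m) m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  def <- pw_defect("stenosis", severity = 50, length = 48e-3,
    mode = "conical"
  )
  for (f in c(0, 1, 8)) {
    em <- pulsenet:::defect_vessel(2 * pi * f, 0.126, 3e-3, 3e-3, 7e5, 3e-4,
      blood, def,
      q0 = 6e-6, n = round(f), omega_max = 2 * pi * 15
    )
    expect_lt(Mod(det2(em$T) - 1), 1e-10)
  }
})

test_that("aneurysm defect reverses the loss coefficients", {
  d <- pw_defect("aneurysm", area = 2 * pi * (3e-3)^2, length = 0.02)
  expect_equal(d$cl_in, 1)
  expect_equal(d$cl_out, 0.52)
  rr <- pulsenet:::defect_loss_resistances(d, pi * (3e-3)^2, 6e-6, 1060)
  expect_gt(rr[1], rr[2]) # inlet (expansion) loss dominates
})

test_that("WK3 impedance limits and tabulated DC value", {
  zc <- 6.1823e7
  r <- 3.1013e9
  c_wk <- 3.6664e-10
  expect_identical(wk3_impedance(zc, r, c_wk, 0), zc + r + 0i)
  expect_lt(Mod(wk3_impedance(zc, r, c_wk, 2 * pi * 1e6) - zc) / zc, 1e-4)
  # iliac termination: Zwk(0) = 6.1823e7 + 3.1013e9 Pa s/m^3
  expect_equal(Re(wk3_impedance(zc, r, c_wk, 0)), 3.163123e9,
    tolerance = 1e-6
  )
  # reflection-free at high frequency when Zc matches Z0
  z0 <- zc
  expect_lt(Mod(wk3_reflection(wk3_impedance(zc, r, c_wk, 2 * pi * 1e5),
    z0
  )), 1e-3)
})

test_that("source one-port: anechoic, constant-flow and passive limits", {
  z0 <- 1e8 + 5e6i
  expect_equal(source_oneport(z0, z0, 1e-6)$rs, 0 + 0i, tolerance = 1e-15)
  hi <- source_oneport(1e30, z0, 1e-6)
  expect_equal(hi$rs, 1 + 0i, tolerance = 1e-12)
  expect_equal(hi$ps, z0 * 1e-6, tolerance = 1e-12)
  expect_identical(source_oneport(1e30, z0, 0)$ps, 0 + 0i)
})

test_that("prescribed source flow is recovered exactly at the inlet port", {
  net <- single_vessel_net()
  infl <- test_inflow()
  sol <- pw_solve(net, infl)
  sp <- pw_decompose(infl, nh = 15)
  fa <- field_at(sol, "vessel", 0)
  expect_lt(max(Mod(fa$flow - sp$x)) / max(Mod(sp$x)), 1e-12)
})
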