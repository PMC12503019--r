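# Node scattering, assembly, solution, conservation and the nonlinear
# fixed point.

test_that("junction scattering: blocked end, matched pair, symmetric tee", {
  # one port, no source: total reflection
  j1 <- junction_scattering(1e8 + 0i)
  expect_equal(j1$S, matrix(1 + 0i, 1, 1))
  # two equal ports: transparent connection
  j2 <- junction_scattering(c(1e8, 1e8) + 0i)
  expect_equal(j2$S, matrix(c(0, 1, 1, 0), 2, 2) + 0i, tolerance = 1e-14)
  # three equal ports: -1/3 diagonal, 2/3 off-diagonal
  j3 <- junction_scattering(c(1, 1, 1) + 0i)
  expect_equal(j3$S,
    (matrix(2 / 3, 3, 3) - diag(3)) + 0i,
    tolerance = 1e-14, ignore_attr = TRUE
  )
})

test_that("junction scattering satisfies continuity for random multiports", {
  set.seed(11)
  for (trial in 1:10) {
    p <- sample(2:5, 1)
    z <- complex(
      real = runif(p, 5e7, 5e8),
      imaginary = runif(p, -5e7, 5e7)
    )
    qs <- complex(real = rnorm(1), imaginary = rnorm(1)) * 1e-6
    jj <- junction_scattering(z, qs)
    p_in <- complex(real = rnorm(p), imaginary = rnorm(p))
    p_out <- as.vector(jj$S %*% p_in + jj$src)
    press <- p_in + p_out
    expect_lt(max(Mod(press - press[1])), 1e-9 * max(Mod(press)))
    q_into <- (p_in - p_out) / z
    expect_lt(Mod(sum(q_into) + qs), 1e-12 * max(Mod(q_into)))
  }
})

test_that("lossy junction reduces to the ideal one and balances DC flow", {
  z <- c(1e8, 2e8, 3e8) + 0i
  ideal <- junction_scattering(z, 1e-6)
  lossy0 <- lossy_junction_scattering(z, c(0, 0, 0), 1e-6)
  expect_equal(lossy0$S, ideal$S, tolerance = 1e-12)
  expect_equal(lossy0$src, ideal$src, tolerance = 1e-12)
  # with losses: flow balance exact, pressure continuity replaced by drops
  rb <- c(0, 4e7, 6e7)
  lj <- lossy_junction_scattering(z, rb, 0)
  p_in <- c(1, 0.3, -0.2) + 0i
  p_out <- as.vector(lj$S %*% p_in)
  q_into <- (p_in - p_out) / z
  expect_lt(Mod(sum(q_into)), 1e-12 * max(Mod(q_into)))
  p_port <- p_in + p_out
  p_interior <- p_port - rb * q_into
  expect_lt(max(Mod(p_interior - p_interior[1])),
    1e-10 * max(Mod(p_port)))
})

test_that("assembled system has size 2M and solves trivial cases", {
  cs <- pw_case_full_aorta()
  net <- pw_network(cs$elements, cs$nodes, cs$fluid)
  expect_equal(net$M, 20)
  expect_equal(length(net$nodes), 21)
  sol <- pw_solve(net, pw_inflow(preset = "aorta"), nh = 2)
  expect_equal(dim(sol$p_plus), c(40, 3))
  # zero source -> zero field
  zero_inflow <- tibble::tibble(
    time = seq(0, 1, length.out = 65)[1:64],
    flow = rep(0, 64)
  )
  sol0 <- pw_solve(single_vessel_net(), zero_inflow, nh = 4)
  expect_lt(max(Mod(sol0$p_plus)), 1e-200)
})

test_that("anechoic chain transmits the source wave with only decay", {
  # matched source (Zs = Z0) and matched load (Zwk = Z0 at all frequencies):
  # no reflections anywhere, outlet wave = source amplitude times e^{-ikL}
  fl <- inviscid
  L <- 0.1
  rd <- 6e-3
  c0 <- wave_speed(700e3, 0.72e-3, 1060, rd)
  z0 <- 1060 * c0 / (pi * rd^2)
  net <- pw_network(
    elements = tibble::tibble(
      element = "v", from = "src", to = "load",
      length = L, radius_d = rd, thickness = 0.72e-3, modulus = 700e3
    ),
    nodes = tibble::tibble(
      node = c("src", "load"), type = c("source", "windkessel"),
      zc = c(NA, z0), r = c(NA, 1e30), c = c(NA, 1e30),
      zs = c(z0, NA)
    ),
    fluid = fl
  )
  infl <- test_inflow(mean = 1e-6, peak = 5e-6)
  sol <- pw_solve(net, infl, nh = 6)
  sp <- pw_decompose(infl, nh = 6)
  for (k in 2:7) {
    w <- sol$omegas[k]
    kappa <- w / c0
    # matched source: p+ = Zs*Z0*qs/(Zs+Z0) = Z0 qs/2, no returning wave
    expect_lt(Mod(sol$p_minus[1, k]), 1e-10 * Mod(sol$p_plus[1, k]))
    expect_equal(sol$p_plus[1, k], z0 * sp$x[k] / 2, tolerance = 1e-10)
    # outlet outgoing wave: inlet wave propagated over L
    expect_equal(sol$p_minus[2, k],
      sol$p_plus[1, k] * exp(-1i * kappa * L),
      tolerance = 1e-10
    )
  }
})

test_that("single vessel with flow source and WK3 matches the closed form", {
  net <- single_vessel_net()
  infl <- test_inflow()
  sol <- pw_solve(net, infl)
  sp <- pw_decompose(infl, nh = 15)
  zs <- 1e30
  for (k in seq_along(sol$omegas)) {
    w <- sol$omegas[k]
    Tm <- sol$elem_freq[[k]][[1]]$T
    zwk <- wk3_impedance(2.4875e8, 1.8697e9, 1.7529e-10, w)
    zin <- (Tm[1, 1] * zwk + Tm[1, 2]) / (Tm[2, 1] * zwk + Tm[2, 2])
    q_in <- sp$x[k] * zs / (zs + zin)
    p_in_cf <- zin * q_in
    fa <- field_at(sol, "vessel", 0)
    scale <- max(Mod(p_in_cf), 1)
    expect_lt(Mod(fa$pressure[k] - p_in_cf) / scale, 1e-10)
    # outlet state from the transfer relation
    out_cf <- pulsenet:::solve2(Tm, c(p_in_cf, q_in))
    fb <- field_at(sol, "vessel", 1)
    expect_lt(Mod(fb$pressure[k] - out_cf[1]) / scale, 1e-10)
  }
})

test_that("scattering solution matches the nodal-impedance oracle", {
  infl_a <- pw_inflow(preset = "aortic_bifurcation")
  for (jl in c(FALSE, TRUE)) {
    cs <- pw_case_bifurcation(junction_loss = jl)
    net <- pw_network(cs$elements, cs$nodes, cs$fluid)
    expect_lt(oracle_deviation(net, infl_a), 1e-8)
  }
  cs <- pw_case_carotid(75)
  expect_lt(oracle_deviation(
    pw_network(cs$elements, cs$nodes, cs$fluid),
    pw_inflow(preset = "carotid")
  ), 1e-8)
  cs <- pw_case_full_aorta()
  expect_lt(oracle_deviation(
    pw_network(cs$elements, cs$nodes, cs$fluid),
    pw_inflow(preset = "aorta")
  ), 1e-8)
})

test_that("randomized small networks (with loops) match the oracle", {
  infl <- test_inflow(mean = 2e-5, peak = 8e-5)
  for (s in 1:5) {
    net <- random_network(2 + s, seed = 2000 + s, p_loop = 0.6)
    expect_lt(oracle_deviation(net, infl), 1e-8)
  }
})

test_that("conservation: junction residuals and DC mass balance", {
  cs <- pw_case_full_aorta()
  net <- pw_network(cs$elements, cs$nodes, cs$fluid)
  infl <- pw_inflow(preset = "aorta")
  sol <- pw_solve(net, infl)
  res <- junction_residuals(sol)
  expect_lt(res["pressure"], 1e-9)
  expect_lt(res["flow"], 1e-9)
  sp <- pw_decompose(infl, nh = 15)
  expect_lt(dc_mass_balance(sol, Re(sp$x[1])), 1e-10)
  expect_lt(max(sol$resids), 1e-10)
})

test_that("identical iliacs give identical left/right waveforms", {
  res <- pw_run(pw_case_bifurcation(junction_loss = TRUE))
  sol <- res$solution
  wf_l <- pw_waveforms(sol, tibble::tibble(position = "L",
    element = "iliac_L", frac = 0.5), n_time = 128)
  wf_r <- pw_waveforms(sol, tibble::tibble(position = "R",
    element = "iliac_R", frac = 0.5), n_time = 128)
  expect_equal(wf_l$pressure_Pa, wf_r$pressure_Pa, tolerance = 1e-12)
  expect_equal(wf_l$flow_m3s, wf_r$flow_m3s, tolerance = 1e-12)
  # DC flow split is exactly 50/50
  q_l <- Re(field_at(sol, "iliac_L", 0)$flow[1])
  q_r <- Re(field_at(sol, "iliac_R", 0)$flow[1])
  expect_equal(q_l, q_r, tolerance = 1e-12)
})

test_that("nonlinear iteration: trivial count, fast convergence, residual", {
  # no nonlinear elements: exactly one solve
  sol_lin <- pw_solve(single_vessel_net(), test_inflow(), nh = 6)
  expect_equal(sol_lin$iterations, 1L)
  expect_equal(nrow(sol_lin$trace), 1L)
  # 75% stenosis with the carotid preset: fewer than five iterations
  cs <- pw_case_carotid(75)
  net <- pw_network(cs$elements, cs$nodes, cs$fluid)
  sol <- pw_solve(net, pw_inflow(preset = "carotid"))
  expect_lt(sol$iterations, 5)
  expect_true(sol$converged)
  # converged state: dp_n = delta_n Rnl_dc q_n across each lumped loss
  q0 <- sol$q0$defect$carotid
  A0 <- pi * 9e-6
  As <- 0.25 * A0
  for (n in c(0, 1, 4)) {
    st <- pulsenet:::element_interface_states(sol, "carotid", n)
    r_in <- borda_carnot_resistance(q0, 0.52, As, 0.25, 1060, n)
    r_out <- borda_carnot_resistance(q0, 1, As, 0.25, 1060, n)
    dp_in <- st[[2]][1] - st[[3]][1]
    dp_out <- st[[4]][1] - st[[5]][1]
    expect_lt(Mod(dp_in - r_in * st[[2]][2]) / Mod(dp_in), 1e-8)
    expect_lt(Mod(dp_out - r_out * st[[4]][2]) / Mod(dp_out), 1e-8)
  }
  # update norm decreases monotonically across iterations
  upd <- sol$trace$update[-1]
  expect_true(all(diff(upd) <= 0))
})

test_that("field reconstruction: port values and interior continuity", {
  cs <- pw_case_carotid(50)
  net <- pw_network(cs$elements, cs$nodes, cs$fluid)
  sol <- pw_solve(net, pw_inflow(preset = "carotid"))
  # x = 0 and x = L reproduce the port states
  fa <- field_at(sol, "carotid", 0)
  g1 <- 1
  z1 <- sol$elem_freq[[2]][[1]]$z0[1]
  expect_equal(fa$pressure[2],
    sol$p_plus[g1, 2] + sol$p_minus[g1, 2],
    tolerance = 1e-12
  )
  # dual route to the outlet state: cascading partial transfer matrices
  # from port 1 must land on the port-2 wave amplitudes
  for (n in c(0, 2, 9)) {
    k <- n + 1
    fb <- field_at(sol, "carotid", 1)
    z2 <- sol$elem_freq[[k]][[1]]$z0[2]
    p2 <- sol$p_plus[2, k] + sol$p_minus[2, k]
    q2 <- (sol$p_minus[2, k] - sol$p_plus[2, k]) / z2
    expect_lt(Mod(fb$pressure[k] - p2) / Mod(p2), 1e-10)
    expect_lt(Mod(fb$flow[k] - q2) / Mod(q2), 1e-10)
    # at DC the flow is constant along the resistive ladder
    if (n == 0) {
      st <- pulsenet:::element_interface_states(sol, "carotid", 0)
      q <- vapply(st, function(s) s[2], complex(1))
      expect_lt(max(Mod(diff(q))) / max(Mod(q)), 1e-10)
    }
  }
  expect_error(field_at(sol, "carotid", 1.2), "frac")
  expect_error(field_at(sol, "nope", 0.5), "unknown element")
})

test_that("degenerate sourceless network solves to the zero field", {
  net <- pw_network(
    elements = tibble::tibble(
      element = "v", from = "a", to = "b",
      length = 0.1, radius_d = 5e-3, thickness = 5e-4, modulus = 5e5
    ),
    nodes = tibble::tibble(
      node = c("a", "b"), type = "windkessel",
      zc = c(1e8, 1e8), r = c(1e9, 1e9), c = c(1e-10, 1e-10)
    )
  )
  sp <- structure(list(f0 = 1, x = rep(0 + 0i, 7), nh = 6),
    class = "pw_spectrum")
  sol <- pw_solve(net, sp, nh = 6)
  expect_lt(max(Mod(sol$p_plus)), 1e-200)
})

test_that("tidy and glance expose the solved amplitudes and run summary", {
  sol <- pw_solve(single_vessel_net(), test_inflow(), nh = 4)
  td <- tidy(sol)
  expect_equal(nrow(td), 2 * (4 + 1) * 1 * 2 / 2) # element x port x harmonic
  expect_true(all(c("element", "harmonic", "port", "p_plus", "p_minus")
  %in% names(td)))
  gl <- glance(sol)
  expect_equal(gl$iterations, 1L)
  expect_lt(gl$max_residual, 1e-10)
})
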