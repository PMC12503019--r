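# Shared fixtures for the test suite. All numeric reference values marked
# "frozen" were computed with an independent high-precision oracle (50-digit
# Bessel series / direct arithmetic) before the implementation and must not
# be regenerated from the package itself.

blood <- pw_fluid(1060, 4e-3)
inviscid <- pw_fluid(1060, 0)

# Womersley friction function F(alpha) on the i^{3/2} ray; 50-digit series
# oracle, frozen.
F_ORACLE <- tibble::tribble(
  ~alpha, ~re, ~im,
  0.01, 9.9999999979166665e-01, -1.2499999996419272e-05,
  0.1, 9.9999791667285154e-01, -1.2499964192815259e-03,
  0.5, 9.9870032813630916e-01, -3.1194155330521330e-02,
  1, 9.7976720482370461e-01, -1.2152309133572023e-01,
  2, 7.7377696909968152e-01, -3.4489550922498430e-01,
  3, 4.9901029758639770e-01, -3.5996283912248300e-01,
  3.871, 3.6993144380020904e-01, -3.0024824618497392e-01,
  5, 2.8405561057599765e-01, -2.4159801693797425e-01,
  8, 1.7719309765283980e-01, -1.6082371328541012e-01,
  12, 1.1796655164141578e-01, -1.1080580925725550e-01,
  20, 7.0734422583590070e-02, -6.8188681159395581e-02,
  30, 4.7147319294530615e-02, -4.6022806231097176e-02,
  40, 3.5358201538751688e-02, -3.4727579828199219e-02,
  50, 2.8285726342837905e-02, -2.7882857971670505e-02
)

# Single uniform vessel between a constant-flow source and a WK3: the
# stenosed-carotid geometry at severity 0.
single_vessel_net <- function(fluid = blood) {
  pw_network(
    elements = tibble::tibble(
      element = "vessel", from = "inlet", to = "outlet",
      length = 126e-3, radius_d = 3e-3, thickness = 0.3e-3, modulus = 700e3
    ),
    nodes = tibble::tibble(
      node = c("inlet", "outlet"), type = c("source", "windkessel"),
      zc = c(NA, 2.4875e8), r = c(NA, 1.8697e9), c = c(NA, 1.7529e-10),
      zs = c(1e30, NA)
    ),
    fluid = fluid
  )
}

test_inflow <- function(mean = 6e-6, peak = 1.2e-5, fs = 0.35, T = 1) {
  pw_inflow(mean, peak, fs, T)
}

# Max relative deviation between scattering and nodal-oracle pressures.
oracle_deviation <- function(net, inflow, nh = 15) {
  sol <- pw_solve(net, inflow, nh = nh)
  ref <- solve_nodal(net, inflow, nh = nh)
  ps <- nodal_pressures(sol)
  max(Mod(ps[ref$nodes, ] - ref$pressure)) / max(Mod(ref$pressure))
}

# Conservation residuals of a solved network: max pressure-continuity and
# flow-sum residual over all ideal junctions and harmonics (relative).
junction_residuals <- function(sol) {
  net <- sol$network
  dp <- 0
  dq <- 0
  for (nd in net$nodes) {
    if (nd$type != "junction" || !is.null(nd$losses)) next
    cn <- net$conn[[nd$id]]
    for (k in seq_along(sol$omegas)) {
      p <- q <- complex(nrow(cn))
      for (j in seq_len(nrow(cn))) {
        g <- cn$gidx[j]
        z <- sol$elem_freq[[k]][[cn$elem_idx[j]]]$z0[cn$port[j]]
        p[j] <- sol$p_plus[g, k] + sol$p_minus[g, k]
        q[j] <- (sol$p_minus[g, k] - sol$p_plus[g, k]) / z
      }
      pscale <- max(Mod(sol$p_plus[, k] + sol$p_minus[, k]))
      qscale <- max(Mod(q))
      if (pscale > 0) dp <- max(dp, max(Mod(p - p[1])) / pscale)
      if (qscale > 0) dq <- max(dq, Mod(sum(q)) / qscale)
    }
  }
  c(pressure = dp, flow = dq)
}

# DC mass balance: sum of terminal Windkessel outflows vs prescribed inflow.
dc_mass_balance <- function(sol, inflow_dc) {
  net <- sol$network
  total <- 0
  for (nd in net$nodes) {
    if (nd$type != "windkessel") next
    cn <- net$conn[[nd$id]]
    g <- cn$gidx[1]
    z <- sol$elem_freq[[1]][[cn$elem_idx[1]]]$z0[cn$port[1]]
    total <- total + Re((sol$p_minus[g, 1] - sol$p_plus[g, 1]) / z)
  }
  abs(total - inflow_dc) / abs(inflow_dc)
}
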