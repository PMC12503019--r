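# Network graph, per-frequency assembly A p+ = B p-s + q s, nonlinear
# fixed-point iteration and field reconstruction.

#' Build an arterial network
#'
#' Assembles a network object from tidy tables of vessel elements and nodes.
#' Each element is a two-port vessel segment connecting two named nodes; each
#' node is an ideal (or lossy) junction, a three-element Windkessel
#' termination, or an active flow source (heart).
#'
#' @param elements A data frame with one row per vessel element and columns:
#'   `element` (id), `from`, `to` (node ids; the element's positive direction
#'   runs from -> to), `length` (m), `radius_d` (diastolic radius, m),
#'   `radius_mean` (time-averaged radius, m; defaults to `radius_d`),
#'   `thickness` (wall thickness, m), `modulus` (Young's modulus, Pa),
#'   optionally `poisson` (default 0.5), and optional list-columns `defect`
#'   ([pw_defect()] specs) and `taper` (lists with `radius_d_in`,
#'   `radius_d_out`, and optionally `radius_mean_in`, `radius_mean_out`).
#' @param nodes A data frame with one row per node and columns: `node` (id),
#'   `type` (`"junction"`, `"windkessel"` or `"source"`); for Windkessel
#'   nodes `zc`, `r`, `c` (WK3 parameters, SI); for source nodes optionally
#'   `zs` (source impedance, default 1e30 Pa s/m^3); optionally a list-column
#'   `losses` (data frames with columns `element`, `cl`) marking junction
#'   branches that carry Borda-Carnot flow-separation losses.
#' @param fluid A [pw_fluid()] object.
#'
#' @return A `pw_network` object.
#' @examples
#' net <- pw_network(
#'   elements = tibble::tibble(
#'     element = "vessel", from = "inlet", to = "outlet",
#'     length = 0.126, radius_d = 3e-3, thickness = 3e-4, modulus = 7e5
#'   ),
#'   nodes = tibble::tibble(
#'     node = c("inlet", "outlet"), type = c("source", "windkessel"),
#'     zc = c(NA, 2.4875e8), r = c(NA, 1.8697e9), c = c(NA, 1.7529e-10)
#'   )
#' )
#' @export
pw_network <- function(elements, nodes, fluid = pw_fluid()) {
  elements <- tibble::as_tibble(elements)
  nodes <- tibble::as_tibble(nodes)
  stopifnot(
    all(c("element", "from", "to", "length", "radius_d", "thickness",
          "modulus") %in% names(elements)),
    all(c("node", "type") %in% names(nodes))
  )
  if (anyDuplicated(elements$element) || anyDuplicated(nodes$node)) {
    stop("element and node ids must be unique", call. = FALSE)
  }
  bad <- setdiff(c(elements$from, elements$to), nodes$node)
  if (length(bad)) {
    stop("dangling element port(s): unknown node(s) ",
      paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!"radius_mean" %in% names(elements)) elements$radius_mean <- NA_real_
  elements$radius_mean <- ifelse(is.na(elements$radius_mean),
    elements$radius_d, elements$radius_mean)
  if (!"poisson" %in% names(elements)) elements$poisson <- 0.5

  elems <- lapply(seq_len(nrow(elements)), function(i) {
    r <- elements[i, ]
    list(
      id = r$element, from = r$from, to = r$to,
      length = r$length, radius_d = r$radius_d,
      radius_mean = r$radius_mean, thickness = r$thickness,
      modulus = r$modulus, poisson = r$poisson,
      defect = if ("defect" %in% names(elements)) r$defect[[1]] else NULL,
      taper = if ("taper" %in% names(elements)) r$taper[[1]] else NULL
    )
  })
  names(elems) <- elements$element

  node_list <- lapply(seq_len(nrow(nodes)), function(i) {
    r <- nodes[i, ]
    n <- list(id = r$node, type = r$type)
    if (r$type == "windkessel") {
      stopifnot(!is.na(r$zc), !is.na(r$r), !is.na(r$c))
      n$zc <- r$zc; n$r <- r$r; n$c <- r$c
    }
    if (r$type == "source") {
      n$zs <- if ("zs" %in% names(nodes) && !is.na(r$zs)) r$zs else 1e30
    }
    if ("losses" %in% names(nodes)) {
      l <- r$losses[[1]]
      if (!is.null(l) && nrow(l)) n$losses <- tibble::as_tibble(l)
    }
    n
  })
  names(node_list) <- nodes$node

  # connectivity: node -> (element, port, global index); global index of
  # element m port j is 2(m-1)+j in element declaration order
  conn <- lapply(node_list, function(n) {
    rows <- list()
    for (m in seq_along(elems)) {
      e <- elems[[m]]
      if (e$from == n$id) rows[[length(rows) + 1]] <- c(m, 1L)
      if (e$to == n$id) rows[[length(rows) + 1]] <- c(m, 2L)
    }
    if (!length(rows)) {
      stop("node ", n$id, " has no attached element port", call. = FALSE)
    }
    mat <- do.call(rbind, rows)
    tibble::tibble(
      elem_idx = mat[, 1], port = mat[, 2],
      gidx = 2L * (mat[, 1] - 1L) + mat[, 2]
    )
  })
  for (n in node_list) {
    if (n$type %in% c("windkessel", "source") && nrow(conn[[n$id]]) != 1) {
      stop("termination node ", n$id, " must attach exactly one port",
        call. = FALSE)
    }
  }
  ports_per_node <- vapply(conn, nrow, integer(1))
  if (sum(ports_per_node) != 2L * length(elems)) {
    stop("inconsistent connectivity", call. = FALSE)
  }
  structure(
    list(elements = elems, nodes = node_list, conn = conn, fluid = fluid,
         M = length(elems)),
    class = "pw_network"
  )
}

#' @export
print.pw_network <- function(x, ...) {
  cat("<pw_network> ", x$M, " elements, ", length(x$nodes), " nodes (",
    sum(vapply(x$nodes, function(n) n$type == "windkessel", logical(1))),
    " windkessel, ",
    sum(vapply(x$nodes, function(n) n$type == "source", logical(1))),
    " source)\n", sep = "")
  invisible(x)
}

#' Ideal junction scattering matrix
#'
#' The unique scattering matrix of a lossless multiport node: all attached
#' port pressures are equal and the port volume flows sum to the nodal source
#' inflow. With port admittances `Yj = 1/Zj`:
#' `S[j,k] = 2 Yk / sum(Y) - delta_jk`, source vector `qs / sum(Y)`.
#'
#' @param z_ports Complex characteristic impedances of the attached ports.
#' @param qs Nodal volume-flow source amplitude (m^3/s), default 0.
#' @return List with the scattering matrix `S` (order = number of ports) and
#'   source vector `src`.
#' @export
junction_scattering <- function(z_ports, qs = 0) {
  y <- 1 / z_ports
  ys <- sum(y)
  if (Mod(ys) < 1e-290) stop("all port admittances are zero", call. = FALSE)
  p <- length(z_ports)
  S <- matrix(rep(2 * y / ys, each = p), p, p) - diag(p)
  list(S = S, src = rep(qs / ys, p))
}

#' Lossy junction scattering matrix
#'
#' Composes a per-branch series loss two-port (resistance `r_branch[j]`,
#' identity when 0) between each element port and an interior ideal junction
#' and returns the resulting node scattering matrix, solved from the chained
#' port relations. All-zero resistances reproduce [junction_scattering()].
#'
#' @inheritParams junction_scattering
#' @param r_branch Series loss resistances (Pa s/m^3), one per port.
#' @return List with scattering matrix `S` and source vector `src`.
#' @export
lossy_junction_scattering <- function(z_ports, r_branch, qs = 0) {
  p <- length(z_ports)
  stopifnot(length(r_branch) == p)
  # unknowns: p+_1..p, p_n; equations: p branch pressure relations + flow sum
  M <- matrix(0 + 0i, p + 1, p + 1)
  rhs <- matrix(0 + 0i, p + 1, p + 1) # columns: unit p-_k (1..p), unit qs
  for (j in seq_len(p)) {
    M[j, j] <- 1 + r_branch[j] / z_ports[j]
    M[j, p + 1] <- -1
    rhs[j, j] <- -(1 - r_branch[j] / z_ports[j])
    M[p + 1, j] <- 1 / z_ports[j]
    rhs[p + 1, j] <- 1 / z_ports[j]
  }
  rhs[p + 1, p + 1] <- 1
  x <- solve(M, rhs)
  list(S = x[seq_len(p), seq_len(p), drop = FALSE],
       src = qs * x[seq_len(p), p + 1])
}

# Node scattering at one frequency. z_ports per attached port (conn order);
# qs_amp is the source-node flow amplitude at this harmonic; nl gives branch
# loss resistances (already delta_n-scaled).
node_matrices <- function(node, z_ports, qs_amp = 0, r_branch = NULL) {
  if (node$type == "windkessel") {
    zwk <- node$zwk_at # filled by caller
    rw <- wk3_reflection(zwk, z_ports[1])
    return(list(S = matrix(rw, 1, 1), src = 0 + 0i))
  }
  if (node$type == "source") {
    so <- source_oneport(node$zs, z_ports[1], qs_amp)
    return(list(S = matrix(so$rs, 1, 1), src = so$ps))
  }
  if (is.null(r_branch) || all(r_branch == 0)) {
    junction_scattering(z_ports, 0)
  } else {
    lossy_junction_scattering(z_ports, r_branch, 0)
  }
}

# ---- solver -----------------------------------------------------------------

# One linear solve across the whole frequency grid for a fixed nonlinear
# state. Returns p_plus, p_minus (2M x nfreq), per-frequency element data,
# rcond estimates and residuals.
solve_linear_system <- function(net, spectrum, nh, q0_state) {
  omega0 <- 2 * pi * spectrum$f0
  omegas <- omega0 * (0:nh)
  omega_max <- max(omegas)
  M <- net$M
  qs_full <- c(spectrum$x, rep(0 + 0i, max(0, nh + 1 - length(spectrum$x))))

  p_plus <- matrix(0 + 0i, 2 * M, nh + 1)
  p_minus <- matrix(0 + 0i, 2 * M, nh + 1)
  elem_freq <- vector("list", nh + 1)
  conds <- numeric(nh + 1)
  resids <- numeric(nh + 1)

  for (k in seq_len(nh + 1)) {
    n_harm <- k - 1L
    w <- omegas[k]
    em <- lapply(net$elements, function(e) {
      q0 <- q0_state$defect[[e$id]] %||% 0
      elem_matrices(e, net$fluid, w, omega_max, q0 = q0, n = n_harm)
    })
    elem_freq[[k]] <- em

    S_E <- matrix(0 + 0i, 2 * M, 2 * M)
    z_all <- complex(2 * M)
    for (m in seq_len(M)) {
      idx <- c(2 * m - 1, 2 * m)
      S_E[idx, idx] <- em[[m]]$S
      z_all[idx] <- em[[m]]$z0
    }

    S_N <- matrix(0 + 0i, 2 * M, 2 * M)
    src_N <- complex(2 * M)
    for (nd in net$nodes) {
      cn <- net$conn[[nd$id]]
      zp <- z_all[cn$gidx]
      if (nd$type == "windkessel") {
        nd$zwk_at <- wk3_impedance(nd$zc, nd$r, nd$c, w)
      }
      qs_amp <- if (nd$type == "source") qs_full[k] else 0
      r_branch <- NULL
      if (!is.null(nd$losses)) {
        r_branch <- numeric(nrow(cn))
        for (j in seq_len(nrow(cn))) {
          eid <- net$elements[[cn$elem_idx[j]]]$id
          li <- match(eid, nd$losses$element)
          if (!is.na(li)) {
            q0b <- q0_state$junction[[nd$id]][[eid]] %||% 0
            area_m <- pi * net$elements[[cn$elem_idx[j]]]$radius_mean^2
            r_branch[j] <- borda_carnot_resistance(
              q0b, nd$losses$cl[li], area_m, 0, net$fluid$density, n_harm
            )
          }
        }
      }
      nm <- node_matrices(nd, zp, qs_amp, r_branch)
      S_N[cn$gidx, cn$gidx] <- nm$S
      src_N[cn$gidx] <- src_N[cn$gidx] + nm$src
    }

    A <- diag(2 * M) - S_N %*% S_E
    rhs <- src_N # element source vectors are zero (B p-s term vanishes)
    sv <- svd(A, nu = 0, nv = 0)$d
    conds[k] <- sv[1] / sv[length(sv)]
    if (!is.finite(conds[k]) || conds[k] > 1e14) {
      stop("assembled system is singular or ill-conditioned at harmonic ",
        n_harm, " (condition estimate ", format(conds[k]), ")", call. = FALSE)
    }
    pp <- solve(A, rhs)
    p_plus[, k] <- pp
    p_minus[, k] <- S_E %*% pp
    nr <- sqrt(sum(Mod(rhs)^2))
    resids[k] <- if (nr > 0) {
      sqrt(sum(Mod(A %*% pp - rhs)^2)) / nr
    } else 0
  }
  list(
    omegas = omegas, p_plus = p_plus, p_minus = p_minus,
    elem_freq = elem_freq, conds = conds, resids = resids
  )
}

# Steady (0 Hz) flow entering element `m` at port 1, from the DC solution.
dc_inlet_flow <- function(lin, m) {
  g <- 2 * m - 1
  z1 <- lin$elem_freq[[1]][[m]]$z0[1]
  Re((lin$p_plus[g, 1] - lin$p_minus[g, 1]) / z1)
}

# Steady flow INTO a node through a given attached port.
dc_flow_into_node <- function(lin, gidx) {
  m <- (gidx + 1) %/% 2
  z <- lin$elem_freq[[1]][[m]]$z0[if (gidx %% 2 == 1) 1 else 2]
  Re((lin$p_minus[gidx, 1] - lin$p_plus[gidx, 1]) / z)
}

# Collect the current q0 at every nonlinear loss site.
extract_q0 <- function(net, lin) {
  defect <- list()
  junction <- list()
  for (m in seq_len(net$M)) {
    e <- net$elements[[m]]
    if (!is.null(e$defect)) defect[[e$id]] <- dc_inlet_flow(lin, m)
  }
  for (nd in net$nodes) {
    if (is.null(nd$losses)) next
    cn <- net$conn[[nd$id]]
    q <- list()
    for (j in seq_len(nrow(cn))) {
      eid <- net$elements[[cn$elem_idx[j]]]$id
      if (eid %in% nd$losses$element) {
        q[[eid]] <- dc_flow_into_node(lin, cn$gidx[j])
      }
    }
    junction[[nd$id]] <- q
  }
  list(defect = defect, junction = junction)
}

q0_vector <- function(state) {
  unlist(c(state$defect, lapply(state$junction, unlist)), use.names = FALSE)
}

#' Solve an arterial network in the frequency domain
#'
#' Solves the assembled scattering system `A p+ = q s` at every harmonic of
#' the inflow fundamental and iterates any quasi-steady nonlinear losses
#' (stenosis/aneurysm elements, lossy junction branches) to a fixed point of
#' the steady flow. The first pass neglects nonlinear effects; each
#' subsequent pass rebuilds the loss resistances from the 0 Hz solution.
#'
#' @param net A [pw_network()].
#' @param inflow Inflow waveform: a data frame with columns `time`, `flow`
#'   (one period, uniform sampling) or a `pw_spectrum` from [pw_decompose()].
#' @param nh Number of harmonics above DC to solve (default 15).
#' @param tol Relative fixed-point tolerance on the steady flows (default
#'   1e-6).
#' @param max_iter Maximum fixed-point iterations (default 50).
#' @param relax Under-relaxation factor in (0, 1] applied to the q0 update
#'   (1 = plain fixed point; the benchmark cases converge without it).
#' @param mean_radius_iter If `TRUE`, run the optional outer loop that
#'   updates each element's time-averaged radius from the local steady
#'   pressure (requires `pd`).
#' @param pd Diastolic pressure (Pa) used by the mean-radius update.
#' @param mr_tol,mr_max_iter Tolerance and iteration cap for the outer
#'   mean-radius loop.
#'
#' @return A `pw_solution` object; see [field_at()], [pw_waveforms()],
#'   [tidy.pw_solution()], [glance.pw_solution()].
#' @export
pw_solve <- function(net, inflow, nh = 15, tol = 1e-6, max_iter = 50,
                     relax = 1, mean_radius_iter = FALSE, pd = NULL,
                     mr_tol = 1e-4, mr_max_iter = 20) {
  spectrum <- if (inherits(inflow, "pw_spectrum")) {
    inflow
  } else {
    pw_decompose(inflow, nh = nh)
  }
  if (mean_radius_iter) {
    if (is.null(pd)) {
      stop("mean_radius_iter = TRUE requires the diastolic pressure pd",
        call. = FALSE)
    }
    return(iterate_mean_radius(net, spectrum, nh, tol, max_iter, relax, pd,
      mr_tol, mr_max_iter))
  }
  solve_fixed_radius(net, spectrum, nh, tol, max_iter, relax)
}

solve_fixed_radius <- function(net, spectrum, nh, tol, max_iter, relax) {
  has_nl <- any(vapply(net$elements, function(e) !is.null(e$defect),
    logical(1))) ||
    any(vapply(net$nodes, function(n) !is.null(n$losses), logical(1)))
  state <- list(defect = list(), junction = list())
  trace <- list()
  lin <- NULL
  n_iter <- if (has_nl) max_iter else 1L
  converged <- !has_nl
  it_done <- 0L
  for (it in seq_len(n_iter)) {
    lin <- solve_linear_system(net, spectrum, nh, state)
    it_done <- it
    new_state <- extract_q0(net, lin)
    v_old <- q0_vector(state)
    v_new <- q0_vector(new_state)
    trace[[it]] <- tibble::tibble(
      iteration = it,
      q0_norm = if (length(v_new)) max(abs(v_new)) else 0,
      update = if (length(v_old) && length(v_new)) {
        max(abs(v_new - v_old)) } else NA_real_
    )
    if (!has_nl) break
    if (length(v_old) == length(v_new) && length(v_new)) {
      rel <- max(abs(v_new - v_old) / pmax(abs(v_new), 1e-300))
      if (rel < tol) { converged <- TRUE; state <- new_state; break }
    }
    if (relax < 1 && length(v_old) == length(v_new)) {
      v_mix <- relax * v_new + (1 - relax) * v_old
      new_state <- relist_q0(new_state, v_mix)
    }
    state <- new_state
  }
  if (has_nl && !converged) {
    stop("nonlinear iteration did not converge in ", max_iter,
      " iterations; trace max update ",
      format(trace[[length(trace)]]$update), call. = FALSE)
  }
  structure(
    list(
      network = net, f0 = spectrum$f0, nh = nh,
      omegas = lin$omegas, p_plus = lin$p_plus, p_minus = lin$p_minus,
      elem_freq = lin$elem_freq, conds = lin$conds, resids = lin$resids,
      iterations = it_done, converged = converged,
      trace = dplyr::bind_rows(trace), q0 = state
    ),
    class = "pw_solution"
  )
}

relist_q0 <- function(state, v) {
  i <- 0
  for (id in names(state$defect)) {
    i <- i + 1; state$defect[[id]] <- v[i]
  }
  for (nd in names(state$junction)) {
    for (eid in names(state$junction[[nd]])) {
      i <- i + 1; state$junction[[nd]][[eid]] <- v[i]
    }
  }
  state
}

# Optional outer loop: update each element's time-averaged radius from the
# local steady pressure (diastolic state taken stress-free), re-solve until
# the radii settle.
iterate_mean_radius <- function(net, spectrum, nh, tol, max_iter, relax, pd,
                                mr_tol, mr_max_iter) {
  sol <- NULL
  for (it in seq_len(mr_max_iter)) {
    sol <- solve_fixed_radius(net, spectrum, nh, tol, max_iter, relax)
    max_dr <- 0
    for (m in seq_len(net$M)) {
      e <- net$elements[[m]]
      p0 <- Re(field_at(sol, e$id, 0.5)$pressure[1])
      r_new <- mean_radius_update(e$radius_d, p0, pd, e$modulus, e$thickness,
        e$poisson)
      max_dr <- max(max_dr, abs(r_new - e$radius_mean) / e$radius_mean)
      net$elements[[m]]$radius_mean <- r_new
    }
    if (max_dr < mr_tol) {
      sol$network <- net
      sol$mean_radius_iterations <- it
      return(sol)
    }
  }
  stop("mean-radius outer iteration did not settle in ", mr_max_iter,
    " passes", call. = FALSE)
}

#' @export
print.pw_solution <- function(x, ...) {
  cat("<pw_solution> ", x$network$M, " elements, harmonics 0..", x$nh,
    " of f0 = ", signif(x$f0, 4), " Hz; ",
    x$iterations, " nonlinear iteration(s)\n", sep = "")
  invisible(x)
}

# ---- field reconstruction ---------------------------------------------------

#' Pressure and flow spectra at a position inside an element
#'
#' Reconstructs the complex pressure and volume-flow amplitudes at a
#' fractional position along an element at every solved harmonic, by
#' cascading partial transfer matrices from the inlet port state. Within a
#' homogeneous span this equals the free-wave field
#' `p(x) = p+ e^{-i kappa x} + p- e^{+i kappa x}`; at 0 Hz it is the
#' resistive (Poiseuille) ladder.
#'
#' @param sol A `pw_solution`.
#' @param element Element id.
#' @param frac Position as a fraction of the element length, in `[0, 1]`.
#' @return List with complex vectors `pressure` (Pa) and `flow` (m^3/s) of
#'   length `nh + 1` (harmonics 0..nh) plus `f0`.
#' @export
field_at <- function(sol, element, frac) {
  if (frac < 0 || frac > 1) {
    stop("frac must lie in [0, 1]", call. = FALSE)
  }
  m <- match(element, names(sol$network$elements))
  if (is.na(m)) stop("unknown element ", element, call. = FALSE)
  g1 <- 2 * m - 1
  nf <- length(sol$omegas)
  pr <- complex(nf)
  fl <- complex(nf)
  L <- sol$network$elements[[m]]$length
  x_target <- frac * L
  for (k in seq_len(nf)) {
    em <- sol$elem_freq[[k]][[m]]
    z1 <- em$z0[1]
    state <- c(
      sol$p_plus[g1, k] + sol$p_minus[g1, k],
      (sol$p_plus[g1, k] - sol$p_minus[g1, k]) / z1
    )
    x_left <- 0
    for (pc in em$pieces) {
      if (pc$type == "lump") {
        state <- solve2(piece_T(pc), state)
        next
      }
      if (x_left + pc$len >= x_target - 1e-12 * max(L, 1e-300)) {
        dx <- min(max(x_target - x_left, 0), pc$len)
        if (dx > 0) state <- solve2(piece_T(pc, dx), state)
        break
      }
      state <- solve2(piece_T(pc), state)
      x_left <- x_left + pc$len
    }
    pr[k] <- state[1]
    fl[k] <- state[2]
  }
  list(pressure = pr, flow = fl, f0 = sol$f0)
}

# States (p, q) at every internal piece boundary of an element at harmonic n
# (0-based). Returns a list of 2-vectors, from the inlet port (index 1)
# through each piece boundary to the outlet port. Used to verify lumped
# pressure drops and interface flow continuity.
element_interface_states <- function(sol, element, n = 0) {
  m <- match(element, names(sol$network$elements))
  k <- n + 1L
  em <- sol$elem_freq[[k]][[m]]
  g1 <- 2 * m - 1
  z1 <- em$z0[1]
  state <- c(
    sol$p_plus[g1, k] + sol$p_minus[g1, k],
    (sol$p_plus[g1, k] - sol$p_minus[g1, k]) / z1
  )
  states <- list(state)
  for (pc in em$pieces) {
    state <- solve2(piece_T(pc), state)
    states[[length(states) + 1]] <- state
  }
  states
}

#' Monitored waveforms from a solved network
#'
#' Synthesizes time-domain pressure and flow at a set of monitoring
#' positions from the solved harmonic field.
#'
#' @param sol A `pw_solution`.
#' @param monitors Data frame with columns `position` (label), `element`
#'   (element id) and `frac` (fractional position along the element).
#' @param n_time Samples per period (default 1000).
#' @return A tibble with columns `time` (s), `position`, `pressure_Pa`,
#'   `flow_m3s`.
#' @export
pw_waveforms <- function(sol, monitors, n_time = 1000) {
  monitors <- tibble::as_tibble(monitors)
  stopifnot(all(c("position", "element", "frac") %in% names(monitors)))
  t_grid <- seq(0, 1 / sol$f0, length.out = n_time + 1)[seq_len(n_time)]
  purrr::map_dfr(seq_len(nrow(monitors)), function(i) {
    fa <- field_at(sol, monitors$element[i], monitors$frac[i])
    tibble::tibble(
      time = t_grid,
      position = monitors$position[i],
      pressure_Pa = synthesize_harmonics(fa$pressure, sol$f0, t_grid),
      flow_m3s = synthesize_harmonics(fa$flow, sol$f0, t_grid)
    )
  })
}

#' @rdname pw_solution_tidiers
#' @export
tidy.pw_solution <- function(x, ...) {
  M <- x$network$M
  ids <- names(x$network$elements)
  purrr::map_dfr(seq_len(M), function(m) {
    tibble::tibble(
      element = ids[m],
      harmonic = rep(0:x$nh, 2),
      port = rep(c(1L, 2L), each = x$nh + 1),
      p_plus = c(x$p_plus[2 * m - 1, ], x$p_plus[2 * m, ]),
      p_minus = c(x$p_minus[2 * m - 1, ], x$p_minus[2 * m, ])
    )
  })
}

#' Tidiers for solved networks
#'
#' `tidy()` returns the solved incident/outgoing wave amplitudes per element
#' port and harmonic; `glance()` returns a one-row summary of the solve
#' (iterations, worst conditioning, worst linear residual).
#'
#' @param x A `pw_solution`.
#' @param ... Unused.
#' @name pw_solution_tidiers
#' @export
glance.pw_solution <- function(x, ...) {
  tibble::tibble(
    n_elements = x$network$M,
    n_harmonics = x$nh,
    f0 = x$f0,
    iterations = x$iterations,
    converged = x$converged,
    max_condition = max(x$conds),
    max_residual = max(x$resids)
  )
}
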