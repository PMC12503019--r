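# Independent verification solver: nodal pressures + element port flows.
#
# This solver never forms wave amplitudes or scattering matrices. Unknowns
# are the nodal pressures and the two port flows of every element; equations
# are the element transfer relations, nodal flow conservation and the
# boundary impedance laws. It exists purely to cross-check the scattering
# assembly on identical inputs.

#' Reference nodal-impedance network solver
#'
#' Solves the same physical problem as [pw_solve()] with a completely
#' different formulation: unknown nodal pressures and element port flows in
#' an impedance (state-variable) formulation, solved as one dense linear
#' system per harmonic, with the same quasi-steady nonlinear fixed-point
#' loop. Intended for verification; returns nodal pressures rather than a
#' full field object.
#'
#' @inheritParams pw_solve
#' @return A list with `nodes` (node ids), `omegas`, `pressure` (complex
#'   matrix, nodes x harmonics), `flows` (complex matrix, 2M x harmonics,
#'   port flows q1, q2 per element) and `iterations`.
#' @seealso [pw_solve()]
#' @export
solve_nodal <- function(net, inflow, nh = 15, tol = 1e-6, max_iter = 50) {
  spectrum <- if (inherits(inflow, "pw_spectrum")) {
    inflow
  } else {
    pw_decompose(inflow, nh = nh)
  }
  has_nl <- any(vapply(net$elements, function(e) !is.null(e$defect),
    logical(1))) ||
    any(vapply(net$nodes, function(n) !is.null(n$losses), logical(1)))
  state <- list(defect = list(), junction = list())
  res <- NULL
  iterations <- 0L
  for (it in seq_len(if (has_nl) max_iter else 1L)) {
    res <- solve_nodal_once(net, spectrum, nh, state)
    iterations <- it
    if (!has_nl) break
    new_state <- nodal_extract_q0(net, res)
    v_old <- q0_vector(state)
    v_new <- q0_vector(new_state)
    if (length(v_old) == length(v_new) && length(v_new)) {
      rel <- max(abs(v_new - v_old) / pmax(abs(v_new), 1e-300))
      state <- new_state
      if (rel < tol) break
    } else {
      state <- new_state
    }
    if (it == max_iter) {
      stop("solve_nodal(): nonlinear iteration did not converge",
        call. = FALSE)
    }
  }
  res$iterations <- iterations
  res
}

solve_nodal_once <- function(net, spectrum, nh, q0_state) {
  omega0 <- 2 * pi * spectrum$f0
  omegas <- omega0 * (0:nh)
  omega_max <- max(omegas)
  M <- net$M
  node_ids <- names(net$nodes)
  N <- length(node_ids)
  qs_full <- c(spectrum$x, rep(0 + 0i, max(0, nh + 1 - length(spectrum$x))))

  # unknown ordering: nodal pressures 1..N, then q1, q2 per element
  iq <- function(m, port) N + 2L * (m - 1L) + port
  press <- matrix(0 + 0i, N, nh + 1)
  flows <- matrix(0 + 0i, 2 * M, nh + 1)

  # per-node, per-branch loss resistance lookup (keyed by element id)
  branch_r <- function(nd, eid, rm, n_harm) {
    if (is.null(nd$losses)) return(0)
    li <- match(eid, nd$losses$element)
    if (is.na(li)) return(0)
    q0b <- q0_state$junction[[nd$id]][[eid]] %||% 0
    borda_carnot_resistance(q0b, nd$losses$cl[li], pi * rm^2, 0,
      net$fluid$density, n_harm)
  }

  for (k in seq_len(nh + 1)) {
    n_harm <- k - 1L
    w <- omegas[k]
    G <- matrix(0 + 0i, N + 2 * M, N + 2 * M)
    b <- complex(N + 2 * M)
    row <- 0L
    for (m in seq_len(M)) {
      e <- net$elements[[m]]
      q0 <- q0_state$defect[[e$id]] %||% 0
      Tm <- elem_matrices(e, net$fluid, w, omega_max, q0 = q0, n = n_harm)$T
      nf <- match(e$from, node_ids)
      nt <- match(e$to, node_ids)
      rf <- branch_r(net$nodes[[e$from]], e$id, e$radius_mean, n_harm)
      rt <- branch_r(net$nodes[[e$to]], e$id, e$radius_mean, n_harm)
      # port pressures: p_port1 = p_from - rf*q1 ; p_port2 = p_to + rt*q2
      # (flow into the node is -q1 at port 1, +q2 at port 2)
      # element: p_port1 = A p_port2 + B q2 ; q1 = C p_port2 + D q2
      # accumulate (nf may equal nt for a ring element)
      row <- row + 1L
      G[row, nf] <- G[row, nf] + 1
      G[row, iq(m, 1)] <- -rf
      G[row, nt] <- G[row, nt] - Tm[1, 1]
      G[row, iq(m, 2)] <- -(Tm[1, 1] * rt + Tm[1, 2])
      row <- row + 1L
      G[row, iq(m, 1)] <- 1
      G[row, nt] <- G[row, nt] - Tm[2, 1]
      G[row, iq(m, 2)] <- -(Tm[2, 1] * rt + Tm[2, 2])
    }
    for (nd in net$nodes) {
      ni <- match(nd$id, node_ids)
      cn <- net$conn[[nd$id]]
      row <- row + 1L
      if (nd$type == "junction") {
        # sum of flows into the node = 0
        for (j in seq_len(nrow(cn))) {
          sgn <- if (cn$port[j] == 1L) -1 else 1
          G[row, iq(cn$elem_idx[j], cn$port[j])] <- sgn
        }
      } else if (nd$type == "windkessel") {
        zwk <- wk3_impedance(nd$zc, nd$r, nd$c, w)
        sgn <- if (cn$port[1] == 1L) -1 else 1
        G[row, ni] <- 1
        G[row, iq(cn$elem_idx[1], cn$port[1])] <- -zwk * sgn
      } else { # source: q_into_node + qs - p_n/Zs = 0
        sgn <- if (cn$port[1] == 1L) -1 else 1
        G[row, iq(cn$elem_idx[1], cn$port[1])] <- sgn
        G[row, ni] <- -1 / nd$zs
        b[row] <- -qs_full[k]
      }
    }
    # equilibrate: flows carry ~Z0 smaller magnitudes than pressures; scale
    # flow columns by a characteristic impedance and rows by their max
    col_scale <- c(rep(1, N), rep(1e-8, 2 * M))
    Gs <- sweep(G, 2, col_scale, `*`)
    row_scale <- apply(Gs, 1, function(r) max(Mod(r)))
    Gs <- sweep(Gs, 1, row_scale, `/`)
    x <- col_scale * solve(Gs, b / row_scale)
    press[, k] <- x[seq_len(N)]
    flows[, k] <- x[N + seq_len(2 * M)]
  }
  list(nodes = node_ids, omegas = omegas, pressure = press, flows = flows)
}

nodal_extract_q0 <- function(net, res) {
  node_ids <- res$nodes
  defect <- list()
  junction <- list()
  for (m in seq_len(net$M)) {
    e <- net$elements[[m]]
    if (!is.null(e$defect)) {
      defect[[e$id]] <- Re(res$flows[2 * m - 1, 1])
    }
  }
  for (nd in net$nodes) {
    if (is.null(nd$losses)) next
    cn <- net$conn[[nd$id]]
    q <- list()
    for (j in seq_len(nrow(cn))) {
      eid <- net$elements[[cn$elem_idx[j]]]$id
      if (eid %in% nd$losses$element) {
        sgn <- if (cn$port[j] == 1L) -1 else 1
        q[[eid]] <- Re(sgn * res$flows[2 * cn$elem_idx[j] - 1 +
          (cn$port[j] - 1L), 1])
      }
    }
    junction[[nd$id]] <- q
  }
  list(defect = defect, junction = junction)
}

#' Nodal pressures from a scattering solution
#'
#' Extracts the complex nodal pressure at every node and harmonic from a
#' [pw_solve()] result (the pressure of any attached port; ideal junctions
#' make them equal). Useful for comparing against [solve_nodal()].
#'
#' @param sol A `pw_solution`.
#' @return Complex matrix, nodes x harmonics, with node ids as rownames.
#' @export
nodal_pressures <- function(sol) {
  net <- sol$network
  node_ids <- names(net$nodes)
  out <- matrix(0 + 0i, length(node_ids), length(sol$omegas))
  rownames(out) <- node_ids
  for (i in seq_along(node_ids)) {
    cn <- net$conn[[node_ids[i]]]
    g <- cn$gidx[1]
    nd <- net$nodes[[node_ids[i]]]
    if (nd$type == "junction" && !is.null(nd$losses)) {
      # lossy junction: port pressures differ; report the interior node
      # pressure via the branch drop of the first attached port
      for (k in seq_along(sol$omegas)) {
        m <- cn$elem_idx[1]
        eid <- net$elements[[m]]$id
        z <- sol$elem_freq[[k]][[m]]$z0[cn$port[1]]
        pp <- sol$p_plus[g, k]; pm <- sol$p_minus[g, k]
        q_in <- (pm - pp) / z
        li <- match(eid, nd$losses$element)
        rb <- 0
        if (!is.na(li)) {
          q0b <- sol$q0$junction[[nd$id]][[eid]] %||% 0
          rb <- borda_carnot_resistance(q0b, nd$losses$cl[li],
            pi * net$elements[[m]]$radius_mean^2, 0, net$fluid$density,
            k - 1L)
        }
        out[i, k] <- pp + pm - rb * q_in
      }
    } else {
      out[i, ] <- sol$p_plus[g, ] + sol$p_minus[g, ]
    }
  }
  out
}

#' Generate a randomized small test network
#'
#' Draws a connected arterial-like network with `n_elements` vessel segments
#' (random physiological-range geometry), one flow source, Windkessel
#' terminations at every other leaf, and optional loops created by merging
#' interior nodes. Used by the verification suite to exercise the solvers on
#' topologies beyond the built-in benchmarks.
#'
#' @param n_elements Number of vessel elements (2-10 sensible).
#' @param seed Integer seed for reproducibility.
#' @param p_loop Probability of attempting one node merge that creates a
#'   loop (default 0.3).
#' @return A `pw_network`.
#' @export
random_network <- function(n_elements, seed, p_loop = 0.3) {
  stopifnot(n_elements >= 2)
  set.seed(seed)
  resample <- function(x, n) x[sample.int(length(x), n)]
  rng <- list(runif = function(n, a, b) stats::runif(n, a, b))
  # random tree: element i joins an existing node to new node i+1
  from <- integer(n_elements)
  to <- integer(n_elements)
  from[1] <- 1L; to[1] <- 2L
  for (i in seq_len(n_elements)[-1]) {
    from[i] <- resample(2:i, 1)
    to[i] <- i + 1L
  }
  node_id <- function(i) paste0("n", i)
  # possible loop: merge two distinct interior (non-root, non-leaf) nodes
  if (n_elements >= 4 && stats::runif(1) < p_loop) {
    deg <- tabulate(c(from, to), n_elements + 1L)
    interior <- setdiff(which(deg >= 2), 1L)
    if (length(interior) >= 2) {
      pick <- resample(interior, 2)
      from[from == pick[2]] <- pick[1]
      to[to == pick[2]] <- pick[1]
    }
  }
  used <- sort(unique(c(from, to)))
  deg <- tabulate(c(from, to), max(used))
  radii <- rng$runif(n_elements, 2e-3, 9e-3)
  elements <- tibble::tibble(
    element = paste0("e", seq_len(n_elements)),
    from = node_id(from), to = node_id(to),
    length = rng$runif(n_elements, 0.03, 0.15),
    radius_d = radii,
    radius_mean = radii * stats::runif(n_elements, 1, 1.05),
    thickness = radii * 0.1,
    modulus = rng$runif(n_elements, 4e5, 1.2e6)
  )
  leaf <- used[deg[used] == 1 & used != 1L]
  nodes <- tibble::tibble(
    node = node_id(used),
    type = ifelse(used == 1L, "source",
      ifelse(used %in% leaf, "windkessel", "junction")),
    zc = ifelse(used %in% leaf, stats::runif(length(used), 5e7, 5e8), NA),
    r = ifelse(used %in% leaf, stats::runif(length(used), 1e9, 5e9), NA),
    c = ifelse(used %in% leaf, stats::runif(length(used), 5e-11, 5e-10), NA),
    zs = ifelse(used == 1L, 1e30, NA)
  )
  pw_network(elements, nodes, pw_fluid())
}
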