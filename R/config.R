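# YAML/JSON network configuration files.
#
# Quantities are SI internally; config files may give any quantity as a
# string "VALUE UNIT" (e.g. "86 mm", "500 kPa"), converted on load.

unit_table <- c(
  "m" = 1, "mm" = 1e-3, "cm" = 1e-2, "um" = 1e-6,
  "Pa" = 1, "kPa" = 1e3, "MPa" = 1e6, "mmHg" = 133.322,
  "s" = 1, "ms" = 1e-3,
  "Pa.s" = 1, "mPa.s" = 1e-3,
  "kg/m3" = 1, "g/cm3" = 1e3,
  "m3/s" = 1, "mL/s" = 1e-6, "L/min" = 1e-3 / 60,
  "Pa.s/m3" = 1, "m3/Pa" = 1,
  "m2" = 1, "mm2" = 1e-6, "1" = 1
)

parse_quantity <- function(x) {
  if (is.null(x) || is.numeric(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    parts <- strsplit(trimws(x), "\\s+")[[1]]
    if (length(parts) == 1) return(as.numeric(parts))
    if (length(parts) == 2) {
      mult <- unit_table[parts[2]]
      if (is.na(mult)) stop("unknown unit '", parts[2], "'", call. = FALSE)
      return(as.numeric(parts[1]) * unname(mult))
    }
  }
  stop("cannot parse quantity: ", deparse(x), call. = FALSE)
}

pq <- function(lst, field, default = NULL) {
  v <- lst[[field]]
  if (is.null(v)) return(default)
  parse_quantity(v)
}

#' Read a network configuration file
#'
#' Loads a YAML (or JSON, a YAML subset) network description: a `fluid`
#' block, `elements` and `nodes` lists, an optional `simulation` block
#' (`period`, `nh`, `tol`, `n_time`), optional `monitors`, and an optional
#' `inflow` block (`preset` name or `file` path). All quantities may be
#' plain SI numbers or `"VALUE UNIT"` strings (mm, kPa, mL/s, ...).
#'
#' @param path Config file path.
#' @return A `pw_case` object.
#' @export
pw_read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fluid <- pw_fluid(
    density = pq(cfg$fluid, "density", 1060),
    viscosity = pq(cfg$fluid, "viscosity", 4e-3)
  )
  elements <- purrr::map_dfr(cfg$elements, function(e) {
    tibble::tibble(
      element = e$element, from = e$from, to = e$to,
      length = pq(e, "length"),
      radius_d = pq(e, "radius_d"),
      radius_mean = pq(e, "radius_mean", pq(e, "radius_d")),
      thickness = pq(e, "thickness"),
      modulus = pq(e, "modulus"),
      poisson = pq(e, "poisson", 0.5),
      defect = list(if (!is.null(e$defect)) {
        d <- e$defect
        pw_defect(d$kind %||% "stenosis",
          severity = pq(d, "severity"),
          area = pq(d, "area"),
          length = pq(d, "length"),
          position = pq(d, "position"),
          cl_in = pq(d, "cl_in"),
          cl_out = pq(d, "cl_out"),
          mode = d$mode %||% "abrupt"
        )
      }),
      taper = list(if (!is.null(e$taper)) {
        lapply(e$taper, parse_quantity)
      })
    )
  })
  nodes <- purrr::map_dfr(cfg$nodes, function(n) {
    tibble::tibble(
      node = n$node, type = n$type,
      zc = pq(n, "zc", NA_real_),
      r = pq(n, "r", NA_real_),
      c = pq(n, "c", NA_real_),
      zs = pq(n, "zs", if (identical(n$type, "source")) 1e30 else NA_real_),
      losses = list(if (!is.null(n$losses)) {
        purrr::map_dfr(n$losses, function(l) {
          tibble::tibble(element = l$element, cl = pq(l, "cl"))
        })
      })
    )
  })
  monitors <- if (!is.null(cfg$monitors)) {
    purrr::map_dfr(cfg$monitors, function(m) {
      tibble::tibble(position = m$position, element = m$element,
        frac = pq(m, "frac"))
    })
  } else {
    tibble::tibble(position = character(), element = character(),
      frac = numeric())
  }
  sim <- list(
    nh = cfg$simulation$nh %||% 15,
    tol = pq(cfg$simulation, "tol", 1e-6),
    n_time = cfg$simulation$n_time %||% 1000
  )
  new_case(cfg$name %||% "config", elements, nodes, fluid, monitors, sim,
    inflow_preset = cfg$inflow$preset %||% NA_character_,
    pd = pq(cfg, "diastolic_pressure", NA_real_))
}

#' Write a network configuration file
#'
#' Serializes a `pw_case` to YAML in SI units. `pw_read_config()` of the
#' written file reproduces the case.
#'
#' @param case A `pw_case`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
pw_write_config <- function(case, path) {
  el <- lapply(seq_len(nrow(case$elements)), function(i) {
    r <- case$elements[i, ]
    out <- list(
      element = r$element, from = r$from, to = r$to,
      length = r$length, radius_d = r$radius_d,
      radius_mean = r$radius_mean, thickness = r$thickness,
      modulus = r$modulus
    )
    if ("poisson" %in% names(case$elements)) out$poisson <- r$poisson
    d <- if ("defect" %in% names(case$elements)) r$defect[[1]] else NULL
    if (!is.null(d)) {
      out$defect <- Filter(Negate(is.null), list(
        kind = d$kind, severity = d$severity, area = d$area,
        length = d$length, position = d$position,
        cl_in = d$cl_in, cl_out = d$cl_out, mode = d$mode
      ))
    }
    tp <- if ("taper" %in% names(case$elements)) r$taper[[1]] else NULL
    if (!is.null(tp)) out$taper <- tp
    out
  })
  nd <- lapply(seq_len(nrow(case$nodes)), function(i) {
    r <- case$nodes[i, ]
    out <- list(node = r$node, type = r$type)
    for (f in c("zc", "r", "c", "zs")) {
      if (f %in% names(case$nodes) && !is.na(r[[f]])) out[[f]] <- r[[f]]
    }
    l <- if ("losses" %in% names(case$nodes)) r$losses[[1]] else NULL
    if (!is.null(l)) {
      out$losses <- lapply(seq_len(nrow(l)), function(j) {
        list(element = l$element[j], cl = l$cl[j])
      })
    }
    out
  })
  mon <- lapply(seq_len(nrow(case$monitors)), function(i) {
    r <- case$monitors[i, ]
    list(position = r$position, element = r$element, frac = r$frac)
  })
  cfg <- list(
    name = case$name,
    fluid = list(density = case$fluid$density,
      viscosity = case$fluid$viscosity),
    elements = el,
    nodes = nd,
    monitors = mon,
    simulation = case$sim,
    inflow = list(preset = case$inflow_preset)
  )
  if (!is.null(case$pd) && !is.na(case$pd)) cfg$diastolic_pressure <- case$pd
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
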