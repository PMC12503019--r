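# Built-in benchmark networks, defined from their published parameter
# tables.

new_case <- function(name, elements, nodes, fluid, monitors, sim,
                     inflow_preset, pd) {
  structure(
    list(
      name = name, elements = elements, nodes = nodes, fluid = fluid,
      monitors = monitors, sim = sim, inflow_preset = inflow_preset,
      pd = pd
    ),
    class = "pw_case"
  )
}

#' @export
print.pw_case <- function(x, ...) {
  cat("<pw_case> ", x$name, ": ", nrow(x$elements), " elements, ",
    nrow(x$nodes), " nodes; inflow preset '", x$inflow_preset, "'\n",
    sep = "")
  invisible(x)
}

#' Benchmark case: healthy aortic bifurcation
#'
#' An idealized abdominal aorta splitting into two identical iliac arteries,
#' each terminated by a three-element Windkessel. Optionally the bifurcation
#' node carries quasi-steady flow-separation losses on both downstream
#' paths (loss coefficient 0.1, referenced to the iliac lumen area, no area
#' change).
#'
#' @param junction_loss Include the bifurcation branch losses?
#' @return A `pw_case`.
#' @export
pw_case_bifurcation <- function(junction_loss = FALSE) {
  elements <- tibble::tibble(
    element = c("aorta", "iliac_L", "iliac_R"),
    from = c("inlet", "bifurcation", "bifurcation"),
    to = c("bifurcation", "wk_L", "wk_R"),
    length = c(86e-3, 85e-3, 85e-3),
    radius_d = c(8.6e-3, 6e-3, 6e-3),
    radius_mean = c(8.9e-3, 6.15e-3, 6.15e-3),
    thickness = c(1.032e-3, 0.72e-3, 0.72e-3),
    modulus = c(500e3, 700e3, 700e3)
  )
  losses <- if (junction_loss) {
    list(NULL, tibble::tibble(element = c("iliac_L", "iliac_R"),
      cl = c(0.1, 0.1)), NULL, NULL)
  } else {
    list(NULL, NULL, NULL, NULL)
  }
  nodes <- tibble::tibble(
    node = c("inlet", "bifurcation", "wk_L", "wk_R"),
    type = c("source", "junction", "windkessel", "windkessel"),
    zc = c(NA, NA, 6.1823e7, 6.1823e7),
    r = c(NA, NA, 3.1013e9, 3.1013e9),
    c = c(NA, NA, 3.6664e-10, 3.6664e-10),
    zs = c(1e30, NA, NA, NA),
    losses = losses
  )
  monitors <- tibble::tibble(
    position = c("mid_aorta", "junction", "mid_iliac"),
    element = c("aorta", "aorta", "iliac_L"),
    frac = c(0.5, 1, 0.5)
  )
  new_case("aortic_bifurcation", elements, nodes, pw_fluid(1060, 4e-3),
    monitors, list(nh = 15, tol = 1e-6, n_time = 1000),
    "aortic_bifurcation", pd = 9.1e3)
}

#' Benchmark case: stenosed common carotid artery
#'
#' A single idealized common carotid vessel (126 mm) with a 48 mm stenosis
#' section of given relative severity `(1 - As/A0) * 100` in percent, with
#' Borda-Carnot losses lumped at the sudden area changes (CL 0.52 in, 1
#' out), terminated by a three-element Windkessel.
#'
#' @param severity Stenosis severity in percent, in (0, 100); 0 is accepted
#'   and yields the healthy uniform vessel.
#' @param nonlinear Include the nonlinear loss two-ports? `FALSE` gives the
#'   linear comparison model.
#' @return A `pw_case`.
#' @export
pw_case_carotid <- function(severity = 75, nonlinear = TRUE) {
  if (severity < 0 || severity >= 100) {
    stop("severity must lie in [0, 100)", call. = FALSE)
  }
  defect <- if (severity > 0) {
    d <- pw_defect("stenosis", severity = severity, length = 48e-3,
      position = 39e-3)
    if (!nonlinear) { d$cl_in <- 0; d$cl_out <- 0 }
    d
  } else {
    NULL
  }
  elements <- tibble::tibble(
    element = "carotid",
    from = "inlet", to = "outlet",
    length = 126e-3, radius_d = 3e-3, radius_mean = 3e-3,
    thickness = 0.3e-3, modulus = 700e3,
    defect = list(defect)
  )
  nodes <- tibble::tibble(
    node = c("inlet", "outlet"),
    type = c("source", "windkessel"),
    zc = c(NA, 2.4875e8),
    r = c(NA, 1.8697e9),
    c = c(NA, 1.7529e-10),
    zs = c(1e30, NA)
  )
  monitors <- tibble::tibble(
    position = c("proximal", "distal"),
    element = "carotid",
    frac = c(0, 1)
  )
  new_case(paste0("carotid_stenosis_", severity), elements, nodes,
    pw_fluid(1060, 4e-3), monitors,
    list(nh = 15, tol = 1e-6, n_time = 1000), "carotid", pd = 10.933e3)
}

# Table of the full-aorta segment parameters (lengths cm, radii mm, E kPa,
# WK: R1 x 1e7, R2 x 1e8 Pa s/m^3, C x 1e-10 m^3/Pa; NA = no termination).
full_aorta_table <- function() {
  tibble::tribble(
    ~segment, ~name, ~length_cm, ~rd_mm, ~r0_mm, ~E_kPa, ~R1, ~R2, ~C,
    1L, "Ao_I", 7.04, 14.55, 14.59, 372.2, NA, NA, NA,
    2L, "Ao_II", 0.8, 13.8, 13.8, 384.2, NA, NA, NA,
    3L, "Ao_III", 0.9, 13.60, 13.65, 387.6, NA, NA, NA,
    4L, "Ao_IV", 6.47, 12.9, 12.9, 400.0, NA, NA, NA,
    5L, "Ao_V", 15.2, 11.1, 11.1, 437.8, NA, NA, NA,
    6L, "Ao_VI", 1.8, 9.8, 9.8, 471.8, NA, NA, NA,
    7L, "Ao_VII", 0.7, 9.66, 9.66, 475.9, NA, NA, NA,
    8L, "Ao_VIII", 0.7, 9.585, 9.6, 478.1, NA, NA, NA,
    9L, "Ao_IX", 4.3, 9.31, 9.31, 486.5, NA, NA, NA,
    10L, "Ao_X", 4.3, 8.88, 8.88, 502.0, NA, NA, NA,
    11L, "brachiocephalic", 3.4, 6.35, 6.35, 612.0, 5.1918, 10.6080, 8.6974,
    12L, "l_carotid", 3.4, 3.6, 3.6, 860.4, 19.1515, 52.2129, 1.7670,
    13L, "l_subclavian", 3.4, 4.8, 4.8, 724.0, 9.8820, 13.0183, 7.0871,
    14L, "celiac", 3.2, 4.45, 4.45, 757.6, 11.7617, 7.5726, 12.1836,
    15L, "sup_mesenteric", 6, 3.75, 3.75, 839.6, 17.4352, 5.5097, 16.7453,
    16L, "r_renal", 3.2, 2.8, 2.8, 1000.4, 34.1378, 5.3949, 17.1017,
    17L, "l_renal", 3.2, 2.8, 2.8, 1000.4, 34.1378, 5.3949, 17.1017,
    18L, "inf_mesenteric", 5, 2.0, 2.0, 1224.2, 74.0167, 46.2252, 1.9959,
    19L, "r_iliac", 8.5, 6.0, 6.0, 633.3, 5.9149, 10.1737, 9.0686,
    20L, "l_iliac", 8.5, 6.0, 6.0, 633.3, 5.9149, 10.1737, 9.0686
  )
}

#' Benchmark case: full aorta with major branches
#'
#' Twenty constant-property vessel elements and 21 nodes: the thoracic and
#' abdominal aorta as ten segments in series, eight side branches
#' (brachiocephalic through inferior mesenteric) leaving at the inter-aortic
#' junctions, and a terminal bifurcation into the two common iliacs; ten
#' Windkessel terminations and one constant-flow heart source. Wall
#' thickness is 10 percent of the diastolic radius. Curved or tapered
#' vessels are represented as straight constant-radius elements at the mean
#' radius. The element-to-node wiring of the side branches follows the
#' standard anatomical ordering (the published schematic is not tabulated;
#' this wiring is the package's documented assumption).
#'
#' @return A `pw_case`.
#' @export
pw_case_full_aorta <- function() {
  tb <- full_aorta_table()
  # aortic chain nodes: heart = n0; junction after aortic segment i = n_i
  aorta_from <- c("heart", paste0("n", 1:9))
  aorta_to <- paste0("n", 1:10)
  # side branch k leaves the junction after aortic segment k - 10
  branch_from <- paste0("n", 1:8)
  branch_to <- paste0("wk_", tb$name[11:18])
  iliac_from <- c("n10", "n10")
  iliac_to <- paste0("wk_", tb$name[19:20])
  elements <- tibble::tibble(
    element = tb$name,
    from = c(aorta_from, branch_from, iliac_from),
    to = c(aorta_to, branch_to, iliac_to),
    length = tb$length_cm * 1e-2,
    radius_d = tb$rd_mm * 1e-3,
    radius_mean = tb$r0_mm * 1e-3,
    thickness = 0.1 * tb$rd_mm * 1e-3,
    modulus = tb$E_kPa * 1e3
  )
  wk <- tb[!is.na(tb$R1), ]
  nodes <- tibble::tibble(
    node = c("heart", paste0("n", 1:10), paste0("wk_", wk$name)),
    type = c("source", rep("junction", 10), rep("windkessel", 10)),
    zc = c(NA, rep(NA, 10), wk$R1 * 1e7),
    r = c(NA, rep(NA, 10), wk$R2 * 1e8),
    c = c(NA, rep(NA, 10), wk$C * 1e-10),
    zs = c(1e30, rep(NA, 20))
  )
  monitors <- tibble::tibble(
    position = c("p1", "p11", "p12", "p13", "p18", "p19"),
    element = c("Ao_I", "brachiocephalic", "l_carotid", "l_subclavian",
      "inf_mesenteric", "r_iliac"),
    frac = 0
  )
  new_case("full_aorta", elements, nodes, pw_fluid(1060, 4e-3), monitors,
    list(nh = 15, tol = 1e-6, n_time = 1000), "aorta", pd = 9.46e3)
}

#' Build a benchmark case by name
#'
#' @param name `"bifurcation"`, `"carotid"` or `"full_aorta"`.
#' @param severity Stenosis severity in percent (carotid case only).
#' @param ... Passed to the specific builder.
#' @return A `pw_case`.
#' @export
pw_case <- function(name = c("bifurcation", "carotid", "full_aorta"),
                    severity = 75, ...) {
  name <- match.arg(name)
  switch(name,
    bifurcation = pw_case_bifurcation(...),
    carotid = pw_case_carotid(severity, ...),
    full_aorta = pw_case_full_aorta()
  )
}
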