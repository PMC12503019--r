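---
title: "Frequency-domain pulse-wave networks: model, conventions and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain pulse-wave networks: model, conventions and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsenet)
```

## Scope and assumptions

`pulsenet` solves periodic, one-dimensional pulse-wave propagation on a
network of compliant vessels in the frequency domain. The core assumptions
are:

* **Linearity of propagation.** Convective nonlinearities are weak in
  normal vessels; pulse transport along each segment is linear and can be
  solved per harmonic. Nonlinearity enters only as *localized* quasi-steady
  losses at stenoses, aneurysms and bifurcations.
* **Thin elastic walls.** The wave speed follows the Moens–Korteweg form
  with a Poisson-ratio correction, default incompressible wall (ν = 0.5).
  A complex Young's modulus is accepted as a hook for wall viscoelasticity,
  but no constitutive model is shipped.
* **Womersley viscous flow.** The frequency-dependent friction function
  F(α) modifies wave number and characteristic impedance; at 0 Hz the
  segment degenerates to its Poiseuille resistance. A complex Womersley
  number is accepted (Maxwellian-fluid hook) but not modelled.
* **Periodic excitation.** The inflow is T-periodic; all fields are
  represented by harmonics 0..Nh of the heart rate. Transients are out of
  scope.

## Time and phase conventions

All spectra use the analysis kernel `exp(-i n ω₀ t)` (the harmonic
amplitude of a cosine is real positive), and signals are reconstructed as

x(t) = x̂₀ + Σₙ Re[ x̂ₙ exp(+i n ω₀ t) ].

Under this standard transform pair the element phase factor `exp(-iκx)`
propagates toward +x as time advances, so decay of the forward wave
requires **Re κ > 0, Im κ ≤ 0**, and the Windkessel capacitor admittance is
`+iωC`. One test locks the convention by propagating a synthesized crest.
The square-root branch in `κ = (ω/c₀)/√(1-F)` and in Z₀ is the principal
branch, which on the physical ray yields exactly this decaying signature;
`wave_number()` asserts it and errors rather than silently amplifying.

The branch convention is a genuine free choice (the decay requirement does
not follow from the defining formulas alone); we adopt
"forward waves never amplify", asserted as `|exp(-iκL)| ≤ 1` for all
ω > 0, μ ≥ 0.

## Womersley friction function

`womersley_F()` evaluates `F = 2J₁(z)/(z J₀(z))` with `z = α·i^{3/2}`,
`i^{3/2} = exp(i3π/4)` (principal branch, Womersley's classical choice).
Base R's Bessel functions are real-only, so the complex ratio is computed
in-package:

* **|z| ≤ 30**: ascending power series of J₀ and J₁. On the `i^{3/2}` ray
  the series has essentially no cancellation because |J₀| itself grows like
  `exp(|z|/√2)`; measured accuracy is ~1e-13.
* **|z| > 30**: Hankel asymptotic expansion, written in terms of the
  exponentially dominant half of cos/sin so that it neither overflows nor
  cancels for large imaginary parts; truncated at the smallest term.

The implementation was validated against an independent 50-digit
series oracle on a grid α ∈ [0.01, 50] (frozen into the tests; agreement
better than 1e-10) and spot values up to α = 1000 (~1e-16).

## Elements

**Uniform vessel.** Scattering matrix `S = [[0, e^{-iκL}], [e^{-iκL}, 0]]`;
backward transfer matrix `T = [[cos κL, iZ₀ sin κL], [i sin κL/Z₀, cos κL]]`.
At 0 Hz, `T = [[1, 8μL/(πR⁴)], [0, 1]]`.

**Wave/state conversions.** `transfer_to_scattering()` /
`scattering_to_transfer()` convert between the two forms using the port
relations `p = p⁺ + p⁻`, `q₁ = (p₁⁺ - p₁⁻)/Z₁`, `q₂ = (p₂⁻ - p₂⁺)/Z₂`
(flow positive inlet→outlet), allowing distinct port impedances for
composite elements. Round-trips are identity to ~1e-12 (property-tested on
randomized two-ports).

**Radius roles.** The wave-speed formula uses the effective radius
`R_d²/R₀` (diastolic squared over time-averaged); lumen areas in Z₀ and the
Poiseuille resistance use R₀. The optional outer iteration
(`mean_radius_iter = TRUE`) updates R₀ from the local steady pressure with
wall stiffness `K = Eh/((1-ν²)R_d²)`, treating the diastolic state as
stress-free; on the aortic-bifurcation benchmark it settles in two passes
and moves radii by a few percent, which is why it is off by default.

**Tapered vessels** are discretized into straight segments with the local
radius, a `cos θ/cos(θ/2)` wave-speed correction (θ = tangent angle), and
segment length at most 1/5 of the shortest wavelength at the highest
requested harmonic. The first and last segments are anchored at the exact
port radii: this keeps the port characteristic impedances exact and makes
the discretization second-order (halving the segment length at the rule's
resolution moves the transmission coefficient by well under 0.1%).

**Defects.** A stenosis/aneurysm splits the vessel into
parent–throat–parent with Borda–Carnot losses lumped at the two area jumps
(`T_def = T₁·T_nl,in·T₂·T_nl,out·T₃`), or, in conical mode, linear-taper
transitions with a single lumped loss carrying the total C_L. The loss
resistance

R_nl = δₙ ρ₀ |q₀| C_L (1-σ)²/(2 A_ref²)

is referenced to the smaller lumen on each side of the jump: for a
stenosis `A_ref = A_s`, σ = A_s/A₀; for an aneurysm `A_ref = A₀`,
σ = A₀/A_s; for a junction branch with no area change σ = 0. This is the
classical Borda–Carnot sudden-expansion coefficient, including the 1/2
velocity-head factor. δₙ is 1 at DC and exactly 2 for every oscillating
harmonic — the cross term of linearizing `q(t)²` about its dominant steady
part. Stenosis defaults C_L,in = 0.52 (sudden contraction, measured
contraction+expansion total 1.52) and C_L,out = 1 (sudden expansion),
swapped for an aneurysm; both are user-overridable. |q₀| is used so losses
oppose flow in either direction. The severity quoted in percent is
`(1 - A_s/A₀)·100` — a distinct quantity from the contraction ratio σ.

**Boundary one-ports.** WK3: `Z_wk = Z_c + (iωC + 1/R)^{-1}`, so
`Z_wk(0) = Z_c + R = R_t` and `Z_wk(∞) → Z_c`; reflection
`R_wk = (Z_wk - Z₀)/(Z_wk + Z₀)` becomes anechoic at high frequency when
`Z_c` matches the terminal impedance. Heart: active one-port
`p̂⁺ = R_s p̂⁻ + p̂⁺ˢ` with `R_s = (Z_s - Z₀)/(Z_s + Z₀)`; a source
impedance of 1e30 Pa·s/m³ prescribes the inflow exactly (verified to
1e-12 at the port).

## Network assembly and solution

Elements are declared in a tibble with `from`/`to` node ids; incident
amplitudes are ordered `(element, port)` in declaration order, giving
reproducible matrices. For each node the scattering matrix maps
node-incident waves (element outgoing) to node-outgoing waves: an ideal
junction has `S = 2Y_k/ΣY - δ_jk` (equal port pressures, conserved flow);
a lossy junction chains per-branch series resistances to an interior ideal
node and is solved from the port relations; terminations are the scalar
reflection coefficients above. Globally, `A = I - S_N S_E` and
`A p̂⁺ = q̂ˢ` is solved densely per frequency (40×40 for the full-aorta
benchmark; frequencies are independent, and identical results are required
regardless of evaluation order). The condition number of every A is
estimated by SVD and the solve refuses past 1e14; observed values are
below ~300 on all benchmarks. Linear residuals are logged (~1e-16).

**DC handling.** ω = 0 never evaluates the oscillatory formulas. Elements
use the Poiseuille ladder; the wave decomposition at DC uses the element's
inviscid characteristic impedance as reference. Any consistent positive
reference yields the same physical (p, q) field — this is asserted by the
independent-solver comparison, which has no notion of wave amplitudes.

**Nonlinear iteration.** Loss resistances depend on the steady flow q₀
through each defect/branch. The solver starts with all R_nl = 0 (pure
linear pass), extracts q₀ from the 0 Hz solution, rebuilds, and repeats
until the largest relative q₀ change is below 1e-6 (cap 50, optional
under-relaxation exposed for pathological inputs but unused by the
benchmarks). With an ideal flow source feeding a single-vessel chain the
DC flow is fixed by the source, so the benchmark stenosis converges in 2
passes; the update norm is asserted to decrease monotonically. Networks
with no loss sites solve exactly once.

**Field reconstruction.** `field_at()` cascades partial transfer matrices
from the inlet port state; within a homogeneous span this equals the free
wave field, at DC the resistive ladder, and for composites the chain is
walked piece by piece (2×2 inverses are applied explicitly — the matrices
are unimodular but can be badly scaled, which trips LAPACK's reciprocal
condition guard spuriously).

## Independent verification solver

`solve_nodal()` re-solves any network from nodal pressures and element
port flows (impedance formulation, equilibrated by column/row scaling),
sharing only the element transfer matrices with the main solver. It runs
its own nonlinear loop. Agreement on the three benchmarks and randomized
looped networks is ~1e-14, far inside the 1e-8 gate used by the tests.

## Synthetic inflow generator

The published benchmark inflows exist only as figures, so `pw_inflow()`
generates a parameterized stand-in: a raised-cosine systolic ejection over
a diastolic baseline, with the baseline set so the period mean is exact.
Presets were fixed once from physiology and are deliberately not tuned to
any output:

* `carotid`: mean 6 mL/s (common-carotid flow; also consistent with the
  benchmark's total peripheral resistance times a ~13 kPa mean pressure),
  period 1.1 s, systole fraction 0.4, peak 9.33 mL/s chosen so the first
  harmonic is one quarter of the steady component — the documented
  spectral signature of this benchmark's inflow.
* `aortic_bifurcation`: mean 7.8 mL/s (abdominal aorta; gives ~12.3 kPa
  mean pressure against the tabulated Windkessels), peak 45 mL/s, period
  1.1 s.
* `aorta`: mean 92 mL/s (~5.5 L/min cardiac output; ~10.7 kPa mean
  pressure against the ten tabulated beds), peak 460 mL/s, period 1 s.

What the generator does **not** emulate: early-diastolic backflow, the
dicrotic notch of measured aortic inflow, beat-to-beat variability, and
measurement noise. Consequently the benchmark runs validate solver
physics (conservation, convergence, limits, cross-solver agreement) and
produce physiologically shaped waveforms, but they do not reproduce the
published waveform-error tables against 3D reference data, whose exact
inflows and reference waveforms are not tabulated. Golden files for the
three benchmark cases are self-generated regression anchors, not external
references.

## Benchmark fixtures

* **Aortic bifurcation**: aorta (86 mm, R_d 8.6 mm, R₀ 8.9 mm, h 1.032 mm,
  E 500 kPa) into two identical iliacs (85 mm, R_d 6 mm, R₀ 6.15 mm,
  h 0.72 mm, E 700 kPa), tabulated WK3 at each iliac. The junction-loss
  variant applies C_L = 0.1 on both downstream paths, referenced to the
  iliac area with σ = 0 — the inlet branch carries no loss two-port.
* **Carotid stenosis**: 126 mm vessel with a 48 mm throat centred 39 mm
  from the inlet (the symmetric split of the remaining length; the
  published geometry does not fix it), severity ∈ (0, 100).
* **Full aorta**: ten aortic segments in series, eight side branches
  leaving at the inter-aortic junctions in anatomical order
  (brachiocephalic → inferior mesenteric; the ninth junction, between
  segments IX and X, carries no branch), terminal iliac bifurcation;
  h = 0.1·R_d; constant-radius elements at the mean radius (tapering the
  aortic segments changes results negligibly). The exact element-to-node
  wiring is this package's documented assumption since the source
  schematic is not tabulated.

## Numerical choices and degenerate inputs

* Default Nh = 15 harmonics (heart-signal energy concentrates in the first
  ~10 orders; margin added), 1000 samples per period for synthesis and
  metrics — both user-overridable. Test and verification runs use 64–256
  samples and these problem sizes throughout, which keeps the whole suite
  in seconds.
* Flow error metrics normalize by max(reference flow) — including the
  diastolic error — because reference flows cross zero; pressure metrics
  normalize pointwise. Systolic/diastolic errors are signed.
* Zero-length elements, zero viscosity (exact inviscid limits), zero pulse
  amplitude, empty monitor lists and sourceless networks (zero field, not
  an error) are all exercised by tests.
* Determinism: no randomness anywhere in the solver; re-runs are
  bit-identical. The randomized verification networks take explicit seeds.

## Known limitations

* No time-domain transients or nonlinear heart coupling; the causal
  scattering form is the enabling structure but the coupling itself is
  not implemented.
* Two-port *sources* (e.g. turbulence noise at a stenosis) have slots in
  the data model (`B p̂⁻ˢ`) but no physical model; element source vectors
  are zero.
* Junction multiport matrices from CFD/system identification are not
  computed here; only ideal and Borda–Carnot-lossy junctions are built in.
* Wall viscoelasticity and Maxwellian fluids are accepted as complex
  E / α inputs only.
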