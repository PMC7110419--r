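---
title: "Montage optimization for transcranial electrical stimulation: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Montage optimization for TES: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tesopt)
```

## The forward model

The quasistatic electric potential in the head obeys a Poisson equation
with Neumann boundary conditions; `tesopt` discretizes it with linear (P1)
tetrahedral finite elements and the Galerkin approach. Assembly produces
the sparse symmetric stiffness matrix `K` with the constant vector in its
null space (pure Neumann); the system is grounded by fixing the potential
of the node nearest the mesh centroid to zero. Every reported quantity is a
potential difference or a field, so the grounding node is immaterial — a
property the test suite checks by re-solving reflected geometries. Solves
use a cached sparse Cholesky factorization rather than an iterative method:
at the problem sizes this package targets (10^4–10^5 nodes) a direct solve
is faster once the factorization is reused across the `L − 1` transfer
columns, reruns are bit-identical, and the algebraic residual (~1e−14)
is far below the 1e−8 contract enforced in `solve_forward()`.

Electrodes are pointwise: each is attached to the nearest outer-surface
node and injects its current as a nodal source. The complete electrode
model (finite contact area and impedance) is out of scope; at the 1–2 mA,
64-channel operating point of interest the pointwise approximation is the
standard simplification and is what the optimization theory assumes.

The transfer matrix `T` stores, per brain element, the electric field
`E = −∇ψ` for a unit current at electrode `l` returned through the
reference electrode `L`. Linearity of the forward map makes each column one
forward solve, and the field of any pattern is `T i`.

## Reciprocity and the lead field

The EEG lead field `L` (potentials at the electrodes due to unit dipoles in
the brain) is related to `T` by transposition, `T = Lᵀ`. `dipole_leadfield()`
computes `L` by the independent EEG route — one partial-integration dipole
load per element and canonical direction, solved against the cached
factorization — precisely so that the identity can be *tested* rather than
assumed. One convention note: with `T` storing the field `E` (not `∇ψ`),
the load that makes `L = Tᵀ` hold sign-exactly is `b_i = −m·∇φ_i`, the
negative of the classical EEG source convention. The identity, not the sign
convention, carries all the structure used downstream: the synthetic
potential `Φ_Γ = Tᵀ Γ d s` needs no dipole solves at all, and its electrode
extrema locate the reciprocity montage.

The analytic verification oracle is the homogeneous-sphere surface
potential of a surface point source, whose Legendre series sums in closed
form (see `sphere_surface_potential()`); the FEM solution is required to
match it within 2% relative RMS away from the injection sites, with the
error decreasing under refinement.

## The synthetic head model

`generate_sphere_head()` builds 4 nested spherical shells — brain, CSF,
skull, scalp with default outer radii 80/81/86/92 mm and conductivities
0.33/1.79/0.006/0.3 S/m — from concentric copies of a subdivided
icosahedron: a tetrahedral fan inside the innermost shell and three
tetrahedra per prism between shells, with prism diagonals fixed by vertex
order so the mesh conforms. Tissue labels are assigned per shell gap, so
even the 1 mm CSF layer is labelled exactly. The seed drives a random rigid
rotation of the tessellation and of the Fibonacci electrode lattice, which
decorrelates the icosahedral symmetry axes from the coordinate axes while
keeping runs reproducible.

What the model emulates: realistic layer radii, conductivity contrasts
(notably the resistive skull and conductive CSF), electrode counts and
current scales, and an ROI with a cortex-normal orientation field. What it
does not: cortical folding, anisotropic white matter, skull
inhomogeneities, real 10–10 electrode positions. Tests passing on spheres
therefore validate the *solvers and the theory's structural claims*
(reciprocity, limit cases, sweep morphology) — not clinical field
predictions for an individual head. Mesh resolution is set by
`edge_length`; the outer surface is chordal, so enclosed volume runs ~1–3%
low at coarse settings (the generator warns beyond 5%). The default 13–16 mm
edge gives ~3·10^4 elements, which keeps every pipeline stage in seconds
on one CPU; the acceptance checks state their sizes explicitly.

## The optimizer family

All methods are instances of: maximize the volume-integrated directional
ROI field `dᵀΓT i` subject to a non-ROI field bound, the `ℓ₁` budget
`‖ĩ‖₁ ≤ 2 i_max`, and per-electrode boxes.

* `wls_closed_form()` — the energy-only solution
  `(TᵀΓ_nonROI T)⁻¹ TᵀΓd·k`. With `alpha_i` given, `k(α_I)` places the
  solution exactly on the energy boundary; with `k` given it is the
  classical (W)LS fit to the desired field `k d`. Exact-mode weights keep
  the ROI out of the energy matrix; approximate mode (`Γ_nonROI := Γ`)
  reproduces the literal WLS normal equations — the difference is a few
  tenths of a percent for cm-scale ROIs.
* `scaled_wls()` — the same direction rescaled to spend exactly `2 i_max`:
  the montage at critical point `a`.
* `constrained_wls()` — the WLS misfit under budget and box constraints,
  a linearly-constrained QP.
* `dirmax()` — the full problem, integral or elementwise bound.
* `reciprocity_one_to_one()` / `reciprocity_limited()` — the loose-bound
  closed forms; the limited variant fills sources at `+c₊` from the top of
  `Φ_Γ` and sinks at `−c₋` from the bottom until `i_max` is reached, the
  last electrode taking the fractional remainder when `i_max/c` is not an
  integer (ties broken to the lowest electrode index; both choices are
  deterministic conventions where the theory is silent).

## Convex solver strategy

The only installed convex-programming primitive is the Goldfarb–Idnani
dual active-set QP (`quadprog`), which handles strictly convex quadratic
objectives with linear inequality constraints. The three problem classes
are reduced to it:

* **ℓ₁ budget** — auxiliary magnitude variables `t ≥ |ĩ|`,
  `Σt ≤ 2 i_max`: linear constraints. A ridge of 1e−10–1e−11 (relative to
  the normalized objective scale) keeps the Hessian positive definite when
  the quadratic part vanishes; the induced bias is orders of magnitude
  below every tolerance asserted in the tests.
* **Integral bound (QCLP)** — bisection on the Lagrange multiplier μ of
  the quadratic constraint. The inner problem
  `max cᵀi − μ iᵀQi` s.t. budget/box is a QP; its non-ROI energy is
  monotone non-increasing in μ, and the energy-only closed form provides
  an upper bracket for μ. When the bound is slack (large α) μ is shrunk
  until the pattern converges to the corner solution; otherwise log-
  bisection drives the energy to the boundary with relative tolerance
  1e−10 in μ, which realizes the "constraint active with equality"
  property of the theory to ~1e−9.
* **Elementwise bound (SOCP)** — outer linearization: each violated cone
  `‖T_n i‖ ≤ α_E` contributes its supporting hyperplane at the current
  iterate, the worst 40 violations per round, until the largest relative
  violation is ≤ 1e−7 (typically 20–40 master QPs). This is exact outer
  approximation for convex cones; the iteration cap (400) surfaces as a
  non-`optimal` status rather than a silent wrong answer.

Currents are internally scaled by `i_max` and the objective normalized to
O(1) before the QP sees them, which keeps the active-set solver in its
comfortable numerical range across the ~6 decades of α a sweep spans.

These reductions are what make the package's central cross-checks
meaningful: `dirmax()` never calls the closed forms, so the low-α/WLS and
high-α/reciprocity matches (asserted at 1e−3 relative, the package's
definition of "equivalent patterns") are genuine numerical verifications
of the limit-case theorems, as are the constrained-WLS equivalences under
the induced bound `α′ = îᵀTᵀΓTî`.

## Sweeps, critical points, focality

`alpha_sweep()` solves `dirmax()` on a log-spaced grid (default 40 points)
anchored by the two closed forms: the lower end at a fraction of the
scaled-WLS energy, the upper end beyond the reciprocity pattern's energy
(for the elementwise mode, the anchors use the reciprocity pattern's
maximum non-ROI field and the low-bound linearity of the budget in α_E).
The grid auto-extends until both the budget-slack and bound-slack regimes
are present. Zones are labelled from the active-constraint flags — pink
(bound active, budget slack), white (both active), blue (budget active,
bound slack) — and the critical points are defined operationally: `a` is
the smallest α with ≥ 99.5% budget use, `b` the smallest α whose pattern
is within 1e−3 relative of the reciprocity closed form. Both thresholds
are package conventions for what the theory identifies visually; the tests
assert the budget is strictly below 100% before `a` and the pattern frozen
beyond `b`. For elementwise sweeps an informational point `c` marks the
steepest log-log decrease of the elementwise focality.

Focality metrics divide the mean directional ROI intensity by the root
mean non-ROI energy (integral) or by the maximum non-ROI field
(elementwise). Both are scale-invariant; both are always computed with
exact non-ROI weights so that sweeps of either mode are comparable. Each
metric is provably at least as good on its own solution family as on the
other at matched intensity (the family traces the optimal frontier of
exactly that ratio); the acceptance suite verifies this numerically,
interpolating only the non-extremal cross curve — interpolating the steep
frontier itself between grid points would spuriously underestimate it.

## Degenerate inputs and edge cases

A zero orientation field yields the zero montage (objective 0) rather than
an error; an ROI whose projected surface normals average to zero (antipodal
walls) is an error, since no single orientation represents it. An ROI
covering the whole domain zeroes `Γ_nonROI` and makes the energy bound
vacuous — `dirmax` then runs against budget and box alone. Rank-deficient
normal equations fall back to the pseudo-inverse with a warning.
`reciprocity_limited` rejects infeasible limit combinations
(`⌈i_max/c₊⌉ + ⌈i_max/c₋⌉ > L`). Patterns serialized to CSV write the
reference electrode as the negative sum of the serialized values, so files
sum to zero as parsed.

## Known limitations

Isotropic conductivities only (the conductivity type reserves a tensor
slot, but the assembler refuses tensors rather than silently ignoring
them); single connected ROI with one orientation field; pointwise
electrodes; no electrode-count-limited (combinatorial) formulations; no
modulus-maximization (non-convex) objective. The elementwise solver's
cutting-plane master grows with the number of active cones, which is
efficient on cm-scale ROIs but would need a different master for bounds
active over most of the domain.
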