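# tesopt — unified optimal targeting for transcranial electrical stimulation

High-density transcranial electrical stimulation (TES/tDCS) injects weak
currents through scalp electrodes to modulate a target brain region. Given a
head model, a region of interest (ROI) with a desired field orientation
**d**, and safety limits on the currents, the montage problem is: how much
current should each electrode carry so the directional electric field in the
ROI is as strong as possible while the field elsewhere stays bounded?

`tesopt` implements the whole family of answers in one framework. The core
problem is the constrained directional maximization

```
maximize   d' Γ T i
subject to i' T' Γ_nonROI T i ≤ α_I        (integral non-ROI energy bound)
      or   ‖T_n i‖₂ ≤ α_E  ∀ n ∈ non-ROI  (elementwise field bound)
           ‖ĩ‖₁ ≤ 2 i_max                  (total current budget)
           ĩ_min ≼ ĩ ≼ ĩ_max               (per-electrode limits)
```

where `T` is the 3N × (L−1) electric-field transfer matrix of the FEM head
model, `Γ` the diagonal matrix of element volumes, `i` the independent
injection pattern and `ĩ = H i` its expansion obeying Kirchhoff's law. The
two classical closed forms are the extreme cases of this single problem in
the non-ROI bound α:

* **tight bound (small α)** — the weighted-least-squares montage
  `î = (T' Γ_nonROI T)⁻¹ T' Γ d · k(α_I)` with
  `k(α_I) = sqrt(α_I / d' Γ T (T' Γ_nonROI T)⁻¹ T' Γ d)`;
* **loose bound (large α)** — the reciprocity montage: source and sink at
  the extrema of the synthetic EEG potential `Φ_Γ = T' Γ d · s`, each at
  `i_max` (and, under uniform per-electrode limits, its multi-source /
  multi-sink "patch" generalizations).

Between the two, sweeping α traces the intensity–focality trade-off with
two critical points: `a`, where the budget saturates (the optimally *scaled*
WLS montage), and `b`, where the solution freezes at the reciprocity corner.
Focality is quantified as the mean directional ROI intensity divided by
either the root-mean non-ROI energy (integral metric) or the maximum
non-ROI field magnitude (elementwise metric).

Everything runs on synthetic 4-layer concentric-sphere head models (brain,
CSF, skull, scalp; conductivities 0.33/1.79/0.006/0.3 S/m by default)
meshed from concentric icosphere shells, so no external data is needed;
Gmsh MSH 2.2 meshes can be imported for real geometries.

## Worked example

```r
library(tesopt)

hd <- generate_sphere_head(edge_length = 0.016, n_electrodes = 64, seed = 1)
sys <- assemble_fem(hd$mesh, conductivity_map(
  c(brain = 0.33, csf = 1.79, skull = 0.006, scalp = 0.3)))
tm  <- build_transfer_matrix(sys, hd$electrodes)

roi    <- select_roi_sphere(hd$mesh, c(0, 0, 0.070), 0.015)
target <- define_roi_orientation(hd$mesh, roi, tm)   # normal-to-cortex d
w      <- build_volume_weights(tm, target, "exact")

opt <- dirmax(tm, w, target, constraint_set(1e-3, tm$L, alpha_i = 1e-6))
opt
#> tes_optimum [dirmax_integral]: objective 1.7253e-06 V/m m^3, budget 2.0000 mA, status optimal
#>   active constraints: energy, budget
mean_roi_intensity(opt$pattern, tm, w, target)   # 0.1345 V/m
integral_focality(opt$pattern, tm, w, target)    # 6.185

sw <- alpha_sweep(tm, w, target, constraint_set(1e-3, tm$L), "integral")
sw
#> tes_sweep (integral): 28 points, alpha in [8.959e-09, 1.165e-03]
#>   critical a = 2.9345e-07, b = 5.5015e-05
#>   zones: blue (8), pink (8), white (12)
plot(sw)
```

Reading the output: at `alpha_i = 1e-6` (between `a` and `b`) both the
energy bound and the 2 mA budget are active — the trade-off zone. The sweep
splits the α axis into the "pink" zone (budget unused, WLS-shaped montages,
highest focality), the "white" transition zone, and the "blue" zone (bound
slack, the two-electrode reciprocity montage, highest intensity ~0.28 V/m
here but lowest focality). `cross_focality_curves()` compares the integral-
and elementwise-constrained families at matched ROI intensity.

A command-line driver for the same pipeline lives in `inst/cli/tesopt.R`
(`make-head`, `transfer`, `optimize`, `sweep`, `report` stages driven by a
YAML config; see `?read_run_config`).

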