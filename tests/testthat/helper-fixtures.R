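# Shared fixtures, built once per test run and memoized. Two sphere head
# models: a tiny 20-electrode one for unit tests and a coarse 64-electrode
# one for the acceptance checks. Literature-standard tissue conductivities
# (scalp 0.3, skull 0.006, CSF 1.79, brain 0.33 S/m) throughout.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

std_conductivities <- function() {
  conductivity_map(c(brain = 0.33, csf = 1.79, skull = 0.006, scalp = 0.3))
}

# build head model + FEM + transfer + ROI target + weights in one go
build_fixture <- function(edge, radial, n_elec, seed, roi_centre, roi_radius) {
  hd <- generate_sphere_head(edge_length = edge, radial_spacing = radial,
                             n_electrodes = n_elec, seed = seed)
  sys <- assemble_fem(hd$mesh, std_conductivities())
  tm <- build_transfer_matrix(sys, hd$electrodes)
  roi <- select_roi_sphere(hd$mesh, roi_centre, roi_radius)
  target <- define_roi_orientation(hd$mesh, roi, tm)
  list(mesh = hd$mesh, electrodes = hd$electrodes, sys = sys, tm = tm,
       roi = roi, target = target,
       w_exact = build_volume_weights(tm, target, "exact"),
       w_approx = build_volume_weights(tm, target, "approximate"))
}

# tiny: ~6k tets, 20 electrodes; sub-second solves
fix_tiny <- function() memo_fixture("tiny",
  build_fixture(edge = 0.028, radial = 0.020, n_elec = 20, seed = 7,
                roi_centre = c(0, 0, 0.070), roi_radius = 0.018))

# standard: ~28k tets, 64 electrodes; the acceptance-scale model
fix_std <- function() memo_fixture("std",
  build_fixture(edge = 0.016, radial = 0.016, n_elec = 64, seed = 1,
                roi_centre = c(0, 0, 0.070), roi_radius = 0.015))

rel_l2_err <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# hand-built 3-element toy transfer system for pencil-and-paper metric
# checks: element volumes 1, 1, 2 m^3; element 1 is the ROI with d = +x.
# Two independent electrodes; fields chosen by construction.
toy_system <- function(M = NULL) {
  if (is.null(M)) {
    # columns: field response (V/m per A) of each independent electrode
    M <- cbind(c(1, 0, 0,  0.5, 0, 0,  0, 0.25, 0),
               c(0, 1, 0,  0, -0.5, 0,  0.25, 0, 0))
  }
  tm <- structure(list(M = M, elements = 1:3, volumes = c(1, 1, 2),
                       labels = c("E1", "E2", "E3"), L = 3L),
                  class = "transfer_matrix")
  target <- structure(list(roi_elements = 1L, roi_local = 1L,
                           d = c(1, 0, 0, rep(0, 6)),
                           mean_orientation = c(1, 0, 0),
                           roi_volume = 1, nonroi_volume = 3),
                      class = "target_spec")
  list(tm = tm, target = target,
       w = build_volume_weights(tm, target, "exact"))
}
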