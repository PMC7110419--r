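# Transfer matrix and lead field: superposition and reciprocity.

test_that("two-electrode transfer matrix equals the direct forward solve", {
  fx <- fix_tiny()
  el <- fx$electrodes
  pair <- electrode_set(el$positions[c(2, 11), ], el$node_index[c(2, 11)],
                        c("A", "B"))
  tm <- build_transfer_matrix(fx$sys, pair)
  expect_equal(ncol(tm$M), 1L)
  fwd <- solve_forward(fx$sys, pair, c(1, -1))
  expect_equal(matrix(tm$M, ncol = 3, byrow = TRUE),
               fwd$field[tm$elements, ], tolerance = 1e-12)
})

test_that("transfer matrix obeys superposition", {
  fx <- fix_tiny()
  tm <- fx$tm
  L <- tm$L
  set.seed(11)
  i <- rnorm(L - 1) * 1e-3
  direct <- solve_forward(fx$sys, fx$electrodes,
                          expand_pattern(i))$field[tm$elements, ]
  viaT <- pattern_field(tm, i)
  expect_lt(max(abs(viaT - direct)) / max(abs(direct)), 1e-10)
  # column norms finite and non-zero
  cn <- sqrt(colSums(tm$M^2))
  expect_true(all(is.finite(cn)) && all(cn > 0))
})

test_that("lead field is the transpose of the transfer matrix (reciprocity)", {
  fx <- fix_tiny()
  # independent EEG-route computation on a subset of brain elements
  # (away from the ground node, where the dipole load is well defined)
  sub <- fx$tm$elements[seq(1, length(fx$tm$elements), by = 40)]
  touches_gnd <- apply(fx$mesh$tets[sub, ] == fx$sys$ground_node, 1, any)
  sub <- sub[!touches_gnd]
  lf <- dipole_leadfield(fx$sys, fx$electrodes, sub)
  tm_sub <- build_transfer_matrix(fx$sys, fx$electrodes, sub)
  expect_lt(max(abs(lf$M - t(tm_sub$M))) / max(abs(tm_sub$M)), 1e-6)
})

test_that("lead field is linear in the dipole moment", {
  fx <- fix_tiny()
  sub <- fx$tm$elements[c(401, 1200)]
  lf <- dipole_leadfield(fx$sys, fx$electrodes, sub)
  m <- c(3, -1, 2)
  # potentials of an arbitrary moment = linear combination of canonical ones
  pot <- lf$M[, 1:3] %*% m
  pot3 <- lf$M[, 1:3] %*% (3 * m)
  expect_equal(as.numeric(pot3), 3 * as.numeric(pot), tolerance = 1e-14)
})

test_that("near-centre radial dipole matches the analytic sphere series", {
  # homogeneous sphere, radial dipole in an element near the centre.
  # Analytic oracle: an axial dipole of moment m at radius b inside a
  # homogeneous sphere (insulating boundary) produces the surface potential
  #   phi(theta) = m / (4 pi sigma R^2) * sum_n (2n+1) (b/R)^(n-1) P_n(cos theta)
  # with theta measured from the dipole axis (only zonal terms for a
  # radial moment on the axis).
  hd <- generate_sphere_head(edge_length = 0.028, radial_spacing = 0.010,
                             n_electrodes = 24, seed = 5)
  sigma <- 0.33; R <- 0.092
  sys <- assemble_fem(hd$mesh, conductivity_map(
    c(brain = sigma, csf = sigma, skull = sigma, scalp = sigma)))
  rc <- sqrt(rowSums(hd$mesh$centroids^2))
  touches_gnd <- apply(hd$mesh$tets == sys$ground_node, 1, any)
  ctr <- which(!touches_gnd)[which.min(rc[!touches_gnd])]
  x0 <- hd$mesh$centroids[ctr, ]
  b <- sqrt(sum(x0^2))
  axis <- x0 / b
  lf <- dipole_leadfield(sys, hd$electrodes, ctr)
  pot <- as.numeric(lf$M %*% axis)        # unit radial moment, ref-relative
  en <- hd$electrodes$node_index
  ct <- as.numeric((hd$mesh$nodes[en, ] %*% axis) / R)
  ana_full <- numeric(length(ct))
  p_prev <- rep(1, length(ct)); p_cur <- ct
  acc <- 3 * p_cur                         # n = 1 term
  for (n in 2:40) {
    p_next <- ((2 * n - 1) * ct * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) * (b / R)^(n - 1) * p_next
    p_prev <- p_cur; p_cur <- p_next
  }
  # the package's lead field uses the source-sign convention that makes
  # L = T^T with the E-field transfer matrix, which is the negative of the
  # classical EEG potential: compare against the negated series
  ana_full <- -acc / (4 * pi * sigma * R^2)
  ana <- ana_full[-length(ana_full)] - ana_full[length(ana_full)]
  # the P1 partial-integration load is identical for any dipole position
  # inside the element, so the comparison carries an O(h) position
  # ambiguity: ~ (5/3) * (element extent) / R ~ 9% here, on top of ~2%
  # FEM error. The discrete reciprocity identity is tested at 1e-6
  # separately; this check pins down the physical sign and scale.
  expect_lt(sqrt(mean((pot - ana)^2) / mean(ana^2)), 0.12)
})
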