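# FEM assembly and forward solves.

test_that("single-tet stiffness annihilates constants and is symmetric", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh <- head_mesh(nodes, rbind(1:4), 1L)
  sys <- assemble_fem(mesh, c(1))
  K <- as.matrix(sys$K)
  expect_lt(max(abs(K %*% rep(1, 4))), 1e-12 * max(abs(K)))
  expect_lt(max(abs(K - t(K))), 1e-12 * max(abs(K)))
})

test_that("stiffness is linear in conductivity", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  mesh <- head_mesh(nodes, rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L)),
                    c(1L, 2L))
  K1 <- as.matrix(assemble_fem(mesh, c(0.3, 1.5))$K)
  K2 <- as.matrix(assemble_fem(mesh, 2 * c(0.3, 1.5))$K)
  expect_equal(K2, 2 * K1, tolerance = 1e-14)
})

test_that("head stiffness is symmetric with constant null space", {
  fx <- fix_tiny()
  K <- fx$sys$K
  ones <- rep(1, nrow(K))
  expect_lt(max(abs(K %*% ones)) / max(abs(K)), 1e-12)
  expect_lt(max(abs(K - Matrix::t(K))) / max(abs(K)), 1e-12)
})

test_that("forward solve is linear and rejects bad patterns", {
  fx <- fix_tiny()
  L <- n_electrodes(fx$electrodes)
  pat <- numeric(L); pat[1] <- 1e-3; pat[L] <- -1e-3
  s1 <- solve_forward(fx$sys, fx$electrodes, pat)
  s2 <- solve_forward(fx$sys, fx$electrodes, 2 * pat)
  expect_equal(s2$potential, 2 * s1$potential, tolerance = 1e-12)
  expect_equal(s2$field, 2 * s1$field, tolerance = 1e-12)
  expect_lt(s1$residual, 1e-8)
  z <- solve_forward(fx$sys, fx$electrodes, numeric(L))
  expect_true(all(z$potential == 0) && all(z$field == 0))
  expect_error(solve_forward(fx$sys, fx$electrodes, rep(1e-3, L)), "Kirchhoff")
  expect_error(solve_forward(fx$sys, fx$electrodes, pat[-1]), "length")
})

test_that("solution transforms correctly under mesh reflection", {
  # reflecting the geometry and the montage must reflect the solution:
  # an independent re-assembly + re-solve on the mirrored mesh
  fx <- fix_tiny()
  mesh <- fx$mesh
  refl <- mesh$nodes %*% diag(c(1, 1, -1))
  mesh2 <- head_mesh(refl, mesh$tets, mesh$tissue, mesh$tissue_names)
  sys2 <- assemble_fem(mesh2, std_conductivities())
  el <- fx$electrodes
  el2 <- electrode_set(el$positions %*% diag(c(1, 1, -1)), el$node_index,
                       el$labels)
  L <- n_electrodes(el)
  pat <- numeric(L); pat[3] <- 5e-4; pat[8] <- -5e-4
  v1 <- solve_forward(fx$sys, el, pat)$potential
  v2 <- solve_forward(sys2, el2, pat)$potential
  expect_lt(max(abs(v1 - v2)) / max(abs(v1)), 1e-6)
})

test_that("potential from two scalp electrodes matches the analytic series", {
  # homogeneous sphere (all tissues at brain conductivity)
  hd <- generate_sphere_head(edge_length = 0.028, radial_spacing = 0.012,
                             n_electrodes = 16, seed = 3)
  sigma <- 0.33
  sys <- assemble_fem(hd$mesh, conductivity_map(
    c(brain = sigma, csf = sigma, skull = sigma, scalp = sigma)))
  en <- hd$electrodes$node_index
  pos <- hd$mesh$nodes
  # most antipodal electrode pair
  cosang <- tcrossprod(pos[en, ] / 0.092)
  pick <- which(cosang == min(cosang), arr.ind = TRUE)[1, ]
  L <- n_electrodes(hd$electrodes)
  pat <- numeric(L); pat[pick[1]] <- 1e-3; pat[pick[2]] <- -1e-3
  v <- solve_forward(sys, hd$electrodes, pat)$potential
  outer_nodes <- which(sqrt(rowSums(pos^2)) > 0.092 * (1 - 1e-9))
  gA <- acos(pmin(1, pmax(-1, (pos[outer_nodes, ] %*% pos[en[pick[1]], ]) / 0.092^2)))
  gB <- acos(pmin(1, pmax(-1, (pos[outer_nodes, ] %*% pos[en[pick[2]], ]) / 0.092^2)))
  keep <- gA > 25 * pi / 180 & gB > 25 * pi / 180
  ana <- sphere_surface_potential(gA[keep], 1e-3, sigma, 0.092) -
         sphere_surface_potential(gB[keep], 1e-3, sigma, 0.092)
  fem <- v[outer_nodes[keep]]
  ana <- ana - mean(ana); fem <- fem - mean(fem)
  expect_lt(sqrt(mean((fem - ana)^2) / mean(ana^2)), 0.02)
})

test_that("truncated Legendre series approaches the closed form", {
  g <- c(pi / 3, pi / 2, 3 * pi / 4)
  exact <- sphere_surface_potential(g, 1e-3, 0.33, 0.092)
  e1 <- abs(sphere_surface_potential(g, 1e-3, 0.33, 0.092, n_terms = 500) - exact)
  e2 <- abs(sphere_surface_potential(g, 1e-3, 0.33, 0.092, n_terms = 8000) - exact)
  expect_true(all(e2 < e1))
  expect_lt(max(e2 / abs(exact)), 0.05)
})
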