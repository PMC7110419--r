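# Montage optimizers: closed forms, convex solves, their relationships.

test_that("WLS closed form scales as sqrt(alpha) and meets the bound", {
  fx <- fix_tiny()
  a1 <- wls_closed_form(fx$tm, fx$w_exact, fx$target, alpha_i = 1e-8)
  a4 <- wls_closed_form(fx$tm, fx$w_exact, fx$target, alpha_i = 4e-8)
  expect_equal(a4$pattern$independent, 2 * a1$pattern$independent,
               tolerance = 1e-12)
  # the energy bound is met with equality by construction
  expect_equal(a1$energy, 1e-8, tolerance = 1e-8)
  expect_equal(a4$k_scale, 2 * a1$k_scale, tolerance = 1e-12)
})

test_that("WLS closed form equals an independent dense normal-equation solve", {
  fx <- fix_tiny()
  el <- fx$electrodes
  ten <- electrode_set(el$positions[1:10, ], el$node_index[1:10],
                       el$labels[1:10])
  tm <- build_transfer_matrix(fx$sys, ten)
  tg <- define_roi_orientation(fx$mesh, fx$roi, tm)
  w <- build_volume_weights(tm, tg, "exact")
  got <- wls_closed_form(tm, w, tg, k = 1)$pattern$independent
  # oracle: explicit weighted design matrix + QR factorization
  sq <- sqrt(w$gamma_nonroi)
  A <- tm$M * sq
  rhs <- crossprod(tm$M, w$gamma * tg$d)
  oracle <- qr.coef(qr(crossprod(A)), rhs)
  expect_lt(rel_l2_err(got, as.numeric(oracle)), 1e-8)
})

test_that("scaled WLS exhausts the budget along the closed-form direction", {
  fx <- fix_tiny()
  i_max <- 1e-3
  sw <- scaled_wls(fx$tm, fx$w_exact, fx$target, i_max)
  expect_equal(pattern_budget(sw$pattern), 2 * i_max, tolerance = 1e-12)
  base <- wls_closed_form(fx$tm, fx$w_exact, fx$target, k = 1)
  d1 <- sw$pattern$independent / sqrt(sum(sw$pattern$independent^2))
  d2 <- base$pattern$independent / sqrt(sum(base$pattern$independent^2))
  expect_lt(rel_l2_err(d1, d2), 1e-10)
})

test_that("constrained WLS reduces to the closed form when the budget is slack", {
  fx <- fix_tiny()
  base <- wls_closed_form(fx$tm, fx$w_approx, fx$target, k = 1)
  big <- 2 * pattern_budget(base$pattern)   # budget comfortably above need
  cw <- constrained_wls(fx$tm, fx$w_approx, fx$target, k = 1,
                        constraint_set(big, fx$tm$L))
  expect_lt(rel_l2_err(cw$pattern$independent, base$pattern$independent), 1e-6)
  expect_false(isTRUE(cw$active$budget))
  # i_max -> 0 drives the pattern to zero
  small <- constrained_wls(fx$tm, fx$w_approx, fx$target, k = 1,
                           constraint_set(1e-9, fx$tm$L))
  expect_lt(pattern_budget(small$pattern), 2.1e-9)
})

test_that("dirmax objective is monotone in the energy bound", {
  fx <- fix_tiny()
  alphas <- 10^seq(-9, -3, by = 1.5)
  objs <- vapply(alphas, function(a)
    dirmax(fx$tm, fx$w_exact, fx$target,
           constraint_set(1e-3, fx$tm$L, alpha_i = a))$objective, 0)
  expect_true(all(diff(objs) > -1e-9 * max(abs(objs))))
})

test_that("dirmax solutions satisfy every declared constraint", {
  fx <- fix_tiny()
  cs_list <- list(
    constraint_set(1e-3, fx$tm$L, alpha_i = 1e-7),
    constraint_set(1e-3, fx$tm$L, alpha_i = 1e-5,
                   i_min_vec = -2e-4, i_max_vec = 4e-4),
    constraint_set(5e-4, fx$tm$L, alpha_i = 1e-2))
  Q <- crossprod(fx$tm$M, fx$w_exact$gamma_nonroi * fx$tm$M)
  for (cs in cs_list) {
    opt <- dirmax(fx$tm, fx$w_exact, fx$target, cs)
    ex <- opt$pattern$expanded
    expect_lt(pattern_budget(ex), 2 * cs$i_max + 1e-9)
    expect_true(all(ex <= cs$i_max_vec + 1e-9))
    expect_true(all(ex >= cs$i_min_vec - 1e-9))
    i <- opt$pattern$independent
    expect_lt(as.numeric(i %*% Q %*% i), cs$alpha_i * (1 + 1e-6))
    # objective recomputable from the pattern
    cv <- crossprod(fx$tm$M, fx$w_exact$gamma * fx$target$d)
    expect_equal(opt$objective, sum(cv * i), tolerance = 1e-8)
  }
})

test_that("dirmax with a zero target returns the zero pattern", {
  fx <- fix_tiny()
  tg0 <- fx$target
  tg0$d <- numeric(length(tg0$d))
  opt <- dirmax(fx$tm, fx$w_exact, tg0,
                constraint_set(1e-3, fx$tm$L, alpha_i = 1e-6))
  expect_equal(opt$objective, 0)
  expect_equal(pattern_budget(opt$pattern), 0)
})

test_that("dirmax is invariant to rescaling the transfer matrix", {
  # T -> c T rescales k by c and, with alpha -> c^2 alpha, leaves the
  # optimal pattern unchanged
  fx <- fix_tiny()
  c0 <- 3.7
  tm2 <- fx$tm
  tm2$M <- c0 * tm2$M
  w2 <- build_volume_weights(tm2, fx$target, "exact")
  a <- 1e-7
  o1 <- dirmax(fx$tm, fx$w_exact, fx$target,
               constraint_set(1e-3, fx$tm$L, alpha_i = a))
  o2 <- dirmax(tm2, w2, fx$target,
               constraint_set(1e-3, fx$tm$L, alpha_i = c0^2 * a))
  expect_lt(rel_l2_err(o2$pattern$independent, o1$pattern$independent), 1e-6)
  k1 <- wls_closed_form(fx$tm, fx$w_exact, fx$target, alpha_i = a)$k_scale
  k2 <- wls_closed_form(tm2, w2, fx$target, alpha_i = c0^2 * a)$k_scale
  expect_equal(k2, c0 * k1, tolerance = 1e-10)
})

test_that("synthetic potential matches the dipole lead-field route", {
  fx <- fix_tiny()
  phi <- synthetic_potential(fx$tm, fx$w_exact, fx$target, s = 1)
  # independent EEG route: lead field of the ROI elements applied to the
  # volume-weighted dipole density Gamma d
  sub <- fx$target$roi_elements
  lf <- dipole_leadfield(fx$sys, fx$electrodes, sub)
  idx <- rep(3 * (fx$target$roi_local - 1), each = 3) + 1:3
  phi_eeg <- as.numeric(lf$M %*% (fx$w_exact$gamma[idx] * fx$target$d[idx]))
  expect_lt(rel_l2_err(phi$phi, phi_eeg), 1e-6)
  # scale behaviour in s
  phi10 <- synthetic_potential(fx$tm, fx$w_exact, fx$target, s = 10)
  expect_equal(phi10$phi, 10 * phi$phi, tolerance = 1e-14)
  expect_equal(which.max(phi10$expanded), which.max(phi$expanded))
  # zero target
  tg0 <- fx$target; tg0$d <- numeric(length(tg0$d))
  expect_true(all(synthetic_potential(fx$tm, fx$w_exact, tg0)$phi == 0))
})

test_that("one-to-one reciprocity picks the potential extrema", {
  opt <- reciprocity_one_to_one(c(3, -1, 0, 0), 1e-3)
  expect_equal(opt$pattern$expanded, c(1e-3, -1e-3, 0, 0))
  # invariance to constant potential shifts
  opt2 <- reciprocity_one_to_one(c(3, -1, 0, 0) + 7, 1e-3)
  expect_equal(opt2$pattern$expanded, opt$pattern$expanded)
  # exhaustive pair-enumeration oracle on random potentials
  set.seed(9)
  for (rep in 1:10) {
    L <- sample(4:32, 1)
    phi <- c(rnorm(L - 1), 0)
    got <- reciprocity_one_to_one(phi, 1e-3)
    best <- -Inf; best_pair <- NULL
    for (a in 1:L) for (b in 1:L) if (a != b) {
      v <- 1e-3 * (phi[a] - phi[b])
      if (v > best) { best <- v; best_pair <- c(a, b) }
    }
    expect_equal(sum(got$pattern$expanded * phi) * 1, best, tolerance = 1e-12)
    expect_equal(which(got$pattern$expanded > 0), best_pair[1])
    expect_equal(which(got$pattern$expanded < 0), best_pair[2])
  }
})

test_that("limited reciprocity spreads sources and sinks per the limits", {
  set.seed(13)
  phi <- c(rnorm(63), 0)
  i_max <- 1e-3
  opt <- reciprocity_limited(phi, i_max, -i_max / 20, i_max / 2)
  ex <- opt$pattern$expanded
  pos <- which(ex > 1e-12)
  neg <- which(ex < -1e-12)
  expect_length(pos, 2L)
  expect_length(neg, 20L)
  expect_equal(ex[pos], rep(i_max / 2, 2), tolerance = 1e-12)
  expect_equal(ex[neg], rep(-i_max / 20, 20), tolerance = 1e-12)
  expect_lt(abs(sum(ex)), 1e-15)
  # sources sit at the top potentials, sinks at the bottom
  expect_setequal(pos, order(phi, decreasing = TRUE)[1:2])
  expect_setequal(neg, order(phi)[1:20])
  # with limits at +-i_max it collapses to the one-to-one montage
  one <- reciprocity_limited(phi, i_max, -i_max, i_max)
  expect_equal(one$pattern$expanded,
               reciprocity_one_to_one(phi, i_max)$pattern$expanded)
  # fractional last electrode when i_max/c is not an integer
  fr <- reciprocity_limited(phi, i_max, -i_max, i_max / 1.5)
  frp <- fr$pattern$expanded[fr$pattern$expanded > 1e-12]
  expect_equal(sort(frp), c(i_max / 3, i_max / 1.5), tolerance = 1e-12)
  expect_error(reciprocity_limited(phi, i_max, -i_max / 50, i_max / 50),
               "infeasible")
})
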