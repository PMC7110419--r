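# ROI definition, orientation averaging, volume weights, patterns.

test_that("cap ROI orientation is close to the radial direction", {
  fx <- fix_std()
  # ROI is a cap around the +z-ish point (0,0,0.070): the volume-weighted
  # average of the projected cortex normals must be nearly radial
  centre_dir <- c(0, 0, 1)
  ang <- acos(sum(fx$target$mean_orientation * centre_dir))
  expect_lt(ang, 5 * pi / 180)
  # d is unit on ROI elements, zero elsewhere
  dm <- matrix(fx$target$d, ncol = 3, byrow = TRUE)
  nr <- sqrt(rowSums(dm^2))
  expect_equal(nr[fx$target$roi_local], rep(1, length(fx$target$roi_local)),
               tolerance = 1e-12)
  expect_true(all(nr[-fx$target$roi_local] == 0))
})

test_that("user-supplied orientations pass through unchanged", {
  fx <- fix_tiny()
  n <- length(fx$roi)
  set.seed(2)
  dm <- matrix(rnorm(3 * n), n, 3)
  dm <- dm / sqrt(rowSums(dm^2)) * 1.5   # non-unit strengths honoured
  tg <- define_roi_orientation(fx$mesh, fx$roi, fx$tm, orientation = dm)
  got <- matrix(tg$d, ncol = 3, byrow = TRUE)[tg$roi_local, ]
  expect_equal(got, dm, tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("single-element ROI takes its projected surface normal", {
  fx <- fix_tiny()
  e1 <- fx$roi[1]
  tg <- define_roi_orientation(fx$mesh, e1, fx$tm)
  # its orientation must be a unit vector roughly radial at the centroid
  cdir <- fx$mesh$centroids[e1, ]
  cdir <- cdir / sqrt(sum(cdir^2))
  expect_lt(acos(pmin(1, sum(tg$mean_orientation * cdir))), 25 * pi / 180)
  expect_equal(sqrt(sum(tg$mean_orientation^2)), 1, tolerance = 1e-12)
})

test_that("degenerate ROIs are rejected", {
  fx <- fix_tiny()
  expect_error(define_roi_orientation(fx$mesh, integer(0), fx$tm), "empty")
  # ROI covering a full spherical shell: normals average to ~zero
  rc <- sqrt(rowSums(fx$mesh$centroids^2))
  shell <- which(fx$mesh$tissue == 1L & rc > 0.80 * 0.080)
  expect_error(define_roi_orientation(fx$mesh, shell, fx$tm), "zero")
})

test_that("volume weights have the right trace and modes", {
  fx <- fix_tiny()
  w <- fx$w_exact
  expect_equal(sum(w$gamma), 3 * sum(fx$tm$volumes), tolerance = 1e-12)
  expect_true(all(w$gamma_nonroi <= w$gamma))
  idx <- rep(3 * (fx$target$roi_local - 1), each = 3) + 1:3
  expect_true(all(w$gamma_nonroi[idx] == 0))
  expect_identical(fx$w_approx$gamma_nonroi, fx$w_approx$gamma)
})

test_that("a tiny ROI leaves the weight matrices nearly identical", {
  # 1000 uniform elements, ROI of one element: 0.1% volume fraction gives
  # a 0.1% trace-norm difference between Gamma and Gamma_nonROI
  tm <- structure(list(M = matrix(0, 3000, 2), elements = 1:1000,
                       volumes = rep(1e-6, 1000), labels = c("a", "b", "c"),
                       L = 3L), class = "transfer_matrix")
  tg <- structure(list(roi_elements = 1L, roi_local = 1L,
                       d = c(1, 0, 0, rep(0, 2997)),
                       mean_orientation = c(1, 0, 0),
                       roi_volume = 1e-6, nonroi_volume = 999e-6),
                  class = "target_spec")
  w <- build_volume_weights(tm, tg, "exact")
  expect_lt(sum(w$gamma - w$gamma_nonroi) / sum(w$gamma), 0.002)
})

test_that("ROI covering everything makes the energy constraint vacuous", {
  toy <- toy_system()
  tg <- toy$target
  tg$roi_local <- 1:3
  tg$roi_elements <- 1:3
  w <- build_volume_weights(toy$tm, tg, "exact")
  expect_true(all(w$gamma_nonroi == 0))
})

test_that("expand/reduce are exact inverses obeying Kirchhoff", {
  p <- expand_pattern(c(0.5e-3, -0.2e-3))
  expect_equal(p$expanded, c(0.5e-3, -0.2e-3, -0.3e-3), tolerance = 1e-15)
  expect_identical(expand_pattern(numeric(5))$expanded, numeric(6))
  set.seed(4)
  for (rep in 1:20) {
    i <- rnorm(sample(2:64, 1)) * 1e-3
    ex <- expand_pattern(i)$expanded
    expect_identical(reduce_pattern(ex), i)
    expect_lt(abs(sum(ex)), 1e-15 * sum(abs(ex)) + 1e-300)
  }
  expect_error(reduce_pattern(c(1e-3, 1e-3)), "zero")
})

test_that("constraint sets validate their inputs", {
  cs <- constraint_set(1e-3, 8L)
  expect_equal(cs$i_max_vec, rep(1e-3, 8))
  expect_error(constraint_set(-1, 8L), "positive")
  expect_error(constraint_set(1e-3, 8L, i_min_vec = rep(0.1e-3, 8)), "i_min_vec")
  expect_error(constraint_set(1e-3, 8L, alpha_i = -2), "alpha_i")
})
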