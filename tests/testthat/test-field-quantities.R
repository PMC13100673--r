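# small helper: wrap per-pulse field matrices into an array
farr <- function(...) field_array(list(...))

test_that("magnitude, polar angle and normal component are exact", {
  st <- flat_sheets(gap = 2)
  mid <- build_layer_surface(st, 0.5)
  fr <- element_frames(mid, st$gm, st$wm) # all axes (0,0,1)
  m <- n_elements(mid)
  F1 <- matrix(rep(c(3, 0, 4), each = m), m, 3)
  f <- farr(F1)
  expect_equal(as.vector(magnitude_map(f)), rep(5, m)) # 3-4-5
  expect_equal(as.vector(normal_component_map(f, fr)), rep(4, m))
  # random vectors vs componentwise oracle
  set.seed(3)
  F2 <- matrix(rnorm(3 * m), m, 3)
  f2 <- farr(F2)
  expect_lt(max(abs(magnitude_map(f2) -
                      matrix(sqrt(rowSums(F2^2)), 1))), 1e-12)
  expect_lt(max(abs(normal_component_map(f2, fr) -
                      matrix(abs(F2[, 3]), 1))), 1e-12)
  # angles: parallel, orthogonal, anti-parallel, zero field
  F3 <- matrix(0, m, 3)
  F3[1, ] <- c(0, 0, 2)    # theta 0
  F3[2, ] <- c(1, 1, 0)    # theta 90
  F3[3, ] <- c(0, 0, -0.5) # theta 180
  th <- polar_angle(farr(F3), fr)
  expect_equal(th[1, 1:3], c(0, 90, 180))
  expect_true(all(is.nan(th[1, 4:m])))
  # |E_perp| <= |E| always
  expect_true(all(normal_component_map(f2, fr) <= magnitude_map(f2) + 1e-12))
})

test_that("quantity maps are invariant under global rotation", {
  st <- flat_sheets(gap = 2)
  mid <- build_layer_surface(st, 0.5)
  fr <- element_frames(mid, st$gm, st$wm)
  m <- n_elements(mid)
  set.seed(8)
  F1 <- matrix(rnorm(3 * m, sd = 30), m, 3)
  R <- rotation_about_axis(c(2, -1, 1), 63)
  fr_rot <- fr
  fr_rot$axis <- fr$axis %*% t(R)
  f <- farr(F1)
  f_rot <- farr(F1 %*% t(R))
  expect_lt(max(abs(magnitude_map(f) - magnitude_map(f_rot))), 1e-9)
  expect_lt(max(abs(normal_component_map(f, fr) -
                      normal_component_map(f_rot, fr_rot))), 1e-9)
  expect_lt(max(abs(polar_angle(f, fr) - polar_angle(f_rot, fr_rot))), 1e-9)
})

test_that("depth gradient is the relative two-point change in %/mm", {
  one <- function(v) matrix(v, 1, 1)
  # uniform field
  expect_equal(as.vector(depth_gradient(one(100), one(100), one(100), 0.5)),
               0)
  # shallow 102, deep 98, layer 100, separation 0.5 mm -> -8 %/mm
  expect_equal(as.vector(depth_gradient(one(100), one(102), one(98), 0.5)),
               -8)
  # scale invariance
  expect_equal(depth_gradient(one(200), one(204), one(196), 0.5),
               depth_gradient(one(100), one(102), one(98), 0.5))
  expect_true(is.nan(as.vector(
    depth_gradient(one(0), one(1), one(1), 0.5))))
  expect_error(depth_gradient(one(1), one(1), one(1), 0), "separation")
})

test_that("gradient sampling points sit 10% toward GM and WM", {
  d <- gradient_sample_depths(0.65)
  expect_equal(unname(d), c(0.65 * 0.9, 0.65 + 0.1 * 0.35))
  # two-point gradient of an exponential depth decay matches the
  # closed-form log-derivative within 1%
  L <- 5 # mm decay length
  depth <- 0.65
  thick <- 2.5
  s_layer <- depth * thick
  s <- gradient_sample_depths(depth) * thick
  magf <- function(s) 120 * exp(-s / L)
  g <- depth_gradient(matrix(magf(s_layer)), matrix(magf(s[1])),
                      matrix(magf(s[2])), s[2] - s[1])
  expect_equal(as.vector(g), -100 / L, tolerance = 0.01)
})

test_that("LUT lookup is bilinear with clamped gradients", {
  lut <- threshold_lut(c(0, 90, 180), c(-10, 0, 10),
                       matrix(c(1, 1.2, 1.4, 1, 1.3, 1.5, 1.1, 1.4, 1.6),
                              3, 3))
  # a grid node returns the node value
  expect_equal(as.vector(lut_lookup(lut, 90, 0)), 1.3)
  expect_equal(as.vector(lut_lookup(lut, 0, 0)), 1)
  # cell center equals the mean of its 4 corners
  expect_equal(as.vector(lut_lookup(lut, 45, -5)),
               mean(c(1, 1.2, 1, 1.3)))
  # gradient clamping, reported
  v <- lut_lookup(lut, c(90, 90), c(50, 0))
  expect_equal(v[1], as.vector(lut_lookup(lut, 90, 10)))
  expect_equal(attr(v, "clamped_fraction"), 0.5)
  expect_error(lut_lookup(lut, 200, 0), "theta")
  expect_error(threshold_lut(c(0, 90), c(0, 1), matrix(2, 2, 2)),
               "normalized")
  expect_error(threshold_lut(c(0, 90), c(0, 1),
                             matrix(c(1, -1, 1, 1), 2, 2)), "positive")
})

test_that("surrogate LUT has the qualitative average-threshold shape", {
  # degenerate parameters give the identity table
  id <- surrogate_lut(kappa = 0, grad_slope = 0)
  expect_true(all(id$S == 1))
  lut <- surrogate_lut(kappa = 0.3, grad_slope = 0)
  expect_equal(as.vector(lut_lookup(lut, 0, 0)), 1)
  # at 90 degrees the effective field sits at 1/1.3 of |E|:
  # between the cosine model (0) and the magnitude model (1)
  expect_equal(as.vector(lut_lookup(lut, 90, 0)), 1.3)
  # symmetry about 90 degrees
  th <- seq(0, 90, by = 5)
  expect_equal(as.vector(lut_lookup(lut, th, 0 * th)),
               as.vector(lut_lookup(lut, 180 - th, 0 * th)))
  expect_error(surrogate_lut(kappa = 1.2), "kappa")
})

test_that("effective field rescales |E| by the firing threshold", {
  st <- flat_sheets(gap = 2)
  mid <- build_layer_surface(st, 0.5)
  fr <- element_frames(mid, st$gm, st$wm)
  m <- n_elements(mid)
  # identity LUT: neuron model degenerates to the magnitude model
  id <- surrogate_lut(kappa = 0, grad_slope = 0)
  set.seed(5)
  F1 <- matrix(rnorm(3 * m, sd = 40), m, 3)
  f <- farr(F1)
  grad <- matrix(0, 1, m)
  expect_equal(as.vector(effective_field_map(f, fr, id, grad)),
               as.vector(magnitude_map(f)))
  # |E| = 100 with S = 1.25 (via the gradient leg) -> 80 V/m
  lut125 <- surrogate_lut(kappa = 0, grad_slope = 0.0125)
  F2 <- matrix(rep(c(0, 0, 100), each = m), m, 3)
  eff <- effective_field_map(farr(F2), fr, lut125, matrix(20, 1, m))
  expect_equal(as.vector(eff), rep(80, m))
  # ordering |E_perp| <= E_eff <= |E| for the angular surrogate
  lut3 <- surrogate_lut(kappa = 0.3, grad_slope = 0)
  eff3 <- effective_field_map(f, fr, lut3, grad)
  expect_true(all(eff3 <= magnitude_map(f) + 1e-9))
  expect_true(all(eff3 >= normal_component_map(f, fr) - 1e-9))
  # monotone in |E| at fixed orientation
  eff_big <- effective_field_map(farr(2 * F1), fr, lut3, grad)
  expect_true(all(eff_big > eff3))
})

test_that("LUT CSV round-trip preserves the table", {
  lut <- surrogate_lut()
  path <- tempfile(fileext = ".csv")
  write_lut(lut, path)
  lut2 <- read_lut(path)
  expect_equal(lut2$theta_grid, lut$theta_grid)
  expect_equal(lut2$grad_grid, lut$grad_grid)
  expect_equal(lut2$S, lut$S, tolerance = 1e-12)
})
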