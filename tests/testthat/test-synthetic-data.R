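test_that("gyral phantom honours its constructor contract", {
  ph <- gyral_phantom(n_x = 9, n_y = 9, seed = 5)
  st <- ph$stack
  expect_identical(st$gm$triangles, st$wm$triangles)
  expect_identical(n_elements(st$gm), 2L * 8L * 8L)
  expect_true(all(st$gm$labels %in% c("precentral", "other")))
  expect_gt(sum(st$gm$labels == "precentral"), 0)
  # cortical thickness is preserved along the offset direction
  d <- sqrt(rowSums((st$gm$vertices - st$wm$vertices)^2))
  expect_lt(max(abs(d - ph$params$thickness)), 1e-9)
  # determinism
  ph2 <- gyral_phantom(n_x = 9, n_y = 9, seed = 5)
  expect_identical(ph$stack$gm$vertices, ph2$stack$gm$vertices)
  ph3 <- gyral_phantom(n_x = 9, n_y = 9, seed = 6)
  expect_false(identical(ph$stack$gm$vertices, ph3$stack$gm$vertices))
  expect_error(gyral_phantom(thickness = -1), "thickness")
  expect_error(gyral_phantom(n_x = 3), "n_x")
})

test_that("zero-amplitude phantom degenerates to flat parallel sheets", {
  ph <- gyral_phantom(n_x = 7, n_y = 7, amplitude = 0)
  expect_true(all(ph$stack$gm$vertices[, 3] == 0))
  fr <- element_frames(ph$stack$gm, ph$stack$gm, ph$stack$wm)
  expect_lt(max(abs(sweep(fr$axis, 2, c(0, 0, 1)))), 1e-9)
})

test_that("random coil placements respect the 3 cm / 60 degree protocol", {
  ph <- gyral_phantom(n_x = 5, n_y = 5)
  ref <- reference_placement(ph)
  # degenerate scatter collapses onto the reference
  pl0 <- sample_coil_placements(ref, 5, radius = 0, max_angle = 0, seed = 2)
  for (p in pl0) {
    expect_equal(p$position, ref$position)
    expect_equal(p$y_axis, ref$y_axis)
  }
  n <- 3000
  pl <- sample_coil_placements(ref, n, seed = 3)
  pos <- t(vapply(pl, function(p) p$position, numeric(3)))
  d <- sqrt(rowSums(sweep(pos, 2, ref$position)^2))
  expect_true(all(d <= 30 + 1e-9))
  ang <- vapply(pl, function(p)
    acos(pmin(1, sum(p$y_axis * ref$y_axis))) * 180 / pi, 0)
  expect_true(all(ang <= 60 + 1e-6))
  # uniform-disc mean: per-coordinate sd is R/2, check within 3 SE
  se <- 30 / 2 / sqrt(n)
  expect_lt(max(abs(colMeans(pos) - ref$position)), 3 * se)
  # orthonormality is preserved after rotation
  for (p in pl[1:5]) {
    A <- rbind(p$x_axis, p$y_axis, p$z_axis)
    expect_lt(max(abs(A %*% t(A) - diag(3))), 1e-9)
  }
})

test_that("figure-of-eight primary field decays, flips and mirrors", {
  ph <- gyral_phantom(n_x = 5, n_y = 5)
  ref <- reference_placement(ph, angle_deg = 0)
  below <- function(depth) ref$position + depth * ref$z_axis
  e1 <- primary_efield(ref, below(15))
  e2 <- primary_efield(ref, below(30))
  expect_gt(sqrt(sum(e1^2)), sqrt(sum(e2^2))) # |r|^-3 decay
  # beneath the center the field points along the current (y) axis
  expect_gt(abs(sum(e1 * ref$y_axis)), 0.999 * sqrt(sum(e1^2)))

  # 180-degree rotation about the coil normal flips the field sign
  R <- rotation_about_axis(ref$z_axis, 180)
  flipped <- coil_placement(ref$position, as.numeric(R %*% ref$x_axis),
                            as.numeric(R %*% ref$y_axis), ref$z_axis)
  pts <- matrix(rnorm(30, sd = 20), 10, 3)
  expect_lt(max(abs(primary_efield(flipped, pts) +
                      primary_efield(ref, pts))), 1e-9)

  # mirror symmetry across the plane through the coil center
  # perpendicular to the dipole-offset (coil x) axis: E(Mx) = M E(x)
  u <- ref$x_axis
  M <- diag(3) - 2 * outer(u, u)
  pts_m <- sweep(sweep(pts, 2, ref$position) %*% t(M), 2, ref$position, `+`)
  expect_lt(max(abs(primary_efield(ref, pts_m) -
                      primary_efield(ref, pts) %*% t(M))), 1e-9)

  expect_error(primary_efield(ref, ref$position + 20 * ref$x_axis),
               "dipole")
  # intensity scales the field linearly
  ref2 <- coil_placement(ref$position, ref$x_axis, ref$y_axis, ref$z_axis,
                         intensity = 2)
  expect_equal(primary_efield(ref2, pts), 2 * primary_efield(ref, pts))
})

test_that("calibration puts the target field magnitude at the target point", {
  ph <- gyral_phantom()
  ref <- reference_placement(ph)
  pt <- c(1, 2, 3)
  sc <- calibrate_primary_scale(ref, pt, target = 87)
  e <- primary_efield(ref, matrix(pt, 1), scale = sc)
  expect_equal(sqrt(sum(e^2)), 87, tolerance = 1e-9)
})

test_that("MEP generation follows the sigmoid with log-normal noise", {
  truth <- ground_truth(1, y0 = 0.02, a = 2, r = 0.1, x0 = 60,
                        noise_sd_log = 0)
  x <- seq(0, 130, length.out = 40)
  expect_equal(generate_meps(truth, x), sigmoid_predict(truth, x))
  # midpoint of the IO curve at x = x0
  expect_equal(generate_meps(truth, rep(60, 3)), rep((0.02 + 2) / 2, 3))

  truth2 <- ground_truth(1, noise_sd_log = 0.3)
  m <- generate_meps(truth2, rep(100, 1e5), seed = 9)
  expect_true(all(m > 0))
  # at high drive the floor is inactive: mean log MEP ~ log sigmoid
  se <- 0.3 / sqrt(1e5)
  expect_lt(abs(mean(log(m)) - log(sigmoid_predict(truth2, 100))), 3 * se)
  # log-MEPs are symmetric (raw MEPs right-skewed)
  expect_lt(abs(bf_skewness(log(m))), 0.05)
  expect_gt(bf_skewness(m), 0.5)
  # determinism
  expect_identical(generate_meps(truth2, x, seed = 4),
                   generate_meps(truth2, x, seed = 4))
  expect_error(generate_meps(truth2, c(-1, 2)), ">= 0")
})

test_that("peak-to-peak extraction respects the 18-35 ms window", {
  fs <- 4000
  t_ms <- (0:(0.06 * fs)) / fs * 1000
  expect_identical(mep_peak_to_peak(numeric(length(t_ms))), 0)
  bump <- function(center_max, center_min) {
    tr <- numeric(length(t_ms))
    tr[which.min(abs(t_ms - center_max))] <- 1.2
    tr[which.min(abs(t_ms - center_min))] <- -0.8
    tr
  }
  expect_equal(mep_peak_to_peak(bump(25, 28)), 2.0)
  # the same deflection outside the window is invisible
  expect_equal(mep_peak_to_peak(bump(40, 43)), 0)
  expect_error(mep_peak_to_peak(numeric(10)), "window")
})

test_that("rMT estimation returns the lowest passing ladder intensity", {
  # deterministic step IO: silent below 0.57, 1 mV above
  step_sim <- function(int) if (int >= 0.57) 1 else 0
  ladder <- seq(0.02, 2, by = 0.02)
  expect_equal(estimate_rmt(step_sim, ladder = ladder),
               ladder[ladder >= 0.57][1])
  # noiseless sigmoid: first ladder intensity whose MEP >= 0.05 mV
  truth <- ground_truth(1, y0 = 0, a = 2, r = 0.1, x0 = 60)
  sig_sim <- function(int) sigmoid_predict(truth, int * 100)
  expected <- ladder[sigmoid_predict(truth, ladder * 100) >= 0.05][1]
  expect_equal(estimate_rmt(sig_sim, ladder = ladder), expected)
  expect_error(estimate_rmt(function(int) 0), "never met")
})

test_that("noisier IO curves never sharpen the rMT estimate", {
  truth_at <- function(sd) ground_truth(1, y0 = 0.01, a = 2, r = 0.1,
                                        x0 = 60, noise_sd_log = sd)
  est <- function(sd, seeds) {
    vapply(seeds, function(s) {
      tr <- truth_at(sd)
      k <- 0
      estimate_rmt(function(int) {
        k <<- k + 1
        generate_meps(tr, int * 100, seed = s * 1000 + k)
      }, seed = s, ladder = seq(0.1, 1.5, by = 0.05))
    }, 0)
  }
  v_lo <- var(est(0.15, 1:100))
  v_hi <- var(est(0.6, 1:100))
  expect_gte(v_hi, v_lo)
})
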