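test_that("sigmoid prediction matches the closed form and is overflow-safe", {
  p <- list(y0 = 0.05, a = 2.0, r = 0.5, x0 = 60)
  expect_equal(sigmoid_predict(p, 60), (0.05 + 2.0) / 2) # midpoint
  expect_equal(sigmoid_predict(p, 70),
               0.05 + 1.95 / (1 + exp(-0.5 * 10)), tolerance = 1e-12)
  # asymptotes, far beyond double overflow of exp
  expect_equal(sigmoid_predict(p, -1e6), 0.05)
  expect_equal(sigmoid_predict(p, 1e6), 2.0)
})

test_that("r2_score equals the variance-ratio definition", {
  # hand computation with population variances:
  # 1 - (2/9) / (2/3) = 2/3
  expect_equal(r2_score(c(1, 2, 3), c(1, 2, 2)), 2 / 3, tolerance = 1e-12)
  y <- c(0.1, 0.5, 1.4, 2.2)
  expect_equal(r2_score(y, y), 1)
  expect_equal(r2_score(y, rep(7, 4)), 0) # any constant scores 0
  # population and sample conventions agree (the ratio cancels)
  set.seed(2)
  yy <- rnorm(50)
  hh <- yy + rnorm(50, sd = 0.3)
  pop <- function(v) mean((v - mean(v))^2)
  expect_equal(r2_score(yy, hh), 1 - pop(yy - hh) / pop(yy))
  expect_equal(r2_score(yy, hh), 1 - var(yy - hh) / var(yy))
  expect_error(r2_score(rep(1, 5), rnorm(5)), "VAR")
})

test_that("fit_sigmoid recovers known parameters and flags degeneracies", {
  truth <- list(y0 = 0.05, a = 2, r = 0.15, x0 = 60)
  set.seed(11)
  x <- runif(400, 0, 130)
  y <- sigmoid_predict(truth, x)
  f <- fit_sigmoid(x, y)
  expect_true(f$converged)
  expect_lt(abs(f$y0 - truth$y0) / truth$y0, 1e-3)
  expect_lt(abs(f$a - truth$a) / truth$a, 1e-3)
  expect_lt(abs(f$r - truth$r) / truth$r, 1e-3)
  expect_lt(abs(f$x0 - truth$x0) / truth$x0, 1e-3)
  expect_gt(f$r2, 0.999999)
  # flat data: a ~ y0 ~ c and R2 = 0
  fc <- fit_sigmoid(x, rep(0.7, 400))
  expect_equal(fc$y0, 0.7, tolerance = 1e-6)
  expect_equal(fc$a, 0.7, tolerance = 1e-6)
  expect_equal(fc$r2, 0)
  # constant x: degenerate input flag
  fd <- fit_sigmoid(rep(50, 20), rnorm(20, 1))
  expect_false(fd$converged)
  expect_equal(fd$r2, 0)
  expect_false(fit_sigmoid(x[1:5], y[1:5])$reliable)
})

test_that("fit_sigmoid matches an independent optimizer on noisy data", {
  skip_if_not_installed("minpack.lm")
  truth <- list(y0 = 0.03, a = 1.6, r = 0.12, x0 = 55)
  set.seed(21)
  for (i in 1:5) {
    x <- runif(300, 0, 120)
    y <- sigmoid_predict(truth, x) * exp(rnorm(300, 0, 0.25))
    f <- fit_sigmoid(x, y)
    o <- minpack.lm::nls.lm(
      par = list(y0 = quantile(y, 0.05), a = quantile(y, 0.95),
                 r = 0.1, x0 = median(x)),
      fn = function(p) sigmoid_predict(p, x) - y,
      lower = c(0, median(y), 1e-8, min(x)),
      upper = c(median(y), 2 * max(y), 1e3, max(x)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    sse_oracle <- sum(o$fvec^2)
    # multi-start never does worse than the single-start oracle
    expect_lte(f$sse, sse_oracle * (1 + 1e-6))
  }
})

test_that("x0 recovery is unbiased under log-normal noise", {
  truth <- ground_truth(1, y0 = 0.02, a = 2, r = 0.1, x0 = 60,
                        noise_sd_log = 0.2)
  rel <- vapply(1:30, function(s) {
    x <- local({ set.seed(s); runif(500, 0, 120) })
    y <- generate_meps(truth, x, seed = 1000 + s)
    abs(fit_sigmoid(x, y)$x0 - 60) / 60
  }, 0)
  expect_lt(median(rel), 0.05)
})

test_that("localize applies the exposure mask and label restriction", {
  # 3 elements, 4 pulses; element 1 sees 45 V/m on exactly 25% of
  # pulses (included), element 2 never exceeds 39 V/m (excluded),
  # element 3 is exposed but lies outside the precentral band
  emag <- cbind(c(45, 10, 10, 10), c(39, 39, 39, 39), c(80, 70, 60, 50))
  x <- emag
  attr(x, "model") <- "magnitude"
  meps <- c(1.2, 0.1, 0.15, 0.08)
  labels <- c("precentral", "precentral", "other")
  map <- localize(x, meps, emag, labels)
  expect_identical(map$mask, c(TRUE, FALSE, FALSE))
  expect_identical(map$hotspot, 1L)
  expect_true(all(is.na(map$fits[2, ])))
  # empty mask is a diagnosed error
  expect_error(localize(x, meps, emag, c("other", "other", "other")),
               "empty element mask")
  # without labels, exposure alone decides
  map2 <- localize(x, meps, emag, labels = NULL)
  expect_identical(map2$mask, c(TRUE, FALSE, TRUE))
})

test_that("localize is bit-reproducible and near-perfect at zero noise", {
  fx <- small_fixture()
  q <- fixture_quantities(fx, 150, seed = derive_seed(77, "loc"))
  truth <- ground_truth(fx$true_element, noise_sd_log = 0)
  meps <- generate_meps(truth, q$magnitude[, fx$true_element])
  m1 <- localize(q$magnitude, meps, attr(q$magnitude, "emag"), fx$labels)
  m2 <- localize(q$magnitude, meps, attr(q$magnitude, "emag"), fx$labels)
  expect_identical(m1$fits, m2$fits)
  expect_identical(m1$hotspot, m2$hotspot)
  # at zero noise the max R2 approaches 1
  expect_gt(m1$r2[m1$hotspot], 0.999)
  expect_identical(m1$hotspot, fx$true_element)
})

test_that("peak R2 comparison reproduces hand-computed rank statistics", {
  # identical models: zero statistic
  same <- matrix(rep(c(0.5, 0.6, 0.7), 3), 3, 3,
                 dimnames = list(NULL, c("m", "n", "c")))
  cmp <- compare_peak_r2(same)
  expect_equal(cmp$friedman$statistic, 0)
  expect_equal(cmp$friedman$p, 1)
  # hand-ranked 3 x 3 case without ties
  mat <- rbind(c(0.60, 0.59, 0.50), c(0.55, 0.60, 0.45),
               c(0.70, 0.72, 0.60))
  colnames(mat) <- c("magnitude", "neuron", "cosine")
  cmp2 <- compare_peak_r2(mat)
  expect_equal(cmp2$friedman$statistic, bf_friedman_stat(mat))
  # one model uniformly above: its pairwise differences are one-sided
  dom <- mat
  dom[, 1] <- apply(mat, 1, max) + 0.05
  cmp3 <- compare_peak_r2(dom)
  expect_true(all(dom[, 1] > dom[, 2]) && all(dom[, 1] > dom[, 3]))
  # signed-rank statistic at its maximum for the dominating pairs
  n <- nrow(dom)
  expect_equal(cmp3$pairwise$statistic[cmp3$pairwise$a == "magnitude"],
               rep(n * (n + 1) / 2, 2))
  expect_error(compare_peak_r2(mat[1:2, ]), "subjects")
})
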