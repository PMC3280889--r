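test_that("sigmoid variants are normalized, monotone and have slope s1 at 0", {
  sp <- sigmoid_spec()
  expect_identical(sigmoid(0, sp), 0)
  expect_equal(sigmoid(0, sigmoid_spec(centered = FALSE)), 0.5)
  # odd about zero, bounded by 1/2
  xs <- seq(-30, 30, by = 0.37)
  expect_equal(sigmoid(-xs, sp), -sigmoid(xs, sp))
  expect_true(all(abs(sigmoid(xs, sp)) < 0.5))
  expect_true(all(diff(sigmoid(xs, sp)) > 0))
  expect_true(all(sigmoid(xs, sigmoid_spec(centered = FALSE)) > 0 &
                    sigmoid(xs, sigmoid_spec(centered = FALSE)) < 1))
  # derivative at 0 equals the slope parameter (finite-difference check)
  for (s1 in c(0.25, 1, 2)) {
    spx <- sigmoid_spec(slope = s1)
    fd <- (sigmoid(1e-6, spx) - sigmoid(-1e-6, spx)) / 2e-6
    expect_equal(fd, s1, tolerance = 1e-8)
    expect_equal(sigmoid_deriv(0, spx), s1)
  }
  expect_error(sigmoid(NaN, sp), "non-finite")
  expect_error(sigmoid_spec(gain = -1), "positive")
})

test_that("ring distance is a period-periodic metric bounded by period/2", {
  expect_identical(ring_distance(0.7, 0.7), 0)
  expect_equal(ring_distance(0, pi), pi)          # antipodal on the 2pi ring
  expect_equal(ring_distance(0, pi / 2, period = pi), pi / 2)
  set.seed(11)
  x <- runif(200, -10, 10); y <- runif(200, -10, 10); z <- runif(200, -10, 10)
  expect_equal(ring_distance(x + 2 * pi, y), ring_distance(x, y))
  expect_equal(ring_distance(x, y), ring_distance(y, x))
  expect_true(all(ring_distance(x, y) <= pi + 1e-12))
  expect_true(all(ring_distance(x, z) <=
                    ring_distance(x, y) + ring_distance(y, z) + 1e-12))
})

test_that("ring grid quadrature is exact for trigonometric polynomials", {
  g <- ring_grid(32)
  expect_true(all(diff(g$nodes) > 0))
  expect_true(all(g$weights > 0))
  expect_lt(abs(sum(g$weights) - 2 * pi), 1e-12)
  # pure cosine modes integrate to 0 (k >= 1) or period (k = 0)
  for (k in 1:10)
    expect_lt(abs(sum(g$weights * cos(k * g$nodes))), 1e-12)
  # quadrature of the reference kernel against cos(k x) matches the closed
  # orthogonality values
  m <- ref_model(n = 32)
  jz <- -1 + 1.5 * cos(2 * g$nodes)
  for (k in 0:4) {
    quad <- sum(g$weights * jz * cos(k * g$nodes))
    expect_equal(quad, fourier_cos_coefficient(m, k), tolerance = 1e-10)
  }
})

test_that("ring model construction records delays and kernel correctly", {
  m <- ref_model(c = 0.5)
  expect_equal(m$delay$tau_max, 0.5 * pi)
  expect_equal(delayfield:::kernel_values(m$kernel$coeffs, 0, 2 * pi), 0.5)
  expect_equal(fourier_cos_coefficient(m, 0:3),
               c(-2 * pi, 0, 1.5 * pi, 0))
  # empty kernel: fully decoupled leaks
  m0 <- zero_model()
  expect_true(all(delayfield:::kernel_matrix(m0) == 0))
  expect_error(make_ring_model(rbind(c(-1, 1))), "nonnegative")
  expect_error(make_ring_model(rbind(c(0, NaN))), "finite")
})

test_that("model configs round-trip through JSON and reject bad input", {
  dir <- withr::local_tempdir()
  m <- ref_model(c = 2, gain = 1.3, n = 32)
  p <- file.path(dir, "m.json")
  save_model_config(m, p)
  m2 <- load_model_config(p)
  expect_equal(m2$kernel$coeffs, m$kernel$coeffs, ignore_attr = TRUE)
  expect_equal(m2$delay$c, 2)
  expect_equal(m2$sigmoid$gain, 1.3)
  expect_equal(m2$grid$nodes, m$grid$nodes)

  bad <- file.path(dir, "bad.json")
  writeLines('{"leak": 1, "bogus": 3}', bad)
  expect_error(load_model_config(bad), "bogus")
  writeLines("", file.path(dir, "empty.json"))
  expect_error(load_model_config(file.path(dir, "empty.json")))
  writeLines('{"leak": -2}', file.path(dir, "neg.json"))
  expect_error(load_model_config(file.path(dir, "neg.json")), "positive")
})

test_that("fixture configs reload into the reference models", {
  dir <- withr::local_tempdir()
  paths <- make_fixtures(dir)
  expect_true(all(file.exists(paths)))
  ring_cfg <- load_model_config(paths[["ring"]])
  expect_equal(ring_cfg$delay$tau_max, ring_cfg$delay$c * pi)
  expect_equal(fourier_cos_coefficient(ring_cfg, 2), 1.5 * pi)
  toy <- load_model_config(paths[["toy0"]])
  r <- solve_mode_roots(linearize(toy), 0:4)
  expect_true(all(abs(r$re + toy$leak) < 1e-10 & abs(r$im) < 1e-10))
})
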