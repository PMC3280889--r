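test_that("stationary-state solver finds the trivial and pattern states", {
  m0 <- zero_model()
  st <- find_stationary(m0)
  expect_length(st, 1L)
  expect_equal(st[[1]]$norm, 0)

  m <- ref_model(gain = 0.6, n = 32) # below the pitchfork: only V = 0
  st <- find_stationary(m)
  expect_length(st, 1L)
  expect_lt(st[[1]]$residual, 1e-10)
  expect_equal(max(abs(st[[1]]$values)), 0)

  m2 <- ref_model(gain = 1.2, n = 32) # past the pitchfork
  st2 <- find_stationary(m2)
  expect_gte(length(st2), 3L)
  norms <- vapply(st2, `[[`, numeric(1), "norm")
  expect_equal(norms[1], 0)
  # the two pattern states form a symmetric pair
  expect_equal(norms[2], norms[3], tolerance = 1e-8)
  expect_gt(norms[2], 1)
  # stationary states do not depend on the delay scale
  st3 <- find_stationary(set_gain(m2, 1.2, c = 4))
  expect_equal(vapply(st3, `[[`, numeric(1), "norm"), norms,
               tolerance = 1e-9)
})

test_that("linearization has the expected mode gains", {
  m <- ref_model(gain = 1)
  lin <- linearize(m)
  expect_true(lin$homogeneous)
  expect_equal(lin$factor, 0.25) # sigma * S'(0) = 1 * 1/4
  expect_equal(mode_gain(lin, 2), 0.25 * 1.5 * pi)
  # gains are linear in the gain at the centered fixed point
  lin2 <- linearize(set_gain(m, 2))
  expect_equal(mode_gain(lin2, c(0, 2)), 2 * mode_gain(lin, c(0, 2)))
  lin_small <- linearize(set_gain(m, 1e-9))
  expect_lt(max(abs(lin_small$Jtilde)), 1e-9)
})

test_that("closed-form kernel transform matches brute quadrature", {
  lin <- linearize(ref_model(c = 1.3))
  for (k in 0:4) {
    for (lam in c(0.3 - 0.7i, -0.5 + 2.1i, 0 + 0i, -1 + 0i)) {
      expect_equal(delayfield:::ring_kernel_transform(lin, k, lam),
                   g_transform_quad(ref_coeffs, k, lam, 1.3),
                   tolerance = 1e-8)
    }
  }
  # analytic lambda-derivative agrees with central differences
  gd <- delayfield:::ring_kernel_transform(lin, 2, 0.4 + 0.9i, deriv = TRUE)
  h <- 1e-6
  fd <- (delayfield:::ring_kernel_transform(lin, 2, 0.4 + 0.9i + h) -
           delayfield:::ring_kernel_transform(lin, 2, 0.4 + 0.9i - h)) / (2 * h)
  expect_equal(gd$dg, fd, tolerance = 1e-7)
})

test_that("characteristic equation: c = 0 closed form, delay-free lambda = 0", {
  m <- ref_model(c = 0, gain = 1.2)
  lin <- linearize(m)
  for (k in 0:6) {
    lam_k <- -m$leak + mode_gain(lin, k)
    expect_lt(Mod(char_residual(lin, k, lam_k + 0i)), 1e-12)
  }
  # Delta_k(0) does not depend on the delay scale (vertical pitchfork line)
  d_at_0 <- function(cc)
    char_residual(linearize(ref_model(c = cc, gain = 1.2)), 2, 0 + 0i)
  expect_equal(d_at_0(0.5), d_at_0(3), tolerance = 1e-12)
  # conjugate symmetry
  lin1 <- linearize(ref_model(c = 1))
  z <- 0.2 + 1.7i
  expect_equal(char_residual(lin1, 3, Conj(z)),
               Conj(char_residual(lin1, 3, z)), tolerance = 1e-14)
})

test_that("mode root solver is exact at c = 0 and stable under refinement", {
  lin0 <- linearize(ref_model(c = 0, gain = 1.1))
  r <- solve_mode_roots(lin0, 0:8, region = list(re = c(-3.5, 2), im_max = 5))
  expect_equal(nrow(r), 9L) # one root per mode
  for (k in 0:8) {
    expect_equal(r$re[r$mode == k], -1 + mode_gain(lin0, k),
                 tolerance = 1e-10)
    expect_equal(r$im[r$mode == k], 0)
  }
  # delayed case: root count in the right part of the plane is invariant
  # under doubling the Newton start density
  lin <- linearize(ref_model(c = 1))
  r1 <- solve_mode_roots(lin, 0:6, density = 3)
  r2 <- solve_mode_roots(lin, 0:6, density = 6)
  right <- function(r) r[r$re > -1 + 0.1, c("mode", "re", "im")]
  expect_equal(nrow(right(r1)), nrow(right(r2)))
  expect_true(all(r1$residual < 1e-10))
})

test_that("root counts match the argument-principle winding number", {
  lin <- linearize(ref_model(c = 1))
  in_box <- function(r, re_lim, im_lim)
    r[r$re > re_lim[1] & r$re < re_lim[2] & r$im < im_lim[2], , drop = FALSE]
  count_with_conj <- function(r) sum(ifelse(r$conjugate_pair, 2L, 1L))
  # mode 0: one conjugate pair inside [-0.9, 1.5] x [-3, 3]
  w0 <- winding_number(lin, 0, c(-0.9, 1.5), c(-3, 3), n = 8000)
  r0 <- in_box(solve_mode_roots(lin, 0,
                                region = list(re = c(-0.9, 1.5), im_max = 3)),
               c(-0.9, 1.5), c(-3, 3))
  expect_equal(round(w0), count_with_conj(r0))
  # mode 2: one real root inside the same box
  w2 <- winding_number(lin, 2, c(-0.6, 1.5), c(-3, 3), n = 8000)
  r2 <- in_box(solve_mode_roots(lin, 2,
                                region = list(re = c(-0.6, 1.5), im_max = 3)),
               c(-0.6, 1.5), c(-3, 3))
  expect_equal(round(w2), count_with_conj(r2))
  expect_gte(count_with_conj(r2), 1L)
})

test_that("generator discretization reproduces pure leak and mode roots", {
  # zero kernel: -l is an eigenvalue of A_N to high accuracy
  lin0 <- linearize(zero_model(c = 1, n = 16))
  ev0 <- generator_eigenvalues(lin0, n_space = 16, m_delay = 12)
  expect_lt(min(Mod(ev0 + 1)), 1e-8)

  # reference model: rightmost eigenvalues match the characteristic roots
  lin <- linearize(ref_model(c = 1))
  ev <- generator_eigenvalues(lin, n_space = 32, m_delay = 24)
  ev_top <- ev[Im(ev) >= -1e-9][1:8]
  roots <- solve_mode_roots(lin, 0:10)
  rl <- complex(real = roots$re, imaginary = roots$im)
  for (z in ev_top) expect_lt(min(Mod(rl - z)), 1e-6)
  # non-real eigenvalues come in conjugate pairs
  cmplx <- ev[abs(Im(ev)) > 1e-7]
  for (z in cmplx[1:20]) expect_lt(min(Mod(cmplx - Conj(z))), 1e-6)
})

test_that("generator eigenvalue error decays spectrally with m_delay", {
  lin <- linearize(ref_model(c = 1))
  # track the mode-0 complex pair (the least-smooth of the rightmost roots)
  exact <- solve_mode_roots(lin, 0)
  lam0 <- complex(real = exact$re[1], imaginary = exact$im[1])
  err <- vapply(c(8, 12, 16, 24), function(m) {
    ev <- generator_eigenvalues(lin, n_space = 24, m_delay = m)
    min(Mod(ev - lam0))
  }, numeric(1))
  # error drops by orders of magnitude, faster than any fixed power
  expect_lt(err[4], 1e-9)
  expect_gt(err[1] / err[3], 50)
})

test_that("number of eigenvalues right of the essential spectrum is stable", {
  lin <- linearize(ref_model(c = 1))
  count_right <- function(m_delay) {
    ev <- generator_eigenvalues(lin, n_space = 32, m_delay = m_delay)
    sum(Re(ev) > -1 + 0.3)
  }
  expect_equal(count_right(16), count_right(24))
})

test_that("spectrum assembly reconciles methods and issues verdicts", {
  # zero connectivity: abscissa = -l, stable
  sp0 <- assemble_spectrum(linearize(zero_model(c = 1, n = 16)),
                           method = "modes", modes = 0:4)
  expect_equal(sp0$abscissa, -1, tolerance = 1e-10)
  expect_equal(sp0$verdict, "stable")
  expect_equal(sp0$essential, -1)

  sp <- assemble_spectrum(linearize(ref_model(c = 1)), method = "both",
                          modes = 0:12, n_space = 32, m_delay = 24)
  expect_equal(sp$verdict, "unstable")
  expect_equal(sp$abscissa, 0.06476619, tolerance = 1e-6)

  # the verdict flips from stable to unstable across the pitchfork at c = 0
  s0 <- ref_sigma0()
  sp_lo <- assemble_spectrum(linearize(ref_model(c = 0, gain = s0 - 0.05)),
                             method = "modes", modes = 0:8)
  sp_hi <- assemble_spectrum(linearize(ref_model(c = 0, gain = s0 + 0.05)),
                             method = "modes", modes = 0:8)
  expect_equal(sp_lo$verdict, "stable")
  expect_equal(sp_hi$verdict, "unstable")
})
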