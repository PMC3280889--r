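test_that("non-delayed decay rate follows the self-adjoint closed form", {
  m <- ref_model(gain = 0.4)
  d <- nondelayed_decay(linearize(m))
  expect_true(d$self_adjoint)
  expect_equal(d$M, 1)
  expect_equal(d$epsilon, 1 - 0.4 * 0.25 * 1.5 * pi, tolerance = 1e-12)
  # epsilon vanishes exactly at the pitchfork gain
  d0 <- nondelayed_decay(linearize(ref_model(gain = ref_sigma0())))
  expect_lt(abs(d0$epsilon), 1e-12)
  # zero connectivity: epsilon = l
  dz <- nondelayed_decay(linearize(zero_model()))
  expect_equal(dz$epsilon, 1)
})

test_that("kernel norms: closed ring forms, matrix-path agreement, ordering", {
  m <- ref_model(gain = 0.7, n = 96)
  lin <- linearize(m)
  nrm <- kernel_norms(lin)
  # hs = sigma s1 sqrt(2 pi (2 pi a0^2 + pi a1^2)); op = sigma s1 max|Jhat|
  expect_equal(nrm$hs, 0.7 * 0.25 * sqrt(2 * pi * (2 * pi + 1.5^2 * pi)),
               tolerance = 1e-12)
  expect_equal(nrm$op, 0.7 * 0.25 * 2 * pi, tolerance = 1e-12)
  expect_lte(nrm$op, nrm$hs)

  # same model with a tabulated kernel matrix goes through the generic path
  mt <- neural_field_model(
    m$grid, leak = 1,
    kernel = list(type = "matrix",
                  values = delayfield:::kernel_matrix(m)),
    delay = list(type = "matrix",
                 values = delayfield:::delay_matrix(m)),
    sigmoid = m$sigmoid)
  st <- find_stationary(mt, guesses = list(rep(0, 96)))
  lint <- linearize(mt, st[[1]])
  nrmt <- kernel_norms(lint)
  expect_false(lint$homogeneous)
  expect_equal(nrmt$hs, nrm$hs, tolerance = 1e-10)
  expect_equal(nrmt$op, nrm$op, tolerance = 1e-10)
  dt <- nondelayed_decay(lint)
  expect_equal(dt$epsilon, nondelayed_decay(lin)$epsilon, tolerance = 1e-10)
  expect_equal(dt$M, 1)
})

test_that("delay-independent condition flips at the norm threshold", {
  lz <- linearize(zero_model())
  cz <- delay_independent_condition(lz)
  expect_true(cz$verdict)
  expect_equal(cz$margin, 1)

  sigma2 <- 1 / (0.25 * sqrt(2 * pi * (2 * pi + 1.5^2 * pi)))
  expect_lt(sigma2, ref_sigma0()) # more conservative than the pitchfork
  below <- delay_independent_condition(linearize(ref_model(gain = sigma2 - 0.01)))
  above <- delay_independent_condition(linearize(ref_model(gain = sigma2 + 0.01)))
  expect_true(below$verdict)
  expect_false(above$verdict)
  expect_lte(above$op, above$hs)
})

test_that("contraction constant: admissibility, c-linearity, monotonicity", {
  m <- ref_model(c = 0.4, gain = 0.4)
  lin <- linearize(m)
  dec <- nondelayed_decay(lin)
  k1 <- contraction_constant(0.2, lin, dec)
  expect_gt(k1, 0)
  # exactly linear in the delay scale on the ring
  k2 <- contraction_constant(0.2, linearize(set_gain(m, 0.4, c = 0.8)), dec)
  expect_equal(k2, 2 * k1, tolerance = 1e-10)
  # beta >= 1/2 is inadmissible on the 1-D ring when J(0) != 0
  expect_true(is.na(contraction_constant(0.6, lin, dec)))
  # unstable non-delayed state: no certification possible
  dec_bad <- list(epsilon = -0.1, M = 1, self_adjoint = TRUE)
  expect_true(is.na(contraction_constant(0.2, lin, dec_bad)))
  expect_error(contraction_constant(-1, lin, dec), "beta")
})

test_that("delay-dependent condition: c = 0 limit and monotone verdict in c", {
  m0 <- ref_model(c = 0, gain = 0.4)
  r0 <- delay_dependent_condition(linearize(m0))
  expect_true(r0$verdict)
  expect_equal(r0$alpha_star, 0)

  cb <- max_stable_delay_scale(ref_model(gain = 0.4))
  expect_gt(cb, 0)
  r_in <- delay_dependent_condition(linearize(ref_model(c = 0.9 * cb,
                                                        gain = 0.4)))
  r_out <- delay_dependent_condition(linearize(ref_model(c = 1.1 * cb,
                                                         gain = 0.4)))
  expect_true(r_in$verdict)
  expect_false(r_out$verdict)

  # above the pitchfork the non-delayed state is unstable: verdict FALSE
  r_bad <- delay_dependent_condition(linearize(ref_model(c = 0.1, gain = 1.2)))
  expect_false(r_bad$verdict)
  expect_equal(max_stable_delay_scale(ref_model(gain = 1.2)), 0)
})

test_that("bounds report is internally consistent", {
  b <- stability_bounds(ref_model(c = 0.05, gain = 0.4))
  expect_s3_class(b, "nf_bounds")
  expect_lte(b$op_norm, b$hs_norm)
  expect_true(b$cond1) # small delay, stable without delays
  expect_true(b$cond2) # gain below the norm threshold
  expect_gt(b$margin2, 0)
  expect_lt(b$alpha_star, 1)
  expect_output(print(b), "certified")
})

test_that("bound regions are subsets of the CV-stable region (small grid)", {
  m <- ref_model(n = 48)
  mp <- stability_map(m, c_values = seq(0, 4, length.out = 6),
                      sigma_values = seq(0.1, 1.5, length.out = 6))
  expect_false(any(mp$flagged))
  # sufficiency: certified cells are never CV-unstable
  expect_true(all(mp$cv_stable[mp$cond1]))
  expect_true(all(mp$cv_stable[mp$cond2]))
  # strictness: the CV method certifies more than either bound
  expect_gt(sum(mp$cv_stable), sum(mp$cond1))
  expect_gt(sum(mp$cv_stable), sum(mp$cond2))
})

test_that("inverse-power delay kernels on the disk integrate iff beta < 1", {
  conv <- disk_power_integral_converges(0.8)
  expect_true(conv$converges)
  expect_equal(conv$exponent, 2 - 2 * 0.8, tolerance = 1e-3)
  expect_false(disk_power_integral_converges(1.05)$converges)
  expect_false(disk_power_integral_converges(1.0)$converges)
  thr <- disk_integrability_threshold()
  expect_equal(thr, 1, tolerance = 5e-3)
})
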