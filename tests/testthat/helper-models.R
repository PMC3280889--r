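# Reference kernel J(z) = -1 + 1.5 cos(2z): lateral-inhibition ring model
# with unit leak; pitchfork mode k = 2 at sigma0 = l / (s1 * 1.5 * pi).
ref_coeffs <- rbind(c(0, -1), c(2, 1.5))

ref_model <- function(c = 1, gain = 1, n = 64, slope = 0.25, leak = 1) {
  make_ring_model(ref_coeffs, c = c, gain = gain, n = n, slope = slope,
                  leak = leak)
}

zero_model <- function(c = 0.5, n = 16) {
  make_ring_model(matrix(numeric(0), 0, 2), c = c, n = n)
}

ref_sigma0 <- function(leak = 1, slope = 0.25) leak / (slope * 1.5 * pi)

# winding number of Delta_k along the boundary of a rectangle in the complex
# plane (argument-principle oracle for the root counts)
winding_number <- function(lin, k, re_lim, im_lim, n = 4000) {
  path <- c(
    complex(real = seq(re_lim[1], re_lim[2], length.out = n),
            imaginary = im_lim[1]),
    complex(real = re_lim[2],
            imaginary = seq(im_lim[1], im_lim[2], length.out = n)),
    complex(real = seq(re_lim[2], re_lim[1], length.out = n),
            imaginary = im_lim[2]),
    complex(real = re_lim[1],
            imaginary = seq(im_lim[2], im_lim[1], length.out = n)))
  v <- char_residual(lin, k, path)
  inc <- Arg(v[-1] / v[-length(v)])
  sum(inc) / (2 * pi)
}

# numeric quadrature oracle for the delayed kernel transform
# G_k(lambda) = int_ring J(z) exp(-lambda c |z|) cos(k z) dz; the integrand
# is even, and smooth on [0, period/2] (the distance kink sits at the
# endpoints), so composite Simpson on the half-arc converges fast.
g_transform_quad <- function(coeffs, k, lambda, c, period = 2 * pi,
                             nq = 8001) {
  z <- seq(0, period / 2, length.out = nq)
  jz <- rep(0, nq)
  for (i in seq_len(nrow(coeffs)))
    jz <- jz + coeffs[i, 2] * cos(2 * pi * coeffs[i, 1] * z / period)
  f <- jz * exp(-lambda * c * z) * cos(2 * pi * k * z / period)
  h <- z[2] - z[1]
  wts <- rep(c(2, 4), length.out = nq); wts[1] <- 1; wts[nq] <- 1
  2 * sum(wts * f) * h / 3
}
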