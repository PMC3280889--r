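#' Stationary (persistent) states
#'
#' Finds time-independent solutions of the field equation, i.e. roots of
#' `-l V + integral J(x,y) S(sigma (V(y) - h)) dy + I_ext = 0`. Stationary
#' states do not depend on the delays, so they are computed from the
#' non-delayed fixed-point equation by a damped (line-searched) Newton
#' iteration from each guess; converged states are deduplicated and sorted
#' by weighted L2 norm.
#'
#' @param model an `nf_model` (time-constant external current).
#' @param guesses list of starting fields (vectors over the grid); by
#'   default the zero field, uniform fields `+-1/2`, and `+-cos` bumps for
#'   each kernel wavenumber.
#' @param tol residual tolerance in weighted L2 norm.
#' @param max_iter Newton iteration cap per guess.
#' @return a list of `nf_stationary` objects (fields `values`, `residual`,
#'   `norm`); empty if no guess converged.
#' @export
find_stationary <- function(model, guesses = NULL, tol = 1e-11,
                            max_iter = 60L) {
  stopifnot(inherits(model, "nf_model"))
  if (is.function(model$I_ext))
    stop("find_stationary requires a time-constant external current")
  x <- model$grid$nodes
  w <- model$grid$weights
  n <- length(x)
  sg <- model$sigmoid
  jw <- kernel_matrix(model) * rep(w, each = n)
  ie <- rep_len(as.numeric(model$I_ext), n)
  l <- model$leak

  ff <- function(v) -l * v + as.vector(
    jw %*% sigmoid(sg$gain * (v - sg$threshold), sg)) + ie
  jac <- function(v) {
    d <- sg$gain * sigmoid_deriv(sg$gain * (v - sg$threshold), sg)
    -l * diag(n) + jw * rep(d, each = n)
  }
  wnorm <- function(v) sqrt(sum(w * v^2))

  if (is.null(guesses)) {
    guesses <- list(rep(0, n), rep(0.5, n), rep(-0.5, n))
    if (model$kernel$type == "cosine" && nrow(model$kernel$coeffs)) {
      for (k in model$kernel$coeffs[, 1L]) {
        if (k > 0) {
          bump <- cos(2 * pi * k * x / model$grid$period)
          guesses <- c(guesses, list(bump, -bump))
        }
      }
    }
  }

  states <- list()
  for (g in guesses) {
    v <- rep_len(as.numeric(g), n)
    if (any(!is.finite(v))) stop("non-finite guess")
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      f <- ff(v)
      r <- wnorm(f)
      if (r < tol) { ok <- TRUE; break }
      step <- tryCatch(solve(jac(v), -f), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        v_new <- v + lam * step
        if (wnorm(ff(v_new)) < r || lam < 1e-6) break
        lam <- lam / 2
      }
      v <- v_new
    }
    if (ok) {
      dup <- any(vapply(states, function(s) wnorm(s$values - v) < 1e-6,
                        logical(1)))
      if (!dup)
        states[[length(states) + 1L]] <- structure(
          list(values = v, residual = wnorm(ff(v)), norm = wnorm(v)),
          class = "nf_stationary")
    }
  }
  if (!length(states))
    message("find_stationary: no guess converged")
  states[order(vapply(states, `[[`, numeric(1), "norm"))]
}

#' @export
print.nf_stationary <- function(x, ...) {
  cat(sprintf("<nf_stationary> |V| = %.8g, residual = %.3g\n",
              x$norm, x$residual))
  invisible(x)
}

#' Linearize the field equation about a stationary state
#'
#' Builds the linearized delay operator about `state`: the effective kernel
#' is `Jtilde(x, y) = J(x, y) * sigma * S'(sigma (V^f(y) - h))`, the leak
#' and delays are unchanged. For a homogeneous ring model at a spatially
#' uniform state the linearization is a convolution and the Fourier modes
#' `cos(kx), sin(kx)` decouple, with mode gains
#' `g_k = sigma * S'(...) * Jhat_k`.
#'
#' @param model an `nf_model`.
#' @param state an `nf_stationary`, a numeric field over the grid, or `NULL`
#'   to use the trivial state `V = 0` (valid for a centered sigmoid with
#'   zero threshold and zero external current).
#' @return an object of class `nf_linearized`.
#' @export
linearize <- function(model, state = NULL) {
  stopifnot(inherits(model, "nf_model"))
  n <- length(model$grid$nodes)
  if (is.null(state)) {
    ie <- if (is.function(model$I_ext)) 1 else
      max(abs(rep_len(as.numeric(model$I_ext), n)))
    if (!(model$sigmoid$centered && model$sigmoid$threshold == 0 && ie == 0))
      stop("default state V = 0 requires a centered sigmoid, zero ",
           "threshold and zero external current; pass a stationary state")
    vf <- rep(0, n)
  } else if (inherits(state, "nf_stationary")) {
    vf <- state$values
  } else vf <- rep_len(as.numeric(state), n)

  sg <- model$sigmoid
  dvec <- sg$gain * sigmoid_deriv(sg$gain * (vf - sg$threshold), sg)
  homogeneous <- is_homogeneous_ring(model) &&
    diff(range(dvec)) < 1e-12 * max(1, abs(dvec[1]))
  jt <- kernel_matrix(model) * rep(dvec, each = n)

  structure(
    list(model = model, grid = model$grid, leak = model$leak,
         state = vf, Jtilde = jt, delay = model$delay,
         homogeneous = homogeneous,
         factor = if (homogeneous) dvec[1] else NA_real_,
         coeffs = if (homogeneous) model$kernel$coeffs else NULL),
    class = "nf_linearized"
  )
}

#' Mode gains of a homogeneous linearization
#'
#' `g_k = sigma * S'(sigma(V^f - h)) * Jhat_k`, the eigenvalue of the
#' (non-delayed) linearized connectivity operator on the `cos(kx)/sin(kx)`
#' eigenspace.
#'
#' @param lin an `nf_linearized` with `homogeneous = TRUE`.
#' @param k mode indices (vectorized).
#' @return numeric vector of gains (1/time).
#' @export
mode_gain <- function(lin, k) {
  if (!lin$homogeneous) stop("mode gains require a homogeneous linearization")
  lin$factor * fourier_cos_coefficient(lin$model, k)
}

# E(a, b, L) = int_0^L exp(-a z) cos(b z) dz, complex a, vectorized in a.
exp_cos_integral <- function(a, b, L) {
  den <- a^2 + b^2
  small <- Mod(a) < 1e-8 & b == 0
  out <- ifelse(small,
                L - a * L^2 / 2 + a^2 * L^3 / 6,
                (a + exp(-a * L) * (b * sin(b * L) - a * cos(b * L))) / den)
  out
}

# d/da of exp_cos_integral.
exp_cos_integral_da <- function(a, b, L) {
  den <- a^2 + b^2
  small <- Mod(a) < 1e-8 & b == 0
  num <- a + exp(-a * L) * (b * sin(b * L) - a * cos(b * L))
  dnum <- 1 + exp(-a * L) * (-L * (b * sin(b * L) - a * cos(b * L)) -
                               cos(b * L))
  ifelse(small, -L^2 / 2 + a * L^3 / 3, dnum / den - 2 * a * num / den^2)
}

# Delayed kernel transform G_k(lambda) = int_ring J(z) e^(-lambda c d(z))
# cos(q_k z) dz with q_k = 2 pi k / period, and its lambda-derivative.
# Exact (closed form) for cosine-series kernels; vectorized in lambda.
ring_kernel_transform <- function(lin, k, lambda, deriv = FALSE) {
  co <- lin$coeffs
  p <- lin$grid$period
  cc <- lin$delay$c
  L <- p / 2
  qk <- 2 * pi * k / p
  a <- lambda * cc
  g <- rep(0 + 0i, length(lambda))
  dg <- rep(0 + 0i, length(lambda))
  if (nrow(co)) {
    for (i in seq_len(nrow(co))) {
      qm <- 2 * pi * co[i, 1L] / p
      am <- co[i, 2L]
      g <- g + am * (exp_cos_integral(a, qm + qk, L) +
                     exp_cos_integral(a, abs(qm - qk), L))
      if (deriv)
        dg <- dg + am * (exp_cos_integral_da(a, qm + qk, L) +
                         exp_cos_integral_da(a, abs(qm - qk), L))
    }
  }
  if (deriv) list(g = g, dg = cc * dg) else g
}

#' Characteristic residual of a Fourier mode
#'
#' The linearized delay operator on the homogeneous ring acts diagonally on
#' the Fourier modes; a complex number `lambda` is a characteristic value
#' (eigenvalue of the infinitesimal generator) for mode `k` iff
#' \deqn{\Delta_k(\lambda) = \lambda + \ell -
#'  \sigma S'(0)\int_\Omega J(z)\, e^{-\lambda c\, d(z)} \cos(q_k z)\, dz = 0}
#' with `d` the ring distance and `q_k = 2*pi*k/period`. `char_residual`
#' evaluates `Delta_k(lambda)` (analytic in `lambda`; closed form for
#' cosine-series kernels). At `c = 0` it reduces to
#' `lambda + l - g_k`, and at `lambda = 0` the delay dependence drops out
#' entirely, which is why the pitchfork line is vertical in the
#' (delay, gain) plane.
#'
#' @param lin an `nf_linearized` with `homogeneous = TRUE`.
#' @param k mode index (single nonnegative integer).
#' @param lambda complex (vectorized).
#' @return complex values of `Delta_k(lambda)`.
#' @export
char_residual <- function(lin, k, lambda) {
  if (!inherits(lin, "nf_linearized")) stop("'lin' must be an nf_linearized")
  if (!lin$homogeneous)
    stop("characteristic equation requires a homogeneous ring ",
         "linearization; use the generator matrix instead")
  lambda + lin$leak - lin$factor * ring_kernel_transform(lin, k, lambda)
}

#' Characteristic roots of one Fourier mode
#'
#' Solves `Delta_k(lambda) = 0` by complex Newton iteration (analytic
#' derivative) started from a rectangular grid covering the requested
#' region of the upper half-plane; converged roots are polished to residual
#' below `tol`, deduplicated, and returned with nonnegative imaginary part
#' (complex roots come in conjugate pairs since the kernel and delays are
#' real).
#'
#' @param lin an `nf_linearized`, homogeneous.
#' @param k single mode index, or vector of modes (results are stacked).
#' @param region list with `re = c(lo, hi)` and `im_max`; default
#'   `re = c(-l - 1, 2)` and `im_max = max(20, 10 / (tau_m + 0.1))`
#'   (delay-induced roots have imaginary parts scaling like `1/tau_m`).
#' @param density approximate number of Newton starts per unit length of the
#'   real axis (imaginary spacing is twice as coarse).
#' @param tol residual tolerance for an accepted root.
#' @return data frame with columns `mode`, `re`, `im`, `residual`,
#'   `conjugate_pair`, sorted by decreasing real part.
#' @export
solve_mode_roots <- function(lin, k = 0:16, region = NULL, density = 4,
                             tol = 1e-10) {
  if (!lin$homogeneous) stop("solve_mode_roots requires a homogeneous ring")
  l <- lin$leak
  tau_m <- lin$delay$tau_max
  if (is.null(region))
    region <- list(re = c(-l - 1, 2),
                   im_max = max(20, 10 / (tau_m + 0.1)))
  res <- lapply(k, function(kk)
    mode_roots_one(lin, kk, region, density, tol))
  out <- do.call(rbind, res)
  out[order(-out$re), , drop = FALSE]
}

mode_roots_one <- function(lin, k, region, density, tol) {
  re_s <- seq(region$re[1], region$re[2], length.out =
                max(4L, ceiling(diff(region$re) * density)))
  im_s <- seq(0, region$im_max, length.out =
                max(4L, ceiling(region$im_max * density / 2)))
  lam <- as.vector(outer(re_s, 1i * im_s, `+`))
  for (it in 1:60) {
    gd <- ring_kernel_transform(lin, k, lam, deriv = TRUE)
    f <- lam + lin$leak - lin$factor * gd$g
    df <- 1 - lin$factor * gd$dg
    step <- f / df
    step[!is.finite(step)] <- 0
    lam <- lam - step
    lam[!is.finite(lam)] <- NA_complex_
  }
  lam <- lam[!is.na(lam)]
  resid <- Mod(char_residual(lin, k, lam))
  keep <- resid < tol & Im(lam) > -1e-9 &
    Re(lam) > region$re[1] - 0.5 & Re(lam) < region$re[2] + 0.5 &
    Im(lam) < region$im_max + 1
  lam <- lam[keep]
  lam[abs(Im(lam)) < 1e-9] <- complex(real = Re(lam[abs(Im(lam)) < 1e-9]),
                                      imaginary = 0)
  roots <- complex(0)
  for (z in lam[order(-Re(lam))])
    if (!length(roots) || min(Mod(roots - z)) > 1e-6)
      roots <- c(roots, z)
  if (!length(roots))
    return(data.frame(mode = integer(0), re = numeric(0), im = numeric(0),
                      residual = numeric(0), conjugate_pair = logical(0)))
  data.frame(mode = k, re = Re(roots), im = Im(roots),
             residual = Mod(char_residual(lin, k, roots)),
             conjugate_pair = Im(roots) > 1e-9)
}

#' Discretized infinitesimal generator of the linearized delay semigroup
#'
#' Collocation approximation `A_N` of the generator `A` acting on history
#' segments `u(theta, x)`, `theta` in `[-tau_m, 0]`: the generator is
#' `d/dtheta` away from `theta = 0`, and at `theta = 0` it applies the
#' delayed linear operator `-l u(0, x) + integral Jtilde(x, y)
#' u(-tau(x, y), y) dy`. The history direction uses Chebyshev-Gauss-Lobatto
#' collocation (`m_delay + 1` points, spectral differentiation, barycentric
#' interpolation at the lags); the spatial direction uses a uniform grid of
#' `n_space` nodes. For homogeneous ring models the boundary integral is
#' computed with Gauss-Legendre panels on the two smooth arcs on either side
#' of the kink of the ring distance, combined with trigonometric
#' interpolation back to the uniform nodes, preserving spectral accuracy;
#' for tabulated kernels the grid trapezoid rule is used (second-order in
#' `n_space`). Eigenvalues of `A_N` converge (spectrally in `m_delay`) to
#' the characteristic values, with the essential-spectrum point `-l` showing
#' up as an accumulation of eigenvalues.
#'
#' @param lin an `nf_linearized`.
#' @param n_space spatial nodes (>= 16); for tabulated models the model grid
#'   is used and `n_space` is ignored.
#' @param m_delay Chebyshev degree in the history direction (>= 8).
#' @param gauss_n Gauss-Legendre points per smooth arc (homogeneous path).
#' @return dense real matrix of size `(m_delay + 1) * n_space` (or the
#'   non-delayed `n x n` operator when `tau_m = 0`).
#' @export
build_generator_matrix <- function(lin, n_space = 64, m_delay = 30,
                                   gauss_n = 32) {
  stopifnot(inherits(lin, "nf_linearized"))
  l <- lin$leak
  tau_m <- lin$delay$tau_max
  if (tau_m == 0) {
    # degenerate (no delays): the generator is the non-delayed operator
    if (lin$homogeneous) {
      g <- ring_grid(n_space, lin$grid$period)
      n <- n_space
      z <- outer(g$nodes, g$nodes, `-`)
      jt <- lin$factor * kernel_values(lin$coeffs, z, g$period)
      return(-l * diag(n) + jt * rep(g$weights, each = n))
    }
    n <- length(lin$grid$nodes)
    return(-l * diag(n) + lin$Jtilde * rep(lin$grid$weights, each = n))
  }
  if (m_delay < 8) stop("'m_delay' must be >= 8")

  if (lin$homogeneous) {
    if (n_space < 16) stop("'n_space' must be >= 16")
    g <- ring_grid(n_space, lin$grid$period)
    n <- n_space
    cs <- cheb_segment(m_delay, tau_m)
    half <- lin$grid$period / 2
    g1 <- gauss_legendre(gauss_n, 0, half)
    g2 <- gauss_legendre(gauss_n, -half, 0)
    zg <- c(g1$nodes, g2$nodes)
    wg <- c(g1$weights, g2$weights)
    jg <- lin$factor * kernel_values(lin$coeffs, zg, g$period)
    dg <- abs(zg)
    h <- g$period / n

    m1 <- m_delay + 1L
    a <- matrix(0, m1 * n, m1 * n)
    idx <- function(m, i) m * n + i # m = 0..m_delay, i = 1..n
    for (m in seq_len(m_delay)) for (mp in 0:m_delay)
      a[cbind(idx(m, seq_len(n)), idx(mp, seq_len(n)))] <-
        cs$diff[m + 1L, mp + 1L]
    for (i in seq_len(n)) a[idx(0L, i), idx(0L, i)] <- -l
    jj <- seq_len(n)
    for (gidx in seq_along(zg)) {
      lth <- bary_row(-lin$delay$c * dg[gidx], cs$theta, cs$bary)
      tv <- trig_cardinal((0:(n - 1L)) * h - zg[gidx], n)
      for (i in seq_len(n)) {
        coefs <- wg[gidx] * jg[gidx] * tv[((i - jj) %% n) + 1L]
        for (m in 0:m_delay)
          a[idx(0L, i), idx(m, jj)] <- a[idx(0L, i), idx(m, jj)] +
            lth[m + 1L] * coefs
      }
    }
    return(a)
  }

  # general tabulated model: trapezoid boundary quadrature on the model grid
  n <- length(lin$grid$nodes)
  w <- lin$grid$weights
  tau <- delay_matrix(lin$model)
  cs <- cheb_segment(m_delay, tau_m)
  m1 <- m_delay + 1L
  a <- matrix(0, m1 * n, m1 * n)
  idx <- function(m, i) m * n + i
  for (m in seq_len(m_delay)) for (mp in 0:m_delay)
    a[cbind(idx(m, seq_len(n)), idx(mp, seq_len(n)))] <-
      cs$diff[m + 1L, mp + 1L]
  for (i in seq_len(n)) {
    a[idx(0L, i), idx(0L, i)] <- a[idx(0L, i), idx(0L, i)] - l
    for (j in seq_len(n)) {
      lth <- bary_row(-tau[i, j], cs$theta, cs$bary)
      a[idx(0L, i), idx(0:m_delay, j)] <-
        a[idx(0L, i), idx(0:m_delay, j)] + w[j] * lin$Jtilde[i, j] * lth
    }
  }
  a
}

#' Eigenvalues of the discretized generator
#'
#' Convenience wrapper: builds `A_N` and returns its eigenvalues sorted by
#' decreasing real part.
#'
#' @inheritParams build_generator_matrix
#' @return complex vector of eigenvalues.
#' @export
generator_eigenvalues <- function(lin, n_space = 64, m_delay = 30,
                                  gauss_n = 32) {
  a <- build_generator_matrix(lin, n_space, m_delay, gauss_n)
  ev <- eigen(a, only.values = TRUE)$values
  ev[order(-Re(ev))]
}

#' Spectrum of the linearized delay operator and stability verdict
#'
#' Assembles the spectrum from one or both methods: per-mode characteristic
#' roots (`"modes"`, homogeneous ring only) and eigenvalues of the
#' discretized generator (`"generator"`). The essential spectrum is the
#' leak spectrum `{-l}` (the characteristic values accumulate there); the
#' spectral abscissa is the largest real part over the computed
#' characteristic values, and the verdict is `"stable"` if the abscissa is
#' below `-tol_marginal`, `"unstable"` if above `tol_marginal`, and
#' `"marginal"` in between (three-valued to avoid overclaiming at
#' bifurcation points). With `method = "both"` the two methods are
#' reconciled: each of the rightmost generator eigenvalues must match a mode
#' root within `reconcile_tol`, otherwise a consistency error is raised.
#'
#' @param lin an `nf_linearized`.
#' @param method `"both"` (default, homogeneous ring), `"modes"`, or
#'   `"generator"`.
#' @param modes mode indices for the root solver.
#' @param n_space,m_delay generator discretization (see
#'   [build_generator_matrix()]).
#' @param n_reconcile number of rightmost generator eigenvalues checked
#'   against the mode roots.
#' @param reconcile_tol allowed cross-method disagreement.
#' @param tol_marginal marginality tolerance on the abscissa.
#' @return an object of class `nf_spectrum`: `essential`, `roots` (data
#'   frame), `abscissa`, `verdict`, `method`, and (if computed)
#'   `generator_values`.
#' @export
assemble_spectrum <- function(lin, method = c("both", "modes", "generator"),
                              modes = 0:16, n_space = 64, m_delay = 30,
                              n_reconcile = 10, reconcile_tol = 1e-4,
                              tol_marginal = 1e-6) {
  method <- match.arg(method)
  if (!lin$homogeneous && method != "generator") {
    if (method == "both") method <- "generator"
    else stop("mode roots require a homogeneous ring linearization")
  }
  roots <- NULL
  gev <- NULL
  if (method %in% c("both", "modes"))
    roots <- solve_mode_roots(lin, modes)
  if (method %in% c("both", "generator"))
    gev <- generator_eigenvalues(lin, n_space, m_delay)

  if (method == "both") {
    top <- gev[Im(gev) >= -1e-9]
    top <- top[seq_len(min(n_reconcile, length(top)))]
    rl <- complex(real = roots$re, imaginary = roots$im)
    for (z in top) {
      if (!length(rl) || min(Mod(rl - z)) > reconcile_tol)
        stop(sprintf(
          "spectral methods disagree: generator eigenvalue %.8g%+.8gi has no mode root within %g",
          Re(z), Im(z), reconcile_tol))
    }
  }

  if (is.null(roots)) {
    keep <- Im(gev) >= -1e-9
    roots <- data.frame(mode = NA_integer_, re = Re(gev[keep]),
                        im = Im(gev[keep]), residual = NA_real_,
                        conjugate_pair = Im(gev[keep]) > 1e-9)
  }
  abscissa <- if (nrow(roots)) max(roots$re) else -lin$leak
  verdict <- if (abscissa < -tol_marginal) "stable"
    else if (abscissa > tol_marginal) "unstable" else "marginal"
  structure(
    list(essential = -lin$leak, roots = roots, abscissa = abscissa,
         verdict = verdict, method = method, generator_values = gev),
    class = "nf_spectrum"
  )
}

#' @export
print.nf_spectrum <- function(x, ...) {
  cat(sprintf(
    "<nf_spectrum> method = %s; essential spectrum at %.6g\n",
    x$method, x$essential))
  cat(sprintf("  %d characteristic roots (upper half-plane), abscissa = %.8g\n",
              nrow(x$roots), x$abscissa))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Spectral abscissa of the linearization
#'
#' Largest real part over the characteristic values, computed from the
#' per-mode characteristic equation (homogeneous ring). Negative abscissa
#' means the stationary state is asymptotically stable.
#'
#' @param lin an `nf_linearized`, homogeneous.
#' @param modes mode indices scanned.
#' @param region optional root-search region (see [solve_mode_roots()]).
#' @return the abscissa (1/time).
#' @export
spectral_abscissa <- function(lin, modes = 0:12, region = NULL) {
  r <- solve_mode_roots(lin, modes, region)
  if (!nrow(r)) -lin$leak else max(r$re)
}
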