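#' Decay of the non-delayed linearized semigroup
#'
#' The delay-dependent sufficient condition requires the semigroup of the
#' *non-delayed* linearization `Ltilde = -L0 + Jtilde` to decay:
#' `|e^(Ltilde t)| <= M_eps e^(-eps t)` with `eps > 0`. On the homogeneous
#' ring `Ltilde` is a self-adjoint convolution operator, so `M_eps = 1` and
#' `eps = l - max(0, max_k g_k)` (the 0 accounts for the accumulation of the
#' mode gains at 0). For tabulated kernels the spectrum of the discretized
#' operator is used; `M_eps = 1` when the weighted kernel matrix is
#' symmetric, otherwise the eigenvector condition number is reported as a
#' computable bound.
#'
#' @param lin an `nf_linearized`.
#' @return list with `epsilon`, `M`, `self_adjoint`.
#' @export
nondelayed_decay <- function(lin) {
  stopifnot(inherits(lin, "nf_linearized"))
  l <- lin$leak
  if (lin$homogeneous) {
    ks <- if (nrow(lin$coeffs)) lin$coeffs[, 1L] else integer(0)
    gmax <- if (length(ks)) max(0, mode_gain(lin, ks)) else 0
    return(list(epsilon = l - gmax, M = 1, self_adjoint = TRUE))
  }
  w <- lin$grid$weights
  b <- sqrt(w) * lin$Jtilde * rep(sqrt(w), each = length(w))
  sym <- max(abs(b - t(b))) < 1e-10 * max(1, max(abs(b)))
  lmat <- -l * diag(length(w)) + b
  e <- eigen(lmat, symmetric = sym)
  eps <- -max(Re(e$values))
  m <- if (sym) 1 else kappa(e$vectors, exact = TRUE)
  list(epsilon = eps, M = m, self_adjoint = sym)
}

#' Norms of the linearized connectivity operator
#'
#' Hilbert-Schmidt norm `|Jtilde|_HS` on `L2(Omega^2)` and operator norm on
#' the weighted `L2(Omega)`; `op <= hs` always. On the ring both have closed
#' forms (`hs = |factor| sqrt(P int J(z)^2 dz)` by Parseval,
#' `op = |factor| max_k |Jhat_k|`).
#'
#' @param lin an `nf_linearized`.
#' @return list with `hs` and `op` (1/time).
#' @export
kernel_norms <- function(lin) {
  stopifnot(inherits(lin, "nf_linearized"))
  if (lin$homogeneous) {
    p <- lin$grid$period
    co <- lin$coeffs
    int_j2 <- if (nrow(co))
      sum(ifelse(co[, 1L] == 0, p, p / 2) * co[, 2L]^2) else 0
    ks <- if (nrow(co)) co[, 1L] else integer(0)
    op <- if (length(ks)) max(abs(mode_gain(lin, ks))) else 0
    return(list(hs = abs(lin$factor) * sqrt(p * int_j2), op = op))
  }
  w <- lin$grid$weights
  hs <- sqrt(sum(outer(w, w) * lin$Jtilde^2))
  b <- sqrt(w) * lin$Jtilde * rep(sqrt(w), each = length(w))
  list(hs = hs, op = max(svd(b, nu = 0, nv = 0)$d))
}

# ||Jtilde * tau^(-beta)||_HS on L2(Omega^2); NA when tau^(-beta) fails to be
# square-integrable against Jtilde^2. Ring: adaptive quadrature of
# P * int J(z)^2 (c d(z))^(-2 beta) dz with the endpoint singularity at 0.
weighted_kernel_hs <- function(lin, beta) {
  if (lin$homogeneous) {
    cc <- lin$delay$c
    if (cc == 0) return(NA_real_)
    p <- lin$grid$period
    co <- lin$coeffs
    j0 <- kernel_values(co, 0, p)
    thresh <- if (abs(j0) < 1e-14) 1.5 else 0.5
    if (beta >= thresh) return(NA_real_)
    f <- function(z) kernel_values(co, z, p)^2 * z^(-2 * beta)
    q <- tryCatch(
      stats::integrate(f, 0, p / 2, rel.tol = 1e-10, abs.tol = 0),
      error = function(e) NULL)
    if (is.null(q)) return(NA_real_)
    return(abs(lin$factor) * cc^(-beta) * sqrt(2 * p * q$value))
  }
  tau <- delay_matrix(lin$model)
  if (any(tau == 0 & abs(lin$Jtilde) > 0)) return(NA_real_)
  w <- lin$grid$weights
  x <- lin$Jtilde^2 * ifelse(tau > 0, tau^(-2 * beta), 0)
  sqrt(sum(outer(w, w) * x))
}

#' Contraction constant of the delay-dependent stability condition
#'
#' The delayed linearization can be written as the non-delayed one plus the
#' time derivative of `Z(t) = integral Jtilde(x, y)
#' int_(t - tau(x,y))^t U(s, y) ds dy`; Cauchy-Schwarz bounds
#' `|Z(t)| <= tau_m^(1 + beta) |Jtilde tau^(-beta)|_HS sup |U|` for any
#' `beta > 0` with `tau^(-beta)` square-integrable, and the
#' variation-of-constants formula then shows that the fixed-point map is a
#' contraction with constant
#' \deqn{K(\beta) = \left(1 + M_\epsilon
#'   \|\tilde L\|/\epsilon\right)\, \tau_m^{1+\beta}\,
#'   \|\tilde J\, \tau^{-\beta}\|_{HS}.}
#' `K < 1` for some admissible `beta` is sufficient for asymptotic
#' stability. On the ring `K` is exactly linear in the delay scale `c`, so a
#' stable non-delayed state tolerates all `c` below `1/K(beta; c = 1)`:
#' small delays never destabilize.
#'
#' @param beta exponent, > 0.
#' @param lin an `nf_linearized`.
#' @param decay output of [nondelayed_decay()] (must have `epsilon > 0`).
#' @return `K(beta)` (dimensionless), or `NA` if `tau^(-beta)` is not
#'   square-integrable against the kernel.
#' @export
contraction_constant <- function(beta, lin, decay = nondelayed_decay(lin)) {
  if (beta <= 0) stop("'beta' must be > 0")
  if (decay$epsilon <= 0) return(NA_real_)
  tau_m <- lin$delay$tau_max
  if (tau_m == 0) return(0)
  whs <- weighted_kernel_hs(lin, beta)
  if (is.na(whs)) return(NA_real_)
  l <- lin$leak
  if (lin$homogeneous) {
    ks <- if (nrow(lin$coeffs)) lin$coeffs[, 1L] else integer(0)
    lt_norm <- max(l, if (length(ks)) max(abs(-l + mode_gain(lin, ks))) else 0)
  } else {
    w <- lin$grid$weights
    b <- -l * diag(length(w)) +
      sqrt(w) * lin$Jtilde * rep(sqrt(w), each = length(w))
    lt_norm <- max(svd(b, nu = 0, nv = 0)$d)
  }
  (1 + decay$M * lt_norm / decay$epsilon) * tau_m^(1 + beta) * whs
}

#' Delay-independent sufficient stability condition
#'
#' The stationary state is asymptotically stable -- for *every* delay
#' function -- when the linearized connectivity is small against the leak:
#' `|Jtilde|_HS < l`. The certified verdict uses the Hilbert-Schmidt norm
#' (the quantity controlled by the Cauchy-Schwarz estimates); the sharper
#' operator norm is reported alongside for information.
#'
#' @param lin an `nf_linearized`.
#' @return list with `verdict`, `margin = l - hs`, `hs`, `op`,
#'   `op_margin = l - op`.
#' @export
delay_independent_condition <- function(lin) {
  nrm <- kernel_norms(lin)
  l <- lin$leak
  list(verdict = nrm$hs < l, margin = l - nrm$hs,
       hs = nrm$hs, op = nrm$op, op_margin = l - nrm$op)
}

#' Delay-dependent sufficient stability condition
#'
#' Requires the non-delayed linearization to decay (`epsilon > 0`; a state
#' unstable without delays is declared not certified immediately) and
#' searches a grid of exponents `beta` for a contraction constant
#' `K(beta) < alpha_max` (see [contraction_constant()]). Exponents with
#' non-square-integrable `tau^(-beta)` are skipped.
#'
#' @param lin an `nf_linearized`.
#' @param decay output of [nondelayed_decay()].
#' @param beta_grid exponents scanned; default 40 log-spaced points in
#'   `[1e-3, 0.999]`.
#' @param alpha_max contraction threshold (< 1 required by the theory;
#'   default 1, i.e. `K(beta) < 1`).
#' @return list with `verdict`, `beta_star`, `alpha_star` (the minimal
#'   contraction value), `skipped` (count of inadmissible exponents), and
#'   the scanned `beta_grid`/`K` values.
#' @export
delay_dependent_condition <- function(lin, decay = nondelayed_decay(lin),
                                      beta_grid = NULL, alpha_max = 1) {
  if (is.null(beta_grid))
    beta_grid <- exp(seq(log(1e-3), log(0.999), length.out = 40))
  if (decay$epsilon <= 0)
    return(list(verdict = FALSE, beta_star = NA_real_,
                alpha_star = NA_real_, skipped = 0L,
                beta_grid = beta_grid, K = rep(NA_real_, length(beta_grid))))
  if (lin$delay$tau_max == 0)
    return(list(verdict = TRUE, beta_star = NA_real_, alpha_star = 0,
                skipped = 0L, beta_grid = beta_grid,
                K = rep(0, length(beta_grid))))
  kv <- vapply(beta_grid, contraction_constant, numeric(1),
               lin = lin, decay = decay)
  ok <- !is.na(kv)
  if (!any(ok))
    return(list(verdict = FALSE, beta_star = NA_real_,
                alpha_star = NA_real_, skipped = sum(!ok),
                beta_grid = beta_grid, K = kv))
  j <- which.min(ifelse(ok, kv, Inf))
  list(verdict = kv[j] < alpha_max, beta_star = beta_grid[j],
       alpha_star = kv[j], skipped = sum(!ok),
       beta_grid = beta_grid, K = kv)
}

#' Sufficient stability bounds report
#'
#' Evaluates both sufficient conditions for the asymptotic stability of a
#' stationary state -- the delay-dependent contraction condition and the
#' delay-independent norm condition -- and collects the computable
#' ingredients (decay rate and semigroup constant of the non-delayed
#' linearization, kernel norms, maximal delay, best exponent and contraction
#' value). Both conditions are conservative: they certify stability but
#' their failure says nothing (the characteristic values decide then).
#'
#' @param lin an `nf_linearized` (or an `nf_model`, linearized about `V = 0`).
#' @param beta_grid,alpha_max see [delay_dependent_condition()].
#' @return an object of class `nf_bounds`.
#' @export
stability_bounds <- function(lin, beta_grid = NULL, alpha_max = 1) {
  if (inherits(lin, "nf_model")) lin <- linearize(lin)
  stopifnot(inherits(lin, "nf_linearized"))
  decay <- nondelayed_decay(lin)
  nrm <- kernel_norms(lin)
  c2 <- delay_independent_condition(lin)
  c1 <- delay_dependent_condition(lin, decay, beta_grid, alpha_max)
  structure(
    list(epsilon = decay$epsilon, M = decay$M,
         self_adjoint = decay$self_adjoint,
         hs_norm = nrm$hs, op_norm = nrm$op,
         tau_m = lin$delay$tau_max,
         beta_star = c1$beta_star, alpha_star = c1$alpha_star,
         cond1 = c1$verdict, cond2 = c2$verdict,
         margin1 = if (is.na(c1$alpha_star)) NA_real_ else
           alpha_max - c1$alpha_star,
         margin2 = c2$margin, skipped_beta = c1$skipped),
    class = "nf_bounds"
  )
}

#' @export
print.nf_bounds <- function(x, ...) {
  cat("<nf_bounds> sufficient stability conditions\n")
  cat(sprintf("  non-delayed decay: eps = %.6g, M = %.6g%s\n",
              x$epsilon, x$M, if (x$self_adjoint) " (self-adjoint)" else ""))
  cat(sprintf("  norms: |Jtilde|_HS = %.6g, op = %.6g; tau_m = %.6g\n",
              x$hs_norm, x$op_norm, x$tau_m))
  cat(sprintf("  delay-dependent:   %s (K = %.6g at beta = %.4g)\n",
              if (isTRUE(x$cond1)) "certified" else "not certified",
              x$alpha_star, x$beta_star))
  cat(sprintf("  delay-independent: %s (margin l - |Jtilde|_HS = %.6g)\n",
              if (isTRUE(x$cond2)) "certified" else "not certified",
              x$margin2))
  invisible(x)
}

#' Largest certified delay scale
#'
#' For a ring model whose stationary state is stable without delays
#' (`epsilon > 0`), the contraction constant is exactly linear in the delay
#' scale `c`, so the delay-dependent condition certifies stability for all
#' `c` below `alpha_max / K(beta; c = 1)`, maximized over admissible `beta`.
#' Returns 0 when `epsilon <= 0` and `Inf` when the connectivity vanishes.
#'
#' @param model a homogeneous ring `nf_model`.
#' @param beta_grid,alpha_max see [delay_dependent_condition()].
#' @return the certified delay-scale bound `c_bound >= 0`.
#' @export
max_stable_delay_scale <- function(model, beta_grid = NULL, alpha_max = 1) {
  stopifnot(inherits(model, "nf_model"))
  if (!is_homogeneous_ring(model))
    stop("max_stable_delay_scale requires a homogeneous ring model")
  m1 <- model
  m1$delay$c <- 1
  m1$delay$tau_max <- m1$grid$period / 2
  lin <- linearize(m1)
  decay <- nondelayed_decay(lin)
  if (decay$epsilon <= 0) return(0)
  c1 <- delay_dependent_condition(lin, decay, beta_grid, alpha_max)
  if (is.na(c1$alpha_star)) return(0)
  if (c1$alpha_star == 0) return(Inf)
  alpha_max / c1$alpha_star
}

#' Replace the sigmoid gain of a model
#'
#' Convenience for parameter sweeps in the (delay scale, gain) plane.
#'
#' @param model an `nf_model`.
#' @param gain new sigmoid gain, > 0.
#' @param c optional new delay scale (ring-delay models only).
#' @return the modified model.
#' @export
set_gain <- function(model, gain, c = NULL) {
  stopifnot(inherits(model, "nf_model"))
  model$sigmoid <- sigmoid_spec(gain = gain, threshold = model$sigmoid$threshold,
                                slope = model$sigmoid$slope,
                                centered = model$sigmoid$centered)
  if (!is.null(c)) {
    if (model$delay$type != "ring") stop("'c' applies to ring delays only")
    model$delay$c <- c
    model$delay$tau_max <- c * model$grid$period / 2
  }
  model
}

# --- square-integrability of inverse-power delay kernels on a planar disk --

# int int_{D x D} |r - r'|^(-2 beta) dr dr' restricted to |r - r'| > delta,
# for the unit disk D, via the isotropic set covariogram
# K(s) = 2 acos(s/2) - (s/2) sqrt(4 - s^2):
# the pair integral reduces to 2 pi int_delta^2 s^(1 - 2 beta) K(s) ds.
disk_power_integral <- function(beta, delta) {
  f <- function(s) 2 * pi * s^(1 - 2 * beta) *
    (2 * acos(pmin(s / 2, 1)) - (s / 2) * sqrt(pmax(4 - s^2, 0)))
  stats::integrate(f, delta, 2, rel.tol = 1e-11, abs.tol = 0,
                   subdivisions = 400L)$value
}

#' Square-integrability of an inverse-power delay kernel on the unit disk
#'
#' The delay-dependent bound needs `tau^(-beta)` square-integrable over
#' `Omega^2`. With `tau` proportional to the Euclidean distance on a planar
#' (2-D) domain this holds iff `beta < 1`. This function decides
#' convergence of `int int |r - r'|^(-2 beta)` over the unit disk
#' numerically: the pair integral is reduced analytically (via the disk
#' covariogram) to a radial integral whose inner cutoff is refined
#' geometrically (`delta = 2^-m`); the increments between successive
#' refinements decay like `2^(-(2 - 2 beta) m)`, so the fitted decay
#' exponent is positive iff the integral converges.
#'
#' @param beta exponent, > 0.
#' @param m_max deepest refinement level.
#' @param slope_tol positive decay-exponent threshold declaring convergence.
#' @return list with `converges` (logical), `exponent` (fitted decay
#'   exponent, approximately `2 - 2 beta`), and the refinement `values`.
#' @export
disk_power_integral_converges <- function(beta, m_max = 14L,
                                          slope_tol = 1e-3) {
  stopifnot(beta > 0)
  ms <- 2:m_max
  vals <- vapply(ms, function(m) disk_power_integral(beta, 2^(-m)),
                 numeric(1))
  inc <- diff(vals)
  if (all(inc < 1e-13 * max(vals)))
    return(list(converges = TRUE, exponent = Inf, values = vals))
  tail_ratio <- inc[length(inc)] / inc[length(inc) - 1L]
  expo <- -log2(tail_ratio)
  list(converges = is.finite(expo) && expo > slope_tol,
       exponent = expo, values = vals)
}

#' Critical exponent for square-integrability on the disk
#'
#' Bisection on [disk_power_integral_converges()] between a convergent and a
#' divergent exponent; the analytic threshold for a 2-D domain is 1.
#'
#' @param lower,upper initial bracket (convergent / divergent).
#' @param tol bisection tolerance on the exponent.
#' @return the estimated threshold exponent.
#' @export
disk_integrability_threshold <- function(lower = 0.6, upper = 1.4,
                                         tol = 1e-3) {
  if (!disk_power_integral_converges(lower)$converges)
    stop("'lower' must be a convergent exponent")
  if (disk_power_integral_converges(upper)$converges)
    stop("'upper' must be a divergent exponent")
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (disk_power_integral_converges(mid)$converges) lower <- mid
    else upper <- mid
  }
  (lower + upper) / 2
}
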