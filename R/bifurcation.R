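#' Pitchfork gain of the ring model
#'
#' At `lambda = 0` the characteristic equation loses its delay dependence,
#' so a zero characteristic value exists at the *same* gain for every delay
#' scale: the pitchfork line is vertical in the (c, sigma) plane. For the
#' centered ring model the critical gain is
#' `sigma_0 = l / (s1 * max_k Jhat_k)`, attained at the mode `k*` with the
#' largest Fourier coefficient; no pitchfork exists when all coefficients
#' are nonpositive.
#'
#' @param model a homogeneous ring `nf_model` (centered sigmoid).
#' @return list with `sigma0` and `mode` (`k*`), or `NULL` when all
#'   coefficients are nonpositive.
#' @examples
#' m <- make_ring_model(rbind(c(0, -1), c(2, 1.5)))
#' pitchfork_gain(m)$sigma0 # l / (s1 * 1.5 * pi / 2 * 2) = 0.8488...
#' @export
pitchfork_gain <- function(model) {
  stopifnot(inherits(model, "nf_model"))
  if (!is_homogeneous_ring(model)) stop("requires a homogeneous ring model")
  co <- model$kernel$coeffs
  if (!nrow(co)) return(NULL)
  jh <- fourier_cos_coefficient(model, co[, 1L])
  if (max(jh) <= 0) return(NULL)
  j <- which.max(jh)
  list(sigma0 = model$leak / (model$sigmoid$slope * jh[j]),
       mode = as.integer(co[j, 1L]))
}

# All Hopf candidates of one mode at delay scale c: purely imaginary roots
# Delta_k(i omega) = 0 solved for (sigma, omega). Since the mode gain is
# linear in sigma, sigma is eliminated: omega must solve
# Im[(i omega + l) conj(G_k(i omega))] = 0 with
# sigma = Re[(i omega + l) / (s1 G_k(i omega))] real positive.
hopf_pairs_mode <- function(model, k, c, omega_max = 40, n_scan = 4000,
                            sigma_max = 50) {
  m <- set_gain(model, 1, c = c)
  lin <- linearize(m)
  s1 <- model$sigmoid$slope
  l <- model$leak
  g_of <- function(w) ring_kernel_transform(lin, k, 1i * w)
  w <- seq(1e-4, omega_max, length.out = n_scan)
  gw <- g_of(w)
  f <- Im((1i * w + l) * Conj(gw))
  sc <- which(f[-1] * f[-n_scan] < 0)
  out <- NULL
  for (j in sc) {
    r <- tryCatch(
      stats::uniroot(function(ww) Im((1i * ww + l) * Conj(g_of(ww))),
                     c(w[j], w[j + 1L]), tol = 1e-13),
      error = function(e) NULL)
    if (is.null(r)) next
    ww <- r$root
    gx <- g_of(ww)
    if (Mod(gx) < 1e-12) next
    sig <- Re((1i * ww + l) / (s1 * gx))
    if (is.finite(sig) && sig > 1e-8 && sig < sigma_max) {
      resid <- Mod(char_residual(linearize(set_gain(model, sig, c = c)),
                                 k, 1i * ww))
      out <- rbind(out, data.frame(c = c, sigma = sig, omega = ww,
                                   mode = k, residual = resid))
    }
  }
  out
}

#' Hopf curve in the (delay scale, gain) plane
#'
#' For each sampled delay scale `c` and each Fourier mode, finds the gains
#' at which a purely imaginary characteristic pair `+-(i omega)` exists, and
#' retains the minimal such gain (the Hopf stability boundary). Without
#' delays the ring model is gradient-like and no Hopf point exists; the
#' curve comes down from large gains as `c` grows.
#'
#' @param model a homogeneous ring `nf_model`.
#' @param c_range range of delay scales (positive).
#' @param n_samples number of samples in `c_range`.
#' @param modes Fourier modes scanned.
#' @param omega_max upper end of the frequency scan.
#' @param sigma_max discard Hopf candidates above this gain.
#' @return data frame of class `nf_hopf_curve` with columns `c`, `sigma`,
#'   `omega`, `mode`, `residual` (rows with `NA` mark sample points where no
#'   Hopf point below `sigma_max` exists).
#' @export
hopf_curve <- function(model, c_range = c(0.25, 5), n_samples = 40,
                       modes = 0:8, omega_max = 40, sigma_max = 50) {
  stopifnot(inherits(model, "nf_model"))
  if (any(c_range <= 0)) stop("'c_range' must be positive")
  cs <- seq(c_range[1], c_range[2], length.out = n_samples)
  rows <- lapply(cs, function(c) {
    best <- NULL
    for (k in modes) {
      hp <- hopf_pairs_mode(model, k, c, omega_max, sigma_max = sigma_max)
      if (!is.null(hp)) {
        cand <- hp[which.min(hp$sigma), , drop = FALSE]
        if (is.null(best) || cand$sigma < best$sigma) best <- cand
      }
    }
    if (is.null(best))
      best <- data.frame(c = c, sigma = NA_real_, omega = NA_real_,
                         mode = NA_integer_, residual = NA_real_)
    best
  })
  out <- do.call(rbind, rows)
  class(out) <- c("nf_hopf_curve", class(out))
  out
}

# Minimal Hopf gain at a single delay scale (helper for fold_hopf).
hopf_sigma_at <- function(model, c, modes = 0:8, omega_max = 40,
                          sigma_max = 50) {
  best <- Inf; w <- NA_real_; md <- NA_integer_
  for (k in modes) {
    hp <- hopf_pairs_mode(model, k, c, omega_max, sigma_max = sigma_max)
    if (!is.null(hp)) {
      j <- which.min(hp$sigma)
      if (hp$sigma[j] < best) { best <- hp$sigma[j]; w <- hp$omega[j]; md <- k }
    }
  }
  list(sigma = best, omega = w, mode = md)
}

#' Fold-Hopf point
#'
#' Locates the intersection of the Hopf curve with the (vertical) pitchfork
#' line `sigma = sigma_0`: the delay scale `c*` at which a zero
#' characteristic value (pattern mode) and a purely imaginary pair `+-i
#' omega*` coexist. Note that `c*` does not depend on the sigmoid slope
#' normalization: gain and slope enter the characteristic equation only
#' through their product, and `sigma_0 * s1` is fixed by the leak and the
#' kernel.
#'
#' @param model a homogeneous ring `nf_model`.
#' @param c_range delay-scale range searched.
#' @param n_scan coarse samples used to bracket the crossing.
#' @param modes,omega_max see [hopf_curve()].
#' @param tol tolerance on `c*`.
#' @return list with `found`, `c_star`, `omega_star`, `mode`, `sigma0`; when
#'   no crossing exists in the range, `found = FALSE` and the scanned range
#'   is reported.
#' @export
fold_hopf <- function(model, c_range = c(0.5, 6), n_scan = 25, modes = 0:8,
                      omega_max = 40, tol = 1e-6) {
  pf <- pitchfork_gain(model)
  if (is.null(pf)) stop("model has no pitchfork (all Jhat_k <= 0)")
  h <- function(c) hopf_sigma_at(model, c, modes, omega_max)$sigma - pf$sigma0
  cs <- seq(c_range[1], c_range[2], length.out = n_scan)
  hv <- vapply(cs, h, numeric(1))
  fin <- is.finite(hv)
  br <- which(fin[-1] & fin[-n_scan] & hv[-1] * hv[-n_scan] < 0)
  if (!length(br))
    return(list(found = FALSE, c_range = c_range, sigma0 = pf$sigma0))
  j <- br[1L]
  c_star <- stats::uniroot(h, c(cs[j], cs[j + 1L]), tol = tol)$root
  at <- hopf_sigma_at(model, c_star, modes, omega_max)
  list(found = TRUE, c_star = c_star, omega_star = at$omega,
       mode = at$mode, sigma0 = pf$sigma0)
}

#' Stability map over the (delay scale, gain) plane
#'
#' At each grid point computes the characteristic-value verdict (spectral
#' abscissa from the per-mode root solver) and the two sufficient bounds.
#' The bound regions are always subsets of the CV-stable region; the three
#' dynamical regimes (decay to rest, stationary pattern beyond the
#' pitchfork, oscillation beyond the Hopf curve) can be located from the
#' map. The delay-dependent bound exploits the exact linearity of the
#' contraction constant in `c`, so the whole `c` column of the map is
#' certified from one evaluation per gain.
#'
#' @param model a homogeneous ring `nf_model`.
#' @param c_values delay scales (>= 0).
#' @param sigma_values gains (> 0).
#' @param modes Fourier modes for the root solver.
#' @param density Newton start density (see [solve_mode_roots()]).
#' @return data frame of class `nf_stability_map` with columns `c`, `sigma`,
#'   `abscissa`, `cv_stable`, `cond1`, `cond2`, `flagged`; the pitchfork
#'   gain is attached as attribute `"sigma0"`.
#' @export
stability_map <- function(model, c_values, sigma_values, modes = 0:8,
                          density = 3) {
  stopifnot(inherits(model, "nf_model"))
  if (!is_homogeneous_ring(model)) stop("requires a homogeneous ring model")
  pf <- pitchfork_gain(model)
  rows <- vector("list", length(sigma_values) * length(c_values))
  ri <- 0L
  for (sig in sigma_values) {
    m1 <- set_gain(model, sig, c = 1)
    lin1 <- linearize(m1)
    decay <- nondelayed_decay(lin1)
    c2 <- delay_independent_condition(lin1)$verdict
    dd1 <- delay_dependent_condition(lin1, decay)
    k_unit <- dd1$alpha_star # K at c = 1; K(c) = c * K(1) on the ring
    for (cc in c_values) {
      lin <- linearize(set_gain(model, sig, c = cc))
      absc <- tryCatch(spectral_abscissa(lin, modes,
                                         region = list(re = c(-model$leak - 0.5, 1.5),
                                                       im_max = max(20, 10 / (lin$delay$tau_max + 0.1)))),
                       error = function(e) NA_real_)
      cond1 <- if (decay$epsilon <= 0) FALSE
        else if (cc == 0) TRUE
        else if (is.na(k_unit)) FALSE else cc * k_unit < 1
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        c = cc, sigma = sig, abscissa = absc,
        cv_stable = !is.na(absc) & absc < -1e-6,
        cond1 = cond1, cond2 = c2, flagged = is.na(absc))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "sigma0") <- if (is.null(pf)) NA_real_ else pf$sigma0
  class(out) <- c("nf_stability_map", class(out))
  out
}

#' @export
print.nf_stability_map <- function(x, ...) {
  cat(sprintf(
    "<nf_stability_map> %d cells: %d CV-stable, %d certified by the delay-dependent bound, %d by the delay-independent bound, %d flagged\n",
    nrow(x), sum(x$cv_stable), sum(x$cond1), sum(x$cond2), sum(x$flagged)))
  s0 <- attr(x, "sigma0")
  if (!is.na(s0)) cat(sprintf("  pitchfork gain sigma0 = %.6g\n", s0))
  invisible(x)
}
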