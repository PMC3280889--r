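#' Ring geometry and quadrature
#'
#' The reference domain is a one-dimensional ring (circle) of circumference
#' `period`, parameterized by angles in `[-period/2, period/2)`. Spatial
#' integrals use the periodic trapezoid rule (uniform nodes, equal weights),
#' which integrates trigonometric polynomials of degree below `n/2` exactly.
#'
#' @param n number of uniformly spaced nodes (>= 4).
#' @param period ring circumference (default `2*pi`).
#' @return an object of class `nf_grid` with fields `nodes`, `weights`,
#'   `period` and `dimension` (always 1 for the ring).
#' @examples
#' g <- ring_grid(64)
#' abs(sum(g$weights) - 2 * pi) < 1e-12
#' @export
ring_grid <- function(n, period = 2 * pi) {
  if (!is.numeric(n) || length(n) != 1L || n < 4 || n != round(n))
    stop("'n' must be an integer >= 4")
  if (!is.numeric(period) || period <= 0) stop("'period' must be > 0")
  nodes <- seq(-period / 2, period / 2, length.out = n + 1L)[seq_len(n)]
  structure(
    list(nodes = nodes, weights = rep(period / n, n),
         period = period, dimension = 1L),
    class = "nf_grid"
  )
}

#' Geodesic distance on the ring
#'
#' Shortest angular distance between two points on a ring of the given
#' period; symmetric, period-periodic in each argument, bounded by
#' `period/2`. This is the metric entering the propagation-delay function
#' `tau(x, y) = c * ring_distance(x, y)`.
#'
#' @param x,y angles (recycled to a common length).
#' @param period ring circumference.
#' @return nonnegative distances, same shape as `x - y`.
#' @examples
#' ring_distance(0, pi, period = 2 * pi) # antipodal: pi
#' @export
ring_distance <- function(x, y, period = 2 * pi) {
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  z <- abs(x - y) %% period
  pmin(z, period - z)
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch).
gauss_legendre <- function(g, a = -1, b = 1) {
  if (g == 1L) return(list(nodes = (a + b) / 2, weights = b - a))
  i <- seq_len(g - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  tm <- matrix(0, g, g)
  tm[cbind(i, i + 1L)] <- beta
  tm[cbind(i + 1L, i)] <- beta
  e <- eigen(tm, symmetric = TRUE)
  list(nodes = (a + b) / 2 + (b - a) / 2 * e$values,
       weights = (b - a) / 2 * 2 * e$vectors[1, ]^2)
}

# Cardinal function of trigonometric interpolation from n (even) uniform
# nodes with spacing 2*pi/n, evaluated at offset z from a node.
trig_cardinal <- function(z, n) {
  ifelse(abs(sin(z / 2)) < 1e-14, 1, sin(n * z / 2) / (n * tan(z / 2)))
}

# Chebyshev-Gauss-Lobatto collocation of [-tau_m, 0]: points (theta_0 = 0 >
# ... > theta_m = -tau_m), spectral differentiation matrix (Trefethen) and
# barycentric weights.
cheb_segment <- function(m, tau_m) {
  j <- 0:m
  theta <- tau_m * (cos(j * pi / m) - 1) / 2
  cvec <- c(2, rep(1, m - 1L), 2) * (-1)^j
  x <- matrix(theta, m + 1L, m + 1L)
  dx <- x - t(x)
  d <- (cvec %o% (1 / cvec)) / (dx + diag(m + 1L))
  d <- d - diag(rowSums(d))
  list(theta = theta, diff = d,
       bary = c(0.5, rep(1, m - 1L), 0.5) * (-1)^j)
}

# Row of barycentric interpolation weights: u(tq) = sum_m w[m] u(theta_m).
bary_row <- function(tq, theta, bary) {
  d <- tq - theta
  hit <- which(abs(d) < 1e-13)
  if (length(hit)) {
    w <- numeric(length(theta))
    w[hit[1L]] <- 1
    return(w)
  }
  w <- bary / d
  w / sum(w)
}
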