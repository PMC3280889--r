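#' Sigmoid firing-rate specification
#'
#' The firing rate of the population is `S(gain * (V - threshold))`. Two
#' variants are supported: the un-centered logistic `S`, mapping into
#' `(0, 1)` with `S(0) = 1/2`, and the centered sigmoid `S0 = S - 1/2`,
#' mapping into `(-1/2, 1/2)` with `S0(0) = 0` (so that `V = 0` is a
#' stationary state of the homogeneous ring model). `slope` is the
#' derivative of the sigmoid at 0; the default `1/4` is the slope of the
#' plain logistic.
#'
#' @param gain nonlinear gain (sigma), dimensionless, > 0.
#' @param threshold activity threshold (h), potential units.
#' @param slope derivative of the (centered) sigmoid at 0, > 0.
#' @param centered logical; use the odd sigmoid `S0` (default) or the
#'   un-centered `S`.
#' @return an object of class `nf_sigmoid`.
#' @export
sigmoid_spec <- function(gain = 1, threshold = 0, slope = 0.25,
                         centered = TRUE) {
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain <= 0)
    stop("'gain' must be a positive number")
  if (!is.numeric(slope) || slope <= 0) stop("'slope' must be > 0")
  if (!is.numeric(threshold) || !is.finite(threshold))
    stop("'threshold' must be finite")
  structure(list(gain = gain, threshold = threshold, slope = slope,
                 centered = isTRUE(centered)),
            class = "nf_sigmoid")
}

#' Evaluate the sigmoid nonlinearity
#'
#' Evaluates the raw sigmoid `S` (or `S0`) of the specification at `x`; the
#' gain and threshold are *not* applied here (they enter as
#' `sigmoid(spec$gain * (V - spec$threshold), spec)` in the field equation).
#'
#' @param x numeric (vector/matrix), finite.
#' @param spec an [sigmoid_spec()].
#' @return values in `(0, 1)` (un-centered) or `(-1/2, 1/2)` (centered).
#' @examples
#' sigmoid(0, sigmoid_spec())                      # 0 (centered)
#' sigmoid(0, sigmoid_spec(centered = FALSE))      # 0.5
#' @export
sigmoid <- function(x, spec = sigmoid_spec()) {
  if (any(!is.finite(x))) stop("non-finite input to sigmoid")
  v <- stats::plogis(4 * spec$slope * x)
  if (spec$centered) v - 0.5 else v
}

#' Derivative of the sigmoid
#'
#' @inheritParams sigmoid
#' @return `dS/dx` at `x`; equals `spec$slope` at `x = 0`.
#' @export
sigmoid_deriv <- function(x, spec = sigmoid_spec()) {
  if (any(!is.finite(x))) stop("non-finite input to sigmoid_deriv")
  p <- stats::plogis(4 * spec$slope * x)
  4 * spec$slope * p * (1 - p)
}

#' Construct a delayed neural field model
#'
#' Full parameterization of the scalar (one-population) delayed neural field
#' equation
#' \deqn{\partial_t V(t, x) = -\ell V(t, x) +
#'   \int_\Omega J(x, y)\, S(\sigma (V(t - \tau(x, y), y) - h))\, dy +
#'   I_{ext}(t, x)}
#' on a ring. The connectivity kernel is either homogeneous, given by its
#' Fourier cosine coefficients (`kernel = list(type = "cosine", coeffs)`
#' where `coeffs` is a two-column matrix of `(wavenumber, amplitude)` rows),
#' or tabulated as a matrix over the grid nodes
#' (`kernel = list(type = "matrix", values)`).  The delay is either
#' `list(type = "ring", c = ...)`, i.e. `tau(x, y) = c * ring_distance(x,y)`
#' with maximal delay `tau_m = c * period / 2`, or a tabulated nonnegative
#' matrix `list(type = "matrix", values)`.
#'
#' @param grid an [ring_grid()].
#' @param leak leak rate `l > 0` (1/time).
#' @param kernel connectivity specification (see Details).
#' @param delay delay specification (see Details).
#' @param sigmoid an [sigmoid_spec()].
#' @param I_ext external current: a single number, a vector over grid nodes,
#'   or a function `f(t, x)`; default 0.
#' @return an object of class `nf_model`.
#' @seealso [make_ring_model()] for the common homogeneous-ring case.
#' @export
neural_field_model <- function(grid, leak = 1, kernel, delay,
                               sigmoid = sigmoid_spec(), I_ext = 0) {
  stopifnot(inherits(grid, "nf_grid"), inherits(sigmoid, "nf_sigmoid"))
  if (!is.numeric(leak) || length(leak) != 1L || leak <= 0)
    stop("'leak' must be a positive scalar")
  n <- length(grid$nodes)

  kernel <- validate_kernel(kernel, grid)
  delay <- validate_delay(delay, grid)

  model <- structure(
    list(p = 1L, grid = grid, leak = leak, kernel = kernel,
         delay = delay, sigmoid = sigmoid, I_ext = I_ext),
    class = "nf_model"
  )
  model
}

validate_kernel <- function(kernel, grid) {
  if (is.null(kernel$type)) stop("kernel needs a 'type'")
  if (kernel$type == "cosine") {
    co <- kernel$coeffs
    if (is.null(co) || length(co) == 0L) {
      co <- matrix(numeric(0), 0L, 2L)
    } else {
      co <- matrix(as.numeric(co), ncol = 2L)
    }
    if (any(!is.finite(co))) stop("kernel coefficients must be finite")
    if (nrow(co) && any(co[, 1L] < 0 | co[, 1L] != round(co[, 1L])))
      stop("wavenumbers must be nonnegative integers")
    # wavenumber k corresponds to cos(2*pi*k*z/period); on the 2*pi ring
    # this is cos(k z), so any integer k is period-periodic.
    kernel$coeffs <- co
  } else if (kernel$type == "matrix") {
    v <- as.matrix(kernel$values)
    n <- length(grid$nodes)
    if (!all(dim(v) == c(n, n)) || any(!is.finite(v)))
      stop("kernel matrix must be finite and n x n over the grid")
    kernel$values <- v
  } else stop("unknown kernel type: ", kernel$type)
  kernel
}

validate_delay <- function(delay, grid) {
  if (is.null(delay$type)) stop("delay needs a 'type'")
  n <- length(grid$nodes)
  if (delay$type == "ring") {
    if (is.null(delay$c) || delay$c < 0 || !is.finite(delay$c))
      stop("ring delay needs inverse speed 'c' >= 0")
    delay$tau_max <- delay$c * grid$period / 2
  } else if (delay$type == "matrix") {
    v <- as.matrix(delay$values)
    if (!all(dim(v) == c(n, n)) || any(!is.finite(v)) || any(v < 0))
      stop("delay matrix must be a nonnegative n x n matrix")
    delay$values <- v
    delay$tau_max <- max(v)
  } else stop("unknown delay type: ", delay$type)
  delay
}

#' Homogeneous ring model
#'
#' Convenience constructor for the reference model: one population on the
#' ring of circumference `period` (default `2*pi`), homogeneous even
#' connectivity given as a cosine series
#' `J(z) = sum_m a_m cos(k_m z)`, propagation delay
#' `tau(x, y) = c * ring_distance(x, y)` (maximal delay `c * period / 2`),
#' and a centered sigmoid so that `V = 0` is a stationary state.
#'
#' @param cos_coeffs two-column matrix (or list of pairs) of
#'   `(wavenumber, amplitude)` rows; e.g. `rbind(c(0, -1), c(2, 1.5))` is
#'   `J(z) = -1 + 1.5 cos(2 z)`.
#' @param c inverse propagation speed (delay scale), >= 0.
#' @param gain sigmoid gain sigma.
#' @param leak leak rate l.
#' @param slope sigmoid slope at 0.
#' @param n number of grid nodes.
#' @param period ring circumference.
#' @param centered logical, centered sigmoid (default TRUE).
#' @param threshold sigmoid threshold h.
#' @param I_ext external current (see [neural_field_model()]).
#' @return an `nf_model`.
#' @examples
#' m <- make_ring_model(rbind(c(0, -1), c(2, 1.5)), c = 1, gain = 1)
#' m$delay$tau_max # c * pi
#' @export
make_ring_model <- function(cos_coeffs, c = 1, gain = 1, leak = 1,
                            slope = 0.25, n = 128, period = 2 * pi,
                            centered = TRUE, threshold = 0, I_ext = 0) {
  if (is.list(cos_coeffs)) cos_coeffs <- do.call(rbind, cos_coeffs)
  if (is.null(cos_coeffs)) cos_coeffs <- matrix(numeric(0), 0L, 2L)
  grid <- ring_grid(n, period)
  neural_field_model(
    grid, leak = leak,
    kernel = list(type = "cosine", coeffs = cos_coeffs),
    delay = list(type = "ring", c = c),
    sigmoid = sigmoid_spec(gain = gain, threshold = threshold,
                           slope = slope, centered = centered),
    I_ext = I_ext
  )
}

#' @export
print.nf_model <- function(x, ...) {
  cat("<nf_model> one-population delayed neural field on a ring\n")
  cat(sprintf("  grid: %d nodes, period %.6g\n",
              length(x$grid$nodes), x$grid$period))
  cat(sprintf("  leak l = %g, gain sigma = %g, slope s1 = %g, %s sigmoid\n",
              x$leak, x$sigmoid$gain, x$sigmoid$slope,
              if (x$sigmoid$centered) "centered" else "un-centered"))
  if (x$kernel$type == "cosine") {
    co <- x$kernel$coeffs
    txt <- if (nrow(co) == 0L) "0" else
      paste(ifelse(co[, 1L] == 0, sprintf("%+g", co[, 2L]),
                   sprintf("%+g cos(%g z)", co[, 2L], co[, 1L])),
            collapse = " ")
    cat("  kernel: J(z) =", txt, "\n")
  } else cat("  kernel: tabulated matrix\n")
  if (x$delay$type == "ring")
    cat(sprintf("  delay: c * ring distance, c = %g (tau_max = %.6g)\n",
                x$delay$c, x$delay$tau_max))
  else cat(sprintf("  delay: tabulated matrix (tau_max = %.6g)\n",
                   x$delay$tau_max))
  invisible(x)
}

# Is the model a homogeneous ring model (cosine kernel + ring delay)?
is_homogeneous_ring <- function(model) {
  model$kernel$type == "cosine" && model$delay$type == "ring"
}

# Kernel values J(z) for a cosine-series kernel; mode k is cos(2*pi*k*z/P).
kernel_values <- function(coeffs, z, period = 2 * pi) {
  out <- rep(0, length(z))
  if (nrow(coeffs)) {
    for (i in seq_len(nrow(coeffs)))
      out <- out + coeffs[i, 2L] * cos(2 * pi * coeffs[i, 1L] * z / period)
  }
  if (!is.null(dim(z))) dim(out) <- dim(z)
  out
}

# Dense kernel matrix J(x_i, y_j) over the grid.
kernel_matrix <- function(model) {
  if (model$kernel$type == "matrix") return(model$kernel$values)
  x <- model$grid$nodes
  z <- outer(x, x, `-`)
  kernel_values(model$kernel$coeffs, z, model$grid$period)
}

# Dense delay matrix tau(x_i, y_j) over the grid.
delay_matrix <- function(model) {
  if (model$delay$type == "matrix") return(model$delay$values)
  x <- model$grid$nodes
  model$delay$c * ring_distance(outer(x, x, `-`), 0, model$grid$period)
}

# External current as a vector over nodes at time t.
external_current <- function(model, t) {
  x <- model$grid$nodes
  ie <- model$I_ext
  if (is.function(ie)) return(ie(t, x))
  rep_len(ie, length(x))
}

#' Fourier cosine coefficient of the connectivity kernel
#'
#' Computes `Jhat_k = integral over the ring of J(z) cos(2*pi*k*z/period) dz`
#' (so `cos(k z)` on the default `2*pi` ring). For cosine-series kernels the
#' value is exact by orthogonality: `Jhat_0 = period * a_0` and
#' `Jhat_k = period/2 * a_k` for `k > 0`.
#'
#' @param model a homogeneous ring `nf_model`.
#' @param k mode index (nonnegative integer, vectorized).
#' @return numeric vector of coefficients.
#' @examples
#' m <- make_ring_model(rbind(c(0, -1), c(2, 1.5)))
#' fourier_cos_coefficient(m, 0:3) # -2*pi, 0, 1.5*pi, 0
#' @export
fourier_cos_coefficient <- function(model, k) {
  if (!is_homogeneous_ring(model))
    stop("Fourier coefficients require a homogeneous ring kernel")
  if (any(k < 0 | k != round(k))) stop("'k' must be nonnegative integers")
  co <- model$kernel$coeffs
  p <- model$grid$period
  vapply(k, function(kk) {
    if (nrow(co) == 0L) return(0)
    hit <- which(co[, 1L] == kk)
    if (!length(hit)) return(0)
    a <- sum(co[hit, 2L])
    if (kk == 0L) p * a else p / 2 * a
  }, numeric(1))
}
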