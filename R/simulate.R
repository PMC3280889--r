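#' Random initial history
#'
#' Initial condition used throughout the numerical experiments: random in
#' space, constant in time. Each node gets an independent uniform draw in
#' `[-amplitude, amplitude]`, held fixed over the whole history interval
#' `[-tau_m, 0]`.
#'
#' @param model an `nf_model`.
#' @param amplitude half-width of the uniform draw (potential units).
#' @param seed integer seed (recorded in the attribute `"seed"`).
#' @return a history function `phi(t)` returning the node vector, with the
#'   seed attached as an attribute.
#' @export
random_history <- function(model, amplitude = 0.1, seed = 0) {
  n <- length(model$grid$nodes)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  v0 <- stats::runif(n, -amplitude, amplitude)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  phi <- function(t) v0
  attr(phi, "seed") <- seed
  attr(phi, "values") <- v0
  phi
}

as_history_fun <- function(history, n) {
  if (is.function(history)) return(history)
  v <- rep_len(as.numeric(history), n)
  function(t) v
}

#' Integrate the delayed neural field equation
#'
#' Fixed-step explicit integration of the delayed integro-differential
#' equation from an initial history, in a method-of-steps fashion: a
#' classical Runge-Kutta (RK4) step in which every delayed value
#' `V(t - tau(x_i, y_j), y_j)` is evaluated from the cubic Hermite
#' interpolant of the already-accepted solution samples (the exact initial
#' history `phi` is used for query times `<= 0`). Lags smaller than the
#' stage offset -- the diagonal `tau(x, x) = 0` in particular -- are served
#' by evaluating the last Hermite segment beyond its right endpoint
#' (a local predictor). When the model has no delays (`tau_m = 0`) the step
#' reduces to the classical RK4 for the non-delayed equation. The spatial
#' integral uses the grid quadrature (periodic trapezoid).
#'
#' @param model an `nf_model`.
#' @param history initial condition on `[-tau_m, 0]`: a function `phi(t)`
#'   returning the node vector (see [random_history()]), or a constant
#'   vector/number.
#' @param t_end final time, > 0.
#' @param dt time step, > 0. A warning is issued if `dt > tau_m / 4` for a
#'   delayed model (delayed-value accuracy).
#' @return an object of class `nf_trajectory`: `times`, `values`
#'   (time x node matrix), `norms` (weighted L2 norm of `V(t, .)` per time),
#'   `dt`, and the model.
#' @examples
#' m <- make_ring_model(matrix(numeric(0), 0, 2), c = 0, n = 16)
#' tr <- integrate_field(m, history = 1, t_end = 1, dt = 1e-3)
#' max(abs(tr$values[nrow(tr$values), ] - exp(-1))) < 1e-6
#' @export
integrate_field <- function(model, history, t_end, dt = 0.01) {
  stopifnot(inherits(model, "nf_model"))
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be > 0")
  if (!is.numeric(t_end) || t_end <= 0) stop("'t_end' must be > 0")
  x <- model$grid$nodes
  w <- model$grid$weights
  n <- length(x)
  phi <- as_history_fun(history, n)
  sg <- model$sigmoid
  l <- model$leak

  tau <- delay_matrix(model)
  tau_m <- max(tau)
  delayed <- tau_m > 0
  if (delayed && dt > tau_m / 4)
    warning("dt > tau_m / 4: delayed values are poorly resolved")

  # J(x_i, y_j) * w_j, so the delayed drive is rowSums(jw * S(...)).
  jw <- kernel_matrix(model) * rep(w, each = n)
  n_steps <- ceiling(t_end / dt - 1e-9)
  times <- dt * (0:n_steps)

  vals <- matrix(NA_real_, n_steps + 1L, n)
  dvals <- matrix(NA_real_, n_steps + 1L, n)
  vals[1L, ] <- phi(0)

  col_idx <- rep(seq_len(n), each = n)

  # Delayed field values V(tq[i, j], y_j) from history/Hermite interpolant;
  # 'acc' = number of accepted samples.
  lagged <- function(tq, acc) {
    out <- matrix(0, n, n)
    past <- tq <= 0
    if (any(past)) {
      # phi is constant in time for the supported history inputs only when
      # given as a vector; call per unique time to stay general.
      uts <- unique(tq[past])
      for (u in uts) {
        v <- phi(u)
        sel <- past & tq == u
        out[sel] <- v[col_idx[sel]]
      }
    }
    fut <- !past
    if (any(fut) && acc == 1L) {
      # no Hermite segment yet: first-order Taylor predictor from t = 0
      j <- col_idx[fut]
      out[fut] <- vals[1L, j] + tq[fut] * dvals[1L, j]
      fut <- rep(FALSE, length(fut))
    }
    if (any(fut)) {
      k <- pmin(pmax(floor(tq[fut] / dt) + 1L, 1L), acc - 1L)
      t0 <- times[k]
      u <- (tq[fut] - t0) / dt
      j <- col_idx[fut]
      v0 <- vals[cbind(k, j)]; v1 <- vals[cbind(k + 1L, j)]
      d0 <- dvals[cbind(k, j)]; d1 <- dvals[cbind(k + 1L, j)]
      h00 <- (1 + 2 * u) * (1 - u)^2
      h10 <- u * (1 - u)^2
      h01 <- u^2 * (3 - 2 * u)
      h11 <- u^2 * (u - 1)
      out[fut] <- h00 * v0 + dt * h10 * d0 + h01 * v1 + dt * h11 * d1
    }
    out
  }

  rhs_delayed <- function(t, v, acc) {
    vd <- lagged(t - tau, acc)
    drive <- rowSums(jw * sigmoid(sg$gain * (vd - sg$threshold), sg))
    -l * v + drive + external_current(model, t)
  }
  rhs_ode <- function(t, v) {
    drive <- as.vector(jw %*% sigmoid(sg$gain * (v - sg$threshold), sg))
    -l * v + drive + external_current(model, t)
  }

  guard <- 100 * max(ultimate_bound(model), 1)

  for (s in seq_len(n_steps)) {
    t0 <- times[s]
    v0 <- vals[s, ]
    if (delayed) {
      k1 <- rhs_delayed(t0, v0, s)
      dvals[s, ] <- k1
      k2 <- rhs_delayed(t0 + dt / 2, v0 + dt / 2 * k1, s)
      k3 <- rhs_delayed(t0 + dt / 2, v0 + dt / 2 * k2, s)
      k4 <- rhs_delayed(t0 + dt, v0 + dt * k3, s)
    } else {
      k1 <- rhs_ode(t0, v0)
      dvals[s, ] <- k1
      k2 <- rhs_ode(t0 + dt / 2, v0 + dt / 2 * k1)
      k3 <- rhs_ode(t0 + dt / 2, v0 + dt / 2 * k2)
      k4 <- rhs_ode(t0 + dt, v0 + dt * k3)
    }
    v1 <- v0 + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(v1)) || sqrt(sum(w * v1^2)) > guard)
      stop(sprintf("integration blow-up at t = %.6g", t0 + dt))
    vals[s + 1L, ] <- v1
    # provisional slope at the new sample (extrapolating the previous
    # segment for sub-dt lags); overwritten by k1 of the next step.
    dvals[s + 1L, ] <- if (delayed) rhs_delayed(t0 + dt, v1, s)
      else rhs_ode(t0 + dt, v1)
  }

  structure(
    list(times = times, values = vals,
         norms = sqrt(as.vector(vals^2 %*% w)),
         dt = dt, model = model),
    class = "nf_trajectory"
  )
}

#' @export
print.nf_trajectory <- function(x, ...) {
  nt <- length(x$times)
  cat(sprintf(
    "<nf_trajectory> %d samples on [0, %.6g], %d nodes; final |V| = %.6g\n",
    nt, x$times[nt], ncol(x$values), x$norms[nt]))
  invisible(x)
}

#' Ultimate bound on the trajectories
#'
#' All trajectories of the delayed neural field equation are ultimately
#' bounded (in the weighted L2 norm over the domain) by the same constant
#' \deqn{R = \left(\sqrt{p\,|\Omega|}\; \|J\|_{L^2(\Omega^2)} +
#'   \|I_{ext}\|_{L^2(\Omega)}\right) / \ell,}
#' the natural constant coming from the Cauchy-Schwarz estimate of the
#' delayed drive (the sigmoid is bounded by 1). The squared-norm derivative
#' along the flow is negative outside the ball of radius `R`, so the ball is
#' attracting and invariant regardless of the delays.
#'
#' @param model an `nf_model` with time-constant external current.
#' @return the radius `R` (potential units).
#' @examples
#' m <- make_ring_model(matrix(numeric(0), 0, 2))
#' ultimate_bound(m) # 0: pure leak decays to rest
#' @export
ultimate_bound <- function(model) {
  if (is.function(model$I_ext))
    stop("ultimate_bound requires a time-constant external current")
  w <- model$grid$weights
  area <- sum(w)
  jm <- kernel_matrix(model)
  hs <- sqrt(sum(outer(w, w) * jm^2))
  ie <- rep_len(as.numeric(model$I_ext), length(w))
  (sqrt(area) * hs + sqrt(sum(w * ie^2))) / model$leak
}

#' Classify the long-time regime of a trajectory
#'
#' Automatic criterion on the trailing window of the weighted L2 norm:
#' `"decay"` if the norm has dropped below `tol_zero`; `"pattern"` if it has
#' converged to a nonzero constant (trailing oscillation amplitude below
#' `tol_flat`); `"oscillation"` if the trailing amplitude exceeds
#' `amp_min`; `"undecided"` otherwise.
#'
#' @param traj an `nf_trajectory`.
#' @param tail_frac fraction of the run used as trailing window.
#' @param tol_zero decay threshold on the trailing norm.
#' @param tol_flat flatness threshold for a stationary pattern.
#' @param amp_min minimal norm-oscillation amplitude.
#' @return one of `"decay"`, `"pattern"`, `"oscillation"`, `"undecided"`.
#' @export
classify_regime <- function(traj, tail_frac = 0.3, tol_zero = 1e-4,
                            tol_flat = 1e-4, amp_min = 1e-3) {
  stopifnot(inherits(traj, "nf_trajectory"))
  nt <- length(traj$times)
  tail <- traj$norms[seq.int(max(1L, floor(nt * (1 - tail_frac))), nt)]
  amp <- max(tail) - min(tail)
  if (max(tail) < tol_zero) return("decay")
  if (amp < tol_flat) return("pattern")
  if (amp > amp_min) return("oscillation")
  "undecided"
}
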