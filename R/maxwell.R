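#' Generalized Maxwell model parameters
#'
#' Constructs the parameter set of an nth-order generalized Maxwell model: a
#' lone spring of stiffness `k0` in parallel with `n` spring--damper (Maxwell)
#' paths `(k[i], b[i])`. Paths are stored sorted by ascending time constant
#' `tau[i] = b[i]/k[i]` (fast path first), ties broken by ascending `k[i]`,
#' so that parameter vectors are identifiable and comparable across fits.
#'
#' Units are consistent model units: stiffness in N/m, damping in N s/m, the
#' input displacement in um, so forces come out in the product unit
#' (um x N/m = uN; scale as needed). A path with `b[i] = 0` is an
#' instantaneously decaying branch: it contributes to the relaxation response
#' only at `t = 0`.
#'
#' @param k0 stiffness of the parallel lone spring (N/m), strictly positive.
#' @param k numeric vector of path stiffnesses (N/m), strictly positive.
#' @param b numeric vector of path damping coefficients (N s/m),
#'   non-negative, same length as `k`.
#' @return An object of class `maxwell_params` with fields `k0`, `k`, `b`,
#'   `n` (number of paths) and `tau` (time constants, ascending).
#' @examples
#' p <- maxwell_params(2.984, k = c(1.110, 1.385), b = c(0.118, 3.108))
#' p$tau
#' parameter_count(p)
#' @seealso [relaxation_response()], [simulate_state_space()]
#' @export
maxwell_params <- function(k0, k = numeric(), b = numeric()) {
  stopifnot(is.numeric(k0), length(k0) == 1L, is.finite(k0))
  if (k0 <= 0) stop("'k0' must be strictly positive")
  k <- as.numeric(k)
  b <- as.numeric(b)
  if (length(k) != length(b)) stop("'k' and 'b' must have the same length")
  if (length(k)) {
    if (any(!is.finite(k)) || any(!is.finite(b))) stop("path parameters must be finite")
    if (any(k <= 0)) stop("path stiffnesses 'k' must be strictly positive")
    if (any(b < 0)) stop("damping coefficients 'b' must be non-negative")
    tau <- b / k
    ord <- order(tau, k)
    k <- k[ord]; b <- b[ord]
  }
  structure(
    list(k0 = k0, k = k, b = b, n = length(k), tau = if (length(k)) b / k else numeric()),
    class = "maxwell_params"
  )
}

#' Number of free parameters of a generalized Maxwell model
#'
#' An order-n model exposes `2n + 1` parameters: `n + 1` elastic and `n`
#' viscous (five parameters at n = 2).
#'
#' @param params a [maxwell_params()] object.
#' @return integer count `2n + 1`.
#' @export
parameter_count <- function(params) {
  stopifnot(inherits(params, "maxwell_params"))
  2L * params$n + 1L
}

#' @export
print.maxwell_params <- function(x, ...) {
  cat(sprintf("Generalized Maxwell model, order %d (%d parameters)\n",
              x$n, parameter_count(x)))
  cat(sprintf("  k0 = %.4g N/m\n", x$k0))
  if (x$n)
    for (i in seq_len(x$n))
      cat(sprintf("  path %d: k = %.4g N/m, b = %.4g N s/m (tau = %.4g s)\n",
                  i, x$k[i], x$b[i], x$tau[i]))
  invisible(x)
}

#' Uniform time grid
#'
#' @param t0 start time (s).
#' @param dt sampling interval (s), strictly positive.
#' @param npoints number of samples, at least 2.
#' @return object of class `time_grid`.
#' @export
time_grid <- function(t0 = 0, dt, npoints) {
  stopifnot(is.numeric(t0), is.numeric(dt), is.numeric(npoints))
  if (dt <= 0) stop("'dt' must be strictly positive")
  npoints <- as.integer(npoints)
  if (npoints < 2L) stop("'npoints' must be at least 2")
  structure(list(t0 = t0, dt = dt, npoints = npoints), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time_grid: %d samples, dt = %g s, t in [%g, %g] s\n",
              x$npoints, x$dt, x$t0, x$t0 + (x$npoints - 1L) * x$dt))
  invisible(x)
}

#' Sample times of a time grid
#' @param grid a [time_grid()].
#' @return numeric vector of times.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t0 + grid$dt * (seq_len(grid$npoints) - 1)
}

# Accept either a time_grid or a uniform numeric time vector; return times.
# Non-uniform vectors are rejected (relative jitter > tol).
.resolve_times <- function(grid, tol = 1e-8) {
  if (inherits(grid, "time_grid")) return(grid_times(grid))
  t <- as.numeric(grid)
  if (length(t) < 2L) stop("a time grid needs at least 2 samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop("time samples must be strictly increasing")
  if ((max(dt) - min(dt)) > tol * median(dt))
    stop("time grid is not uniform; resample first")
  t
}

#' Closed-form stress-relaxation response
#'
#' Evaluates the step (relaxation) response of a generalized Maxwell model to
#' a constant input displacement held from `t = 0`:
#' `y(t) = k0 u + u * sum_i k[i] exp(-(k[i]/b[i]) t)`,
#' a constant component plus one exponential decay per path. A path with
#' `b[i] = 0` decays instantaneously: its term is included only at `t = 0`.
#'
#' @param params a [maxwell_params()] object.
#' @param u_const the constant input displacement (um).
#' @param grid a [time_grid()] or a uniform numeric vector of times (s).
#' @return numeric vector of forces on the grid (product units).
#' @examples
#' p <- maxwell_params(1, 1, 1)
#' relaxation_response(p, 1, time_grid(0, log(2), 2)) # 2, then 1.5 at t = ln 2
#' @export
relaxation_response <- function(params, u_const, grid) {
  stopifnot(inherits(params, "maxwell_params"))
  if (!is.numeric(u_const) || length(u_const) != 1L || !is.finite(u_const))
    stop("'u_const' must be a finite scalar")
  t <- .resolve_times(grid)
  y <- rep(params$k0 * u_const, length(t))
  for (i in seq_len(params$n)) {
    if (params$b[i] == 0) {
      if (any(t < 0)) stop("a path with b = 0 requires t >= 0")
      y <- y + ifelse(t == 0, params$k[i] * u_const, 0)
    } else {
      y <- y + u_const * params$k[i] * exp(-(params$k[i] / params$b[i]) * t)
    }
  }
  y
}

#' Steady-state (fully relaxed) force
#'
#' The `t -> Inf` limit of the relaxation response: all Maxwell paths have
#' relaxed and only the lone spring carries load, `y = k0 * u`.
#'
#' @inheritParams relaxation_response
#' @return scalar force.
#' @export
steady_state_force <- function(params, u_const) {
  stopifnot(inherits(params, "maxwell_params"), is.numeric(u_const), length(u_const) == 1L)
  params$k0 * u_const
}

#' Integrate the Maxwell state-space model
#'
#' Numerically integrates the state-space form of the generalized Maxwell
#' model with a fixed-step 4th-order Runge--Kutta scheme:
#' `dx[i]/dt = -(k[i]/b[i]) x[i] + (k[i]/b[i]) u(t)`,
#' `y = -sum k[i] x[i] + (k0 + sum k[i]) u(t)`,
#' where state `x[i]` is the displacement of the junction between the spring
#' and damper of path i. The input `u` may vary over time (given per sample;
#' linearly interpolated at Runge--Kutta substeps). This integrator is the
#' brute-force counterpart of [relaxation_response()]: for constant input and
#' zero initial state the two agree to integration accuracy.
#'
#' The integration substep is chosen as `tau_min / 50` or finer (the system is
#' linear and non-stiff at that step). Paths with `b = 0` are rejected here
#' (degenerate rate); use the closed form for those.
#'
#' @param params a [maxwell_params()] object; all `b > 0`.
#' @param u numeric vector of input displacement per sample (um), or a scalar
#'   for constant input.
#' @param grid a [time_grid()] or uniform numeric time vector (s).
#' @param x_init initial state vector (length n, um); defaults to all zero
#'   (fully unrelaxed paths).
#' @return A `state_trajectory` object: list with `t`, `states` (n-column
#'   matrix of x per sample), `output` (force per sample), `u`.
#' @export
simulate_state_space <- function(params, u, grid, x_init = NULL) {
  stopifnot(inherits(params, "maxwell_params"))
  if (params$n && any(params$b == 0))
    stop("state-space integration requires all b > 0; use relaxation_response() for b = 0 paths")
  t <- .resolve_times(grid)
  np <- length(t)
  if (length(u) == 1L) u <- rep(as.numeric(u), np)
  if (length(u) != np) stop("'u' must be scalar or match the grid length")
  n <- params$n
  if (is.null(x_init)) x_init <- rep(0, n)
  if (length(x_init) != n) stop("'x_init' must have length n")
  rate <- if (n) params$k / params$b else numeric()

  dt <- if (np > 1L) t[2] - t[1] else 0
  nsub <- if (n) max(1L, ceiling(dt / (min(1 / rate) / 50))) else 1L
  h <- dt / nsub

  states <- matrix(0, np, max(n, 1L))
  x <- as.numeric(x_init)
  states[1L, seq_len(n)] <- x
  deriv <- function(x, uval) rate * (uval - x)
  for (j in seq_len(np - 1L)) {
    for (s in seq_len(nsub)) {
      # linear interpolation of u inside the sample interval
      a0 <- (s - 1) / nsub; a1 <- s / nsub
      u0 <- u[j] * (1 - a0) + u[j + 1L] * a0
      um <- u[j] * (1 - (a0 + a1) / 2) + u[j + 1L] * (a0 + a1) / 2
      u1 <- u[j] * (1 - a1) + u[j + 1L] * a1
      if (n) {
        q1 <- deriv(x, u0)
        q2 <- deriv(x + h / 2 * q1, um)
        q3 <- deriv(x + h / 2 * q2, um)
        q4 <- deriv(x + h * q3, u1)
        x <- x + h / 6 * (q1 + 2 * q2 + 2 * q3 + q4)
      }
    }
    states[j + 1L, seq_len(n)] <- x
  }
  ksum <- sum(params$k)
  output <- (params$k0 + ksum) * u -
    if (n) as.numeric(states[, seq_len(n), drop = FALSE] %*% params$k) else 0
  structure(list(t = t, states = states[, seq_len(n), drop = FALSE],
                 output = output, u = u),
            class = "state_trajectory")
}

#' Serialize Maxwell parameters to a flat config list
#'
#' Flat key-value form `{order, k0, k1, b1, ..., kn, bn}` suitable for
#' JSON/YAML-style round-tripping.
#'
#' @param params a [maxwell_params()] object.
#' @return named list.
#' @seealso [maxwell_from_config()]
#' @export
maxwell_to_config <- function(params) {
  stopifnot(inherits(params, "maxwell_params"))
  out <- list(order = params$n, k0 = params$k0)
  for (i in seq_len(params$n)) {
    out[[paste0("k", i)]] <- params$k[i]
    out[[paste0("b", i)]] <- params$b[i]
  }
  out
}

#' Deserialize Maxwell parameters from a flat config list
#' @param config named list as produced by [maxwell_to_config()].
#' @return a [maxwell_params()] object.
#' @export
maxwell_from_config <- function(config) {
  n <- as.integer(config$order)
  k <- vapply(seq_len(n), function(i) as.numeric(config[[paste0("k", i)]]), numeric(1))
  b <- vapply(seq_len(n), function(i) as.numeric(config[[paste0("b", i)]]), numeric(1))
  maxwell_params(as.numeric(config$k0), k, b)
}
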