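# Lawson-Hanson style non-negative least squares for the few-column
# amplitude solve inside the variable-projection fit. A is n x p with p <= ~7.
.nnls <- function(A, y) {
  p <- ncol(A)
  passive <- logical(p)
  x <- numeric(p)
  w <- drop(crossprod(A, y))                 # gradient at x = 0
  tol <- 1e-12 * max(abs(w), 1)
  for (outer in seq_len(10L * p)) {
    free <- which(!passive & w > tol)
    if (!length(free)) break
    passive[free[which.max(w[free])]] <- TRUE
    repeat {
      idx <- which(passive)
      s <- numeric(p)
      s[idx] <- drop(qr.coef(qr(A[, idx, drop = FALSE]), y))
      s[idx][is.na(s[idx])] <- 0
      if (all(s[idx] > 0)) { x <- s; break }
      bad <- idx[s[idx] <= 0]
      alpha <- min(x[bad] / (x[bad] - s[bad]))
      x <- x + alpha * (s - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, y - A %*% x))
  }
  x
}

#' Residual norm and coefficient of determination
#'
#' @param y_model model output samples.
#' @param y_data measured samples, same length.
#' @return list with `residual_norm` (L2 norm of the residual) and
#'   `r_squared` (1 - SS_res/SS_tot; `NA` for zero-variance data).
#' @export
goodness_of_fit <- function(y_model, y_data) {
  if (length(y_model) != length(y_data)) stop("lengths differ")
  res <- y_data - y_model
  ss_tot <- sum((y_data - mean(y_data))^2)
  list(residual_norm = sqrt(sum(res^2)),
       r_squared = if (ss_tot == 0) NA_real_ else 1 - sum(res^2) / ss_tot)
}

#' Initial values for an exponential-sum fit by sequential peeling
#'
#' Produces a starting point for [fit_relaxation()]. The constant term `A0` is
#' the tail mean of the curve; the slowest exponential is then fitted by
#' log-linear regression on `y - A0` over the last third of the window,
#' subtracted, and the procedure repeats for the faster terms. If the residual
#' signal is non-positive at any peel, the remaining time constants fall back
#' to a geometric grid spanning `[2 dt, t_end]`.
#'
#' @param t uniform time samples (s).
#' @param y relaxation force samples.
#' @param u_const constant input displacement (nonzero).
#' @param order number of exponential terms.
#' @return list with `A0`, `A` (amplitudes, length `order`, fast term first)
#'   and `tau` (time constants, ascending).
#' @export
initialize_exponentials <- function(t, y, u_const, order) {
  t <- .resolve_times(t)
  order <- as.integer(order)
  stopifnot(length(t) == length(y), order >= 0L)
  dt <- t[2] - t[1]
  t_end <- max(t) - min(t)
  # baseline: geometric (Aitken) extrapolation of three tail block means --
  # a plain tail mean overestimates A0 when the slowest mode has not fully
  # decayed within the window
  n <- length(y)
  tail_idx <- seq.int(max(1L, n - n %/% 2L), n)
  blocks <- split(y[tail_idx], cut(seq_along(tail_idx), 3L, labels = FALSE))
  m <- vapply(blocks, mean, numeric(1))
  denom <- m[1L] + m[3L] - 2 * m[2L]
  A0 <- if (is.finite(denom) && abs(denom) > 1e-12 * max(abs(y), 1))
    (m[1L] * m[3L] - m[2L]^2) / denom else mean(tail(y, max(3L, n %/% 10L)))
  if (!is.finite(A0)) A0 <- mean(tail(y, max(3L, n %/% 10L)))
  A0 <- min(max(A0, 0), min(m))
  if (order == 0L) return(list(A0 = A0, A = numeric(), tau = numeric()))

  A <- numeric(order); tau <- numeric(order)
  resid <- y - A0
  t0 <- t - min(t)
  fallback_from <- NA_integer_
  prev_tau <- NA_real_
  for (j in rev(seq_len(order))) {      # slowest term first
    if (j == order && order > 1L) {
      # slowest term: last third of the window, where faster terms have died
      win <- seq.int(max(1L, length(t0) - length(t0) %/% 3L), length(t0))
    } else if (j < order) {
      # faster terms: early window where the previous (slower) term is flat
      win <- which(t0 <= prev_tau / 8)
      if (length(win) < 5L) win <- seq_len(min(length(t0), 5L))
    } else {
      # single term: descending part of the residual
      win <- which(resid > 0.05 * max(resid))
      if (length(win) < 3L) win <- seq_along(t0)
    }
    pos <- win[resid[win] > 0]
    if (length(pos) < 3L) { fallback_from <- j; break }
    fit <- stats::lm.fit(cbind(1, t0[pos]), log(resid[pos]))
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0) { fallback_from <- j; break }
    tau[j] <- -1 / slope
    A[j] <- exp(fit$coefficients[1])
    resid <- resid - A[j] * exp(-t0 / tau[j])
    prev_tau <- tau[j]
  }
  if (!is.na(fallback_from)) {
    grid <- exp(seq(log(2 * dt), log(max(t_end, 4 * dt)), length.out = order))
    for (j in seq_len(fallback_from)) {
      tau[j] <- grid[j]
      A[j] <- max(mean(resid[resid > 0], na.rm = TRUE), 0)
      if (!is.finite(A[j])) A[j] <- 0
    }
  }
  ord <- order(tau)
  tau <- pmax(tau[ord], dt)
  # refine amplitudes by one constrained linear solve at the peeled taus
  B <- cbind(1, exp(-outer(t0, 1 / tau)))
  a_ref <- .nnls(B, y)
  list(A0 = a_ref[1L], A = a_ref[-1L], tau = tau)
}

#' Fit a generalized Maxwell model to a relaxation curve by least squares
#'
#' Estimates the parameter vector `theta = (k0, k1, b1, ..., kn, bn)` of a
#' given order by minimizing `sum_j (y_theta(t_j) - y(t_j))^2`. The model
#' output under constant input `u` is the exponential sum
#' `y = A0 + sum_i A_i exp(-t/tau_i)` with `A0 = k0 u`, `A_i = k_i u`,
#' `b_i = k_i tau_i`. The amplitudes enter linearly and are solved in closed
#' form (non-negatively constrained) for each candidate `tau` vector; only the
#' log time constants are iterated (separable, variable-projection-style
#' least squares), which makes the notoriously ill-conditioned exponential-sum
#' fit converge reliably. Paths are reordered by ascending `tau` before
#' return.
#'
#' @param t uniform time samples (s), re-zeroed internally to start at 0.
#' @param y measured relaxation force samples, same length as `t`.
#' @param u_const the constant input displacement (nonzero).
#' @param order model order n (number of exponential terms); `0` fits the
#'   constant `k0 u` only. The data must contain at least `2 (2 n + 1)`
#'   samples.
#' @param init optional initial values as returned by
#'   [initialize_exponentials()].
#' @param max_iter iteration cap for the outer optimizer (default 500).
#' @param tol relative objective-change convergence tolerance (default 1e-10).
#' @return A `fit_result` object: list with `params` ([maxwell_params()]),
#'   `residual_norm`, `r_squared`, `converged`, `n_iterations`, `tau`,
#'   `objective`.
#' @export
fit_relaxation <- function(t, y, u_const, order, init = NULL,
                           max_iter = 500L, tol = 1e-10) {
  t <- .resolve_times(t)
  y <- as.numeric(y)
  if (length(t) != length(y)) stop("'t' and 'y' must have the same length")
  if (!is.numeric(u_const) || length(u_const) != 1L || u_const == 0)
    stop("'u_const' must be a nonzero scalar")
  order <- as.integer(order)
  if (order < 0L) stop("'order' must be non-negative")
  if (length(y) < 2L * (2L * order + 1L))
    stop(sprintf("need at least %d samples for order %d", 2L * (2L * order + 1L), order))
  t0 <- t - min(t)
  dt <- t0[2]

  if (order == 0L) {
    k0 <- mean(y) / u_const
    gof <- goodness_of_fit(rep(mean(y), length(y)), y)
    return(structure(list(
      params = maxwell_params(max(k0, .Machine$double.xmin)),
      residual_norm = gof$residual_norm, r_squared = gof$r_squared,
      converged = TRUE, n_iterations = 0L, tau = numeric(),
      objective = gof$residual_norm^2), class = "fit_result"))
  }

  if (is.null(init)) init <- initialize_exponentials(t0, y, u_const, order)
  tau_init <- pmin(pmax(init$tau, 2 * dt), 10 * max(t0))
  if (any(!is.finite(tau_init)))
    tau_init <- exp(seq(log(2 * dt), log(max(t0)), length.out = order))

  amp_solve <- function(tau) {
    B <- cbind(1, exp(-outer(t0, 1 / tau)))
    a <- .nnls(B, y)
    list(a = a, rss = sum((y - B %*% a)^2))
  }
  objfun <- function(ltau) amp_solve(exp(ltau))$rss

  lb <- log(dt / 2); ub <- log(50 * max(t0))
  opt <- stats::optim(log(tau_init), objfun, method = "L-BFGS-B",
                      lower = lb, upper = ub,
                      control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
  # guard: never return worse than the initializer
  if (opt$value > objfun(log(tau_init)) + 1e-12) {
    opt$par <- log(tau_init)
    opt$value <- objfun(opt$par)
  }
  tau <- exp(opt$par)
  sol <- amp_solve(tau)
  ord <- order(tau)
  tau <- tau[ord]
  A <- sol$a[-1L][ord]
  A0 <- sol$a[1L]

  k <- pmax(A / u_const, 1e-12)
  b <- k * tau
  params <- maxwell_params(max(A0 / u_const, 1e-12), k, b)
  y_hat <- A0 + drop(exp(-outer(t0, 1 / tau)) %*% A)
  gof <- goodness_of_fit(y_hat, y)
  structure(list(params = params,
                 residual_norm = gof$residual_norm,
                 r_squared = gof$r_squared,
                 converged = opt$convergence == 0L,
                 n_iterations = as.integer(opt$counts[["function"]]),
                 tau = params$tau,
                 objective = sol$rss), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Maxwell fit: order %d, residual norm %.4g, R^2 %.6f (%s)\n",
              x$params$n, x$residual_norm, x$r_squared,
              if (x$converged) "converged" else "not converged"))
  print(x$params)
  invisible(x)
}
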