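#' Force curve container
#'
#' A uniformly sampled AFM indentation record: time, PZT z-position, and
#' either force or cantilever deflection (exactly one of the two must be
#' supplied; deflection is converted on load when a spring constant is known).
#' Phase labels per sample are `"approach"`, `"relaxation"`, `"retract"` or
#' `"unknown"`.
#'
#' @param t time samples (s), uniform and strictly increasing.
#' @param z PZT z-position (um); scalar or per-sample.
#' @param force force (nN), or `NULL` when `deflection` is given.
#' @param deflection cantilever deflection (um), or `NULL`.
#' @param phase per-sample phase labels (recycled if scalar).
#' @param spring_constant cantilever spring constant (N/m); required to
#'   convert deflection.
#' @return object of class `force_curve` with fields `t`, `z`, `force`,
#'   `deflection`, `phase`, `spring_constant`, `fs`.
#' @export
force_curve <- function(t, z, force = NULL, deflection = NULL,
                        phase = "unknown", spring_constant = NA_real_) {
  t <- .resolve_times(t)
  n <- length(t)
  if (length(z) == 1L) z <- rep(as.numeric(z), n)
  stopifnot(length(z) == n)
  if (is.null(force) == is.null(deflection))
    stop("exactly one of 'force' or 'deflection' must be supplied")
  if (is.null(force)) {
    if (!is.finite(spring_constant))
      stop("a spring constant is required to convert deflection to force")
    force <- deflection_to_force(deflection, spring_constant)
  }
  stopifnot(length(force) == n)
  if (length(phase) == 1L) phase <- rep(phase, n)
  stopifnot(length(phase) == n,
            all(phase %in% c("approach", "relaxation", "retract", "unknown")))
  structure(list(t = t, z = z, force = as.numeric(force),
                 deflection = deflection, phase = phase,
                 spring_constant = spring_constant,
                 fs = 1 / (t[2] - t[1])),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("force_curve: %d samples at %.6g Hz (%.4g s)\n",
              length(x$t), x$fs, max(x$t) - min(x$t)))
  ph <- table(x$phase)
  cat("  phases:", paste(sprintf("%s (%d)", names(ph), ph), collapse = ", "), "\n")
  invisible(x)
}

#' Convert cantilever deflection to force
#'
#' The tip--sample force follows from the cantilever deflection and the
#' calibrated spring constant. With deflection in um and the spring constant
#' in N/m the force comes out in nN (1 um x 1 N/m = 1000 nN).
#'
#' @param deflection deflection series (um).
#' @param spring_constant calibrated cantilever spring constant (N/m),
#'   strictly positive.
#' @return force series (nN).
#' @examples
#' deflection_to_force(1, 0.2960)  # 296 nN
#' @export
deflection_to_force <- function(deflection, spring_constant) {
  if (!is.numeric(spring_constant) || length(spring_constant) != 1L ||
      !is.finite(spring_constant) || spring_constant <= 0)
    stop("'spring_constant' must be a positive scalar (N/m)")
  1000 * spring_constant * as.numeric(deflection)
}

#' Read a force curve from delimited text
#'
#' Reads a header-bearing delimited text file and maps its columns to the
#' curve fields via `columns`, a named character vector with names from
#' `time`, `z`, `force`, `deflection` and values naming file columns. Vendor
#' formats vary, so no column guessing is attempted. The time column must be
#' strictly increasing; slightly jittered grids (relative jitter below 1% of
#' the median interval) are resampled onto a uniform grid by linear
#' interpolation, larger irregularity is an error.
#'
#' @param path file path.
#' @param columns named character vector mapping curve fields to file columns;
#'   default `c(time = "time", z = "z", force = "force")`.
#' @param delimiter field separator (default tab; use "," for CSV).
#' @param spring_constant cantilever spring constant (N/m), required when a
#'   deflection column is mapped instead of force.
#' @return a [force_curve()].
#' @export
read_curve <- function(path, columns = c(time = "time", z = "z", force = "force"),
                       delimiter = "\t", spring_constant = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, header = TRUE, sep = delimiter, check.names = FALSE)
  need <- intersect(c("time", "z", "force", "deflection"), names(columns))
  if (!"time" %in% need) stop("'columns' must map a time column")
  missing_cols <- setdiff(unname(columns[need]), names(df))
  if (length(missing_cols))
    stop("missing columns in file: ", paste(missing_cols, collapse = ", "))
  get <- function(field) {
    v <- df[[columns[[field]]]]
    if (!is.numeric(v)) stop("column '", columns[[field]], "' is not numeric")
    v
  }
  t <- get("time")
  if (any(diff(t) <= 0)) stop("time column must be strictly increasing")
  dt <- median(diff(t))
  jitter <- max(abs(diff(t) - dt))
  grab <- function(field) if (field %in% need) get(field) else NULL
  z <- if ("z" %in% need) get("z") else rep(0, length(t))
  force <- grab("force"); deflection <- grab("deflection")
  if (jitter > 0.01 * dt) stop("irregular sampling beyond 1% jitter tolerance")
  if (jitter > 0) {
    tu <- seq(min(t), max(t), length.out = length(t))
    interp <- function(v) if (is.null(v)) NULL else stats::approx(t, v, tu)$y
    z <- interp(z); force <- interp(force); deflection <- interp(deflection)
    t <- tu
  }
  force_curve(t, z, force = force, deflection = deflection,
              spring_constant = spring_constant)
}

#' Write a force curve to delimited text
#'
#' Numeric content is written with enough digits to round-trip through
#' [read_curve()] to better than 1e-9 relative error.
#'
#' @param curve a [force_curve()].
#' @param path output file path.
#' @param delimiter field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, delimiter = "\t") {
  stopifnot(inherits(curve, "force_curve"))
  df <- data.frame(time = sprintf("%.12e", curve$t),
                   z = sprintf("%.12e", curve$z),
                   force = sprintf("%.12e", curve$force))
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- Butterworth low-pass design and zero-phase filtering -------------------
# No DSP package ships with the environment, so the standard 4th-order
# Butterworth (bilinear transform) and filtfilt (odd-extension padding with
# steady-state initial conditions) are implemented here.

# Returns list(b, a) for an order-n Butterworth low-pass at 'cutoff' Hz.
.butter_lowpass <- function(cutoff, fs, order = 4L) {
  n <- as.integer(order)
  wc <- 2 * fs * tan(pi * cutoff / fs)            # pre-warped analog cutoff
  kseq <- seq_len(n)
  p <- wc * exp(1i * pi * (2 * kseq + n - 1) / (2 * n))   # analog poles (LHP)
  zp <- (2 * fs + p) / (2 * fs - p)               # bilinear transform
  poly_from_roots <- function(r) {
    coef <- 1
    for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
    coef
  }
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(rep(-1 + 0i, n)))       # n zeros at z = -1
  gain <- sum(a) / sum(b)                          # unity DC gain
  list(b = b * gain, a = a)
}

# Direct-form II transposed IIR filter with initial state zi (length
# length(a) - 1). Returns the filtered signal.
.iir_filter <- function(b, a, x, zi = NULL) {
  m <- length(a) - 1L
  z <- if (is.null(zi)) numeric(m) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    yi <- b[1L] * x[i] + z[1L]
    if (m > 1L)
      for (j in seq_len(m - 1L))
        z[j] <- b[j + 1L] * x[i] + z[j + 1L] - a[j + 1L] * yi
    z[m] <- b[m + 1L] * x[i] - a[m + 1L] * yi
    y[i] <- yi
  }
  y
}

# Steady-state filter state for a unit-amplitude constant input, so that
# constant signals pass with no start-up transient.
.filter_zi <- function(b, a) {
  m <- length(a) - 1L
  A <- matrix(0, m, m)
  A[, 1L] <- -a[-1L]
  if (m > 1L) A[cbind(seq_len(m - 1L), seq_len(m - 1L) + 1L)] <- 1
  B <- b[-1L] - b[1L] * a[-1L]
  solve(diag(m) - A, B)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Smooths a force series with an order-4 Butterworth low-pass applied forward
#' and backward (zero phase, so relaxation time constants are not shifted).
#' The default 10 Hz cutoff matches the smoothing used on the measured curves.
#' Edge transients are controlled by odd-extension padding plus steady-state
#' initial conditions; a constant series passes unchanged to better than
#' 1e-9.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz); must exceed `2 * cutoff`.
#' @param cutoff cutoff frequency (Hz), default 10.
#' @param order filter order (default 4).
#' @return filtered series, same length as `x`.
#' @export
lowpass <- function(x, fs, cutoff = 10, order = 4L) {
  if (fs <= 2 * cutoff) stop("'fs' must exceed twice the cutoff frequency")
  x <- as.numeric(x)
  ba <- .butter_lowpass(cutoff, fs, order)
  zi <- .filter_zi(ba$b, ba$a)
  pad <- min(3L * (length(ba$a) + length(ba$b)), length(x) - 1L)
  ext <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - pad)])
  y <- .iir_filter(ba$b, ba$a, ext, zi * ext[1L])
  y <- rev(.iir_filter(ba$b, ba$a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + length(x))]
}

#' Segment the stress-relaxation (hold) phase of an indentation record
#'
#' Finds the longest contiguous window in which the PZT z-position is held
#' constant (|dz/dt| below `hold_tolerance`) and returns the quantities the
#' Maxwell analysis needs: time re-zeroed to the window start, the constant
#' input `u_const` (mean z over the window), and the force samples.
#'
#' @param curve a [force_curve()] with a z-position channel.
#' @param hold_tolerance |dz/dt| threshold declaring the actuator stationary
#'   (um/s, default 0.1; the approach/retract ramps move at um/s scale).
#' @param min_duration shortest acceptable hold window (s, default 1).
#' @return list with `t` (re-zeroed times), `u_const` (um), `y` (force
#'   samples), `idx` (sample indices of the window in `curve`).
#' @export
segment_relaxation <- function(curve, hold_tolerance = 0.1, min_duration = 1) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$z
  if (all(!is.finite(z))) stop("curve has no z-position channel")
  dz <- diff(z) * curve$fs
  still <- abs(dz) < hold_tolerance
  runs <- rle(still)
  if (!any(runs$values)) stop("no hold window found")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]
  idx <- seq.int(starts[best], ends[best] + 1L)   # diffs i..j span samples i..j+1
  if (length(idx) / curve$fs < min_duration)
    stop(sprintf("longest hold window (%.3g s) is shorter than min_duration (%g s)",
                 length(idx) / curve$fs, min_duration))
  list(t = curve$t[idx] - curve$t[idx[1L]],
       u_const = mean(z[idx]),
       y = curve$force[idx],
       idx = idx)
}
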