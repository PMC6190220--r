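#' Impulse-response sequence from a step response
#'
#' The stress-relaxation force curve is the step response of the cell system
#' (constant input held from t = 0); the impulse-response sequence is obtained
#' by differencing adjacent samples, `g(i) = y(i+1) - y(i)`.
#'
#' @param y numeric step-response sequence, length at least 3.
#' @param dt sampling interval of `y` (s).
#' @return An `impulse_sequence` object: list with `g` (length `length(y) - 1`)
#'   and `dt`.
#' @export
impulse_from_step <- function(y, dt = 1) {
  y <- as.numeric(y)
  if (length(y) < 3L) stop("step response must have at least 3 samples")
  if (any(!is.finite(y))) stop("step response contains non-finite values")
  structure(list(g = diff(y), dt = dt), class = "impulse_sequence")
}

.as_impulse <- function(g) {
  if (inherits(g, "impulse_sequence")) return(g)
  structure(list(g = as.numeric(g), dt = 1), class = "impulse_sequence")
}

#' Build a Hankel matrix from an impulse sequence
#'
#' Entry (r, c) is `g(k + r + c - 2)` (1-based), so the matrix is constant
#' along anti-diagonals; its rank equals the order of the underlying linear
#' system for noise-free data.
#'
#' @param g an impulse sequence ([impulse_from_step()]) or numeric vector.
#' @param l matrix dimension (l x l), at least 1.
#' @param k starting index, between 1 and `L - 2l + 2` where `L = length(g)`.
#' @return an `l` x `l` numeric matrix.
#' @export
build_hankel <- function(g, l, k = 1L) {
  g <- .as_impulse(g)$g
  L <- length(g)
  l <- as.integer(l); k <- as.integer(k)
  if (l < 1L) stop("'l' must be at least 1")
  if (k < 1L || k > L - 2L * l + 2L)
    stop(sprintf("'k' must lie in [1, %d] for l = %d, L = %d", L - 2L * l + 2L, l, L))
  outer(seq_len(l), seq_len(l), function(r, c) g[k + r + c - 2L])
}

# Signed determinants of H(l, k) over the admissible k-range.
.hankel_dets <- function(g, l) {
  L <- length(g)
  K <- L - 2L * l + 2L
  if (K < 1L) return(numeric())
  vapply(seq_len(K), function(k) det(build_hankel(g, l, k)), numeric(1))
}

#' Hankel determinant-ratio statistic
#'
#' The singularity measure used to identify the system order: the ratio of the
#' k-averaged determinant of dimension-l Hankel matrices to the k-averaged
#' determinant at dimension l + 1,
#' `D_l = | mean_k det H(l, k) | / | mean_k det H(l+1, k) |`,
#' with the numerator averaged over `k = 1..L-2l+2` and the denominator over
#' its own range `k = 1..L-2l`. Signed determinants are averaged: for a
#' decaying multi-exponential sequence the signal determinants share a sign,
#' while noise-dominated determinants average toward zero, which is what makes
#' the statistic peak at the true order.
#'
#' `D_l` grows with l below the true order, peaks at the order, and is
#' meaningless above it (both numerator and denominator are then noise or
#' round-off); [identify_order()] censors those dimensions.
#'
#' @param g an impulse sequence or numeric vector.
#' @param l Hankel dimension, at least 2 (the ratio at l = 1,
#'   `|mean g| / |mean det H(2,.)|`, is used internally by [identify_order()]
#'   as the order-1 limit of the same formula).
#' @return the statistic (dimensionless ratio); `Inf` if the denominator
#'   average is exactly zero while the numerator is not.
#' @export
dl_statistic <- function(g, l) {
  g <- .as_impulse(g)$g
  l <- as.integer(l)
  if (l < 1L) stop("'l' must be at least 1")
  L <- length(g)
  if (L < 2L * (l + 1L)) stop(sprintf("need length(g) >= %d for l = %d", 2L * (l + 1L), l))
  if (all(g == 0)) stop("degenerate (all-zero) impulse sequence")
  num <- mean(.hankel_dets(g, l))
  den <- mean(.hankel_dets(g, l + 1L))
  if (den == 0) {
    if (num == 0) return(NA_real_)
    return(Inf)
  }
  abs(num) / abs(den)
}

#' Block-average decimation of a sampled curve
#'
#' Reduces a uniformly sampled sequence to about `npoints` samples by
#' averaging consecutive blocks. Averaging (rather than sub-sampling) shrinks
#' white measurement noise by `sqrt(m)` for block length m without introducing
#' filter poles into the impulse sequence, which matters for Hankel analysis:
#' determinant conditioning degrades badly on oversampled, nearly identical
#' adjacent samples.
#'
#' @param y numeric vector.
#' @param npoints target number of points (the result has
#'   `floor(length(y) / m)` points with `m = floor(length(y) / npoints)`).
#' @return list with `y` (decimated values) and `factor` (block length m).
#' @export
decimate_curve <- function(y, npoints = 16L) {
  y <- as.numeric(y)
  npoints <- as.integer(npoints)
  if (npoints < 2L) stop("'npoints' must be at least 2")
  m <- max(1L, length(y) %/% npoints)
  nblk <- length(y) %/% m
  dec <- colMeans(matrix(y[seq_len(nblk * m)], nrow = m))
  list(y = dec, factor = m)
}

#' Identify the system order from an impulse sequence
#'
#' Determines the model order by combining the determinant-ratio statistic
#' with two safeguards that make it usable on both noise-free and noisy data:
#'
#' 1. *Rank crash (noise-free data)*: if the k-averaged absolute determinant
#'    collapses between dimensions l and l + 1 by more than `1/rank_tol`
#'    (relative), the Hankel matrices of dimension l + 1 are numerically
#'    singular, the rank is l, and the order is l. This is the exact rank
#'    criterion evaluated at round-off precision.
#' 2. *Noise censoring (noisy data)*: the standard error of each signed mean
#'    determinant under the measurement noise is estimated by Monte-Carlo
#'    perturbation (noise drawn at the step-response level with standard
#'    deviation `noise_sd`, differenced, added to `g`). Dimensions whose mean
#'    determinant is within `z * SE` of zero carry no detectable signal rank
#'    and are excluded; the selected order is the largest surviving dimension,
#'    which is also the argmax of the censored D_l profile. If no dimension
#'    l >= 2 survives, the order is 1.
#'
#' When `noise_sd` is `NULL` it is estimated from the second differences of
#' the tail third of the sequence (where the relaxation has flattened), via
#' `mad(diff(g_tail)) / sqrt(6)`.
#'
#' This function draws random numbers for the Monte-Carlo calibration; results
#' are reproducible under [set.seed()].
#'
#' @param g an impulse sequence ([impulse_from_step()]) or numeric vector.
#' @param lmax largest candidate order (default 6); needs
#'   `length(g) >= 2 * (lmax + 1) - 1`.
#' @param noise_sd standard deviation of the measurement noise on the step
#'   response samples underlying `g`, or `NULL` to estimate it.
#' @param z censoring threshold in standard errors (default 3).
#' @param mc_reps Monte-Carlo replicates for the SE estimate (default 100).
#' @param rank_tol relative collapse ratio declaring numerical rank
#'   deficiency (default 1e-8).
#' @return A `hankel_profile` object: list with `profile` (data.frame of `l`
#'   and `dl` for l = 1..lmax; `dl` is `NA` for censored dimensions),
#'   `selected_order`, `mean_det`, `se_det`, `noise_sd`, and `method`
#'   (`"rank-crash"` or `"noise-censored"`).
#' @export
identify_order <- function(g, lmax = 6L, noise_sd = NULL, z = 3,
                           mc_reps = 100L, rank_tol = 1e-8) {
  gi <- .as_impulse(g)
  g <- gi$g
  lmax <- as.integer(lmax)
  if (lmax < 2L) stop("'lmax' must be at least 2")
  L <- length(g)
  if (L < 2L * (lmax + 1L) - 1L)
    stop(sprintf("need length(g) >= %d for lmax = %d", 2L * (lmax + 1L) - 1L, lmax))
  if (all(g == 0)) stop("degenerate (all-zero) impulse sequence")

  dets <- lapply(seq_len(lmax + 1L), function(l) .hankel_dets(g, l))
  M <- vapply(dets, mean, numeric(1))
  Mabs <- vapply(dets, function(d) mean(abs(d)), numeric(1))

  # D_l profile with degenerate dimensions censored to NA
  dl <- abs(M[seq_len(lmax)]) / abs(M[seq_len(lmax) + 1L])
  dl[!is.finite(dl)] <- NA_real_

  # 1) round-off rank crash
  ratio <- Mabs[-1L] / Mabs[-(lmax + 1L)]
  crash <- which(is.finite(ratio) & ratio < rank_tol | Mabs[-1L] == 0)
  if (length(crash)) {
    n0 <- crash[1L]
    if (n0 < lmax) dl[(n0 + 1L):lmax] <- NA_real_
    return(.hankel_profile(lmax, dl, n0, M, rep(NA_real_, lmax + 1L),
                           NA_real_, "rank-crash"))
  }

  # 2) noise-calibrated censoring
  if (is.null(noise_sd)) {
    tail_g <- g[seq.int(max(1L, L - L %/% 3L), L)]
    noise_sd <- mad(diff(tail_g)) / sqrt(6)
  }
  if (!is.finite(noise_sd) || noise_sd <= 0) {
    # no noise scale available: fall back to the raw argmax of defined D_l
    sel <- which.max(ifelse(is.na(dl), -Inf, dl))
    return(.hankel_profile(lmax, dl, as.integer(sel), M,
                           rep(NA_real_, lmax + 1L), noise_sd, "argmax"))
  }
  pert <- matrix(NA_real_, mc_reps, lmax + 1L)
  for (r in seq_len(mc_reps)) {
    e <- diff(rnorm(L + 1L, sd = noise_sd))
    gp <- g + e
    for (l in seq_len(lmax + 1L))
      pert[r, l] <- mean(.hankel_dets(gp, l)) - M[l]
  }
  SE <- apply(pert, 2L, sd)
  significant <- which(abs(M) > z * SE)
  n0 <- if (length(significant)) min(max(significant), lmax) else 1L
  if (n0 < lmax) dl[(n0 + 1L):lmax] <- NA_real_
  .hankel_profile(lmax, dl, as.integer(n0), M, SE, noise_sd, "noise-censored")
}

.hankel_profile <- function(lmax, dl, selected, M, SE, noise_sd, method) {
  structure(list(
    profile = data.frame(l = seq_len(lmax), dl = dl),
    selected_order = selected,
    mean_det = M, se_det = SE, noise_sd = noise_sd, method = method
  ), class = "hankel_profile")
}

#' @export
print.hankel_profile <- function(x, ...) {
  cat(sprintf("Hankel order identification (%s): selected order %d\n",
              x$method, x$selected_order))
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Identify the system order from a relaxation force curve
#'
#' High-level wrapper around [identify_order()]: restricts the step response
#' to an analysis window (by default the first half of the record, where the
#' relaxation happens), decimates it by block averaging ([decimate_curve()]),
#' estimates the raw measurement-noise level from the high-frequency content
#' of the tail half of the full record, differences to the impulse sequence,
#' and runs the censored determinant-ratio test.
#'
#' @param y numeric relaxation (step-response) force samples, uniformly
#'   sampled, or a `force_curve` (its `force` field is used).
#' @param fs sampling rate (Hz); taken from the curve if one is given.
#' @param window analysis window length (s); `NULL` (default) uses the first
#'   half of the record.
#' @param npoints decimation target for the Hankel analysis (default 16;
#'   coarse averaging concentrates determinant signal-to-noise).
#' @param ... passed to [identify_order()] (`lmax`, `z`, `mc_reps`,
#'   `rank_tol`).
#' @return a `hankel_profile` (see [identify_order()]) with extra fields
#'   `decimation_factor` and `window`.
#' @export
identify_order_curve <- function(y, fs, window = NULL, npoints = 16L, ...) {
  if (inherits(y, "force_curve")) {
    fs <- y$fs
    y <- y$force
  }
  y <- as.numeric(y)
  if (length(y) < 4L) stop("curve too short for order identification")
  # raw-resolution noise estimate from the flat tail half
  tail_y <- y[seq.int(length(y) %/% 2L, length(y))]
  sigma_raw <- mad(diff(tail_y)) / sqrt(2)
  if (is.null(window)) window <- (length(y) / fs) / 2
  nwin <- max(min(length(y), round(window * fs)), 2L * npoints)
  nwin <- min(nwin, length(y))
  dec <- decimate_curve(y[seq_len(nwin)], npoints)
  g <- impulse_from_step(dec$y, dt = dec$factor / fs)
  prof <- identify_order(g, noise_sd = sigma_raw / sqrt(dec$factor), ...)
  prof$decimation_factor <- dec$factor
  prof$window <- nwin / fs
  prof
}
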