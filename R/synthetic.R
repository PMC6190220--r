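#' Published per-cell-type viscoelastic parameter statistics
#'
#' Means and standard deviations of the five second-order Maxwell parameters
#' (k0, k1, k2 in N/m; b1, b2 in N s/m) for the four cell lines whose
#' stress-relaxation behavior the model was validated on: MCF-7 (human breast
#' cancer), Neuro-2a (mouse neuroblastoma), HEK-293 (human embryonic kidney)
#' and L-929 (mouse fibroblast). These rows define the sampling distributions
#' of the synthetic-population generator.
#'
#' @return data.frame with columns `label`, `<p>_mean` and `<p>_sd` for each
#'   of `k0, k1, b1, k2, b2`.
#' @seealso [sample_population()]
#' @export
cell_population_stats <- function() {
  data.frame(
    label = c("MCF-7", "Neuro-2a", "HEK-293", "L-929"),
    k0_mean = c(2.984, 2.425, 1.099, 0.534),
    k0_sd   = c(0.742, 0.589, 0.496, 0.096),
    k1_mean = c(1.110, 1.519, 0.472, 0.195),
    k1_sd   = c(0.372, 0.286, 0.203, 0.067),
    b1_mean = c(0.118, 0.242, 0.158, 0.0124),
    b1_sd   = c(0.306, 0.296, 0.244, 0.049),
    k2_mean = c(1.385, 1.259, 0.609, 0.235),
    k2_sd   = c(0.114, 0.121, 0.090, 0.009),
    b2_mean = c(3.108, 1.934, 1.956, 0.374),
    b2_sd   = c(1.618, 0.891, 0.796, 0.150),
    stringsAsFactors = FALSE
  )
}

.stats_row <- function(stats) {
  if (is.character(stats) && length(stats) == 1L) {
    tab <- cell_population_stats()
    row <- tab[tab$label == stats, ]
    if (!nrow(row)) stop("unknown cell type: ", stats,
                         " (known: ", paste(tab$label, collapse = ", "), ")")
    return(row)
  }
  stats <- as.data.frame(stats)
  need <- as.vector(outer(c("k0", "k1", "b1", "k2", "b2"),
                          c("_mean", "_sd"), paste0))
  if (!all(need %in% names(stats))) stop("stats row lacks columns: ",
                                         paste(setdiff(need, names(stats)), collapse = ", "))
  if (nrow(stats) != 1L) stop("supply a single stats row")
  stats
}

#' Draw a synthetic parameter population for one cell type
#'
#' Each of the five parameters is drawn independently from a Gaussian with the
#' cell type's mean and SD (the published table reports marginal moments only,
#' so independence is the stated emulation model). Draws are truncated at a
#' positive floor rather than resampled: stiffnesses at `0.01 * mean`, damping
#' coefficients at 0 -- several rows put substantial Gaussian mass below zero
#' (e.g. the L-929 fast-path damping 0.0124 +/- 0.049), which is unphysical.
#'
#' @param stats a cell type label (one of the rows of
#'   [cell_population_stats()]) or a single-row data.frame with the same
#'   schema.
#' @param n number of cells to draw.
#' @param seed optional integer seed for reproducibility.
#' @return list of [maxwell_params()] objects with attribute `label`.
#' @export
sample_population <- function(stats, n, seed = NULL) {
  row <- .stats_row(stats)
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  draw <- function(p) rnorm(n, row[[paste0(p, "_mean")]], row[[paste0(p, "_sd")]])
  k0 <- pmax(draw("k0"), 0.01 * row$k0_mean)
  k1 <- pmax(draw("k1"), 0.01 * row$k1_mean)
  b1 <- pmax(draw("b1"), 0)
  k2 <- pmax(draw("k2"), 0.01 * row$k2_mean)
  b2 <- pmax(draw("b2"), 0)
  out <- lapply(seq_len(n), function(i)
    maxwell_params(k0[i], c(k1[i], k2[i]), c(b1[i], b2[i])))
  attr(out, "label") <- if ("label" %in% names(row)) row$label else NA_character_
  out
}

#' Generate a synthetic stress-relaxation curve
#'
#' Evaluates the closed-form relaxation response of a Maxwell parameter set on
#' a uniform grid and adds i.i.d. Gaussian measurement noise whose SD is a
#' fraction `noise_sd` of the initial relaxation amplitude
#' `y(0) - y(Inf) = u * sum(k_i)`.
#'
#' @param params a [maxwell_params()] object.
#' @param u_const constant hold displacement (um), default 1 (the PZT hold
#'   depth used in the experiments).
#' @param fs sampling rate (Hz), default 1000.
#' @param duration relaxation window (s), default 6.
#' @param noise_sd noise SD as a fraction of the relaxation amplitude,
#'   default 0 (noise-free).
#' @param seed optional integer seed.
#' @return a [force_curve()] with phase `"relaxation"` throughout.
#' @export
generate_curve <- function(params, u_const = 1, fs = 1000, duration = 6,
                           noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "maxwell_params"))
  t <- seq(0, duration, by = 1 / fs)
  y <- relaxation_response(params, u_const, t)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    amp <- abs(u_const) * sum(params$k)
    y <- y + rnorm(length(y), sd = noise_sd * amp)
  }
  force_curve(t, z = u_const, force = y, phase = "relaxation")
}

#' Generate a full synthetic indentation record (approach-hold-retract)
#'
#' Builds the PZT z-trajectory of a complete indentation experiment -- a ramp
#' at `speed` lasting `approach` seconds that ends `hold_depth` above the
#' contact point, a hold of `hold` seconds, and a retract ramp -- and
#' integrates the Maxwell state-space model under the time-varying
#' contact-clipped input `u(t) = max(z(t), 0)`. Defaults reproduce the
#' experimental protocol: 4 um/s ramps, 1 s approach, 6 s hold at 1 um,
#' 1 s retract. Used to exercise [segment_relaxation()] end to end; requires
#' all `b > 0` (state-space integration).
#'
#' @param params a [maxwell_params()] object with all `b > 0`.
#' @param speed PZT ramp speed (um/s), default 4.
#' @param approach approach duration (s), default 1.
#' @param hold hold duration (s), default 6.
#' @param retract retract duration (s), default 1.
#' @param hold_depth z-position held during relaxation (um), default 1.
#' @param fs sampling rate (Hz), default 1000.
#' @return a [force_curve()] with phase labels set per segment; its `z`
#'   channel carries the full PZT trajectory (negative before contact).
#' @export
generate_full_indentation <- function(params, speed = 4, approach = 1, hold = 6,
                                      retract = 1, hold_depth = 1, fs = 1000) {
  stopifnot(inherits(params, "maxwell_params"))
  if (hold <= 0) stop("'hold' must be positive")
  t <- seq(0, approach + hold + retract, by = 1 / fs)
  z0 <- hold_depth - speed * approach            # start below contact
  z <- ifelse(t < approach, z0 + speed * t,
       ifelse(t < approach + hold, hold_depth,
              hold_depth - speed * (t - approach - hold)))
  u <- pmax(z, 0)
  traj <- simulate_state_space(params, u, t)
  phase <- ifelse(t < approach, "approach",
           ifelse(t < approach + hold, "relaxation", "retract"))
  force_curve(t, z = z, force = traj$output, phase = phase)
}
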