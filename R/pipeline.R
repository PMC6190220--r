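#' Analysis run configuration
#'
#' Bundles the instrument constants and stage settings of the pipeline with
#' validation. The configuration round-trips losslessly through JSON
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param spring_constant cantilever spring constant (N/m).
#' @param fs sampling rate (Hz).
#' @param filter_cutoff low-pass cutoff for curve smoothing (Hz); `NA`
#'   disables smoothing.
#' @param lmax largest candidate order for Hankel identification.
#' @param decimate decimation target (points) for Hankel analysis.
#' @param order forced model order; `NA` (default) identifies it per curve.
#' @param hold_tolerance |dz/dt| threshold for hold-phase segmentation (um/s).
#' @param seed integer seed for the stochastic stages.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(spring_constant = 0.2960, fs = 1000, filter_cutoff = 10,
                       lmax = 6L, decimate = 16L, order = NA_integer_,
                       hold_tolerance = 0.1, seed = 1L) {
  stopifnot(spring_constant > 0, fs > 0, lmax >= 2, decimate >= 4,
            hold_tolerance > 0)
  if (!is.na(filter_cutoff) && filter_cutoff <= 0) stop("'filter_cutoff' must be positive")
  structure(list(spring_constant = spring_constant, fs = fs,
                 filter_cutoff = filter_cutoff, lmax = as.integer(lmax),
                 decimate = as.integer(decimate), order = as.integer(order),
                 hold_tolerance = hold_tolerance, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  lst$order <- if (is.null(lst$order) || is.na(lst$order)) NA_integer_ else as.integer(lst$order)
  do.call(run_config, lst[setdiff(names(lst), character())])
}

#' Analyze one relaxation curve: smooth, identify order, fit
#'
#' Runs the single-curve pipeline stages on a [force_curve()]. If the curve
#' contains non-hold phases (z varies), the relaxation window is segmented
#' first; otherwise the whole record is used with `u = mean(z)`. Smoothing
#' uses the configured zero-phase low-pass; order identification runs on the
#' unsmoothed window (the filter's own poles would enter the Hankel
#' statistic) unless an order override is configured.
#'
#' @param curve a [force_curve()].
#' @param config a [run_config()].
#' @return list with `order` (identified or forced), `profile`
#'   (`hankel_profile` or `NULL` when forced), `fit` (`fit_result`),
#'   `u_const`.
#' @export
analyze_curve <- function(curve, config = run_config()) {
  stopifnot(inherits(curve, "force_curve"), inherits(config, "run_config"))
  if (max(curve$z) - min(curve$z) > 100 * .Machine$double.eps * max(abs(curve$z), 1)) {
    seg <- segment_relaxation(curve, config$hold_tolerance)
  } else {
    seg <- list(t = curve$t - curve$t[1L], u_const = mean(curve$z), y = curve$force)
  }
  profile <- NULL
  if (is.na(config$order)) {
    profile <- identify_order_curve(seg$y, fs = curve$fs,
                                    npoints = config$decimate, lmax = config$lmax)
    ord <- profile$selected_order
  } else {
    ord <- config$order
  }
  y_fit <- seg$y
  if (!is.na(config$filter_cutoff) && curve$fs > 2 * config$filter_cutoff)
    y_fit <- lowpass(seg$y, curve$fs, config$filter_cutoff)
  fit <- fit_relaxation(seg$t, y_fit, seg$u_const, ord)
  list(order = ord, profile = profile, fit = fit, u_const = seg$u_const)
}

#' Run the full analysis pipeline on a cohort of curves
#'
#' Per curve: segmentation (when needed), order identification, least-squares
#' parameter extraction. Cohort level: the fitted five-parameter vectors are
#' summarized by PCA and, when labels are available for at least two classes,
#' a train/test split is classified with the backpropagation network.
#' Per-curve failures are collected, not fatal.
#'
#' @param curves list of [force_curve()] objects.
#' @param config a [run_config()].
#' @param labels optional per-curve cell-type labels.
#' @param train_frac fraction of each class used for classifier training
#'   (default 0.75, i.e. the 30-train/10-test design at 40 curves per type).
#' @return A `pipeline_result`: list with `curves` (per-curve data.frame:
#'   label, order, k0, k1, b1, k2, b2, residual_norm, r_squared, converged),
#'   `pca` (`pca_summary` or `NULL`), `classification` (list with `model`,
#'   `accuracy`, `confusion`, or `NULL`), `errors` (named list).
#' @export
run_pipeline <- function(curves, config = run_config(), labels = NULL,
                         train_frac = 0.75) {
  stopifnot(is.list(curves))
  if (!length(curves)) stop("empty curve set")
  if (!is.null(labels)) stopifnot(length(labels) == length(curves))
  set.seed(config$seed)
  rows <- list(); errors <- list()
  for (i in seq_along(curves)) {
    res <- tryCatch(analyze_curve(curves[[i]], config), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[as.character(i)]] <- conditionMessage(res)
      next
    }
    p <- res$fit$params
    rows[[length(rows) + 1L]] <- data.frame(
      curve = i,
      label = if (is.null(labels)) NA_character_ else as.character(labels[i]),
      order = res$order,
      k0 = p$k0,
      k1 = if (p$n >= 1) p$k[1] else NA_real_,
      b1 = if (p$n >= 1) p$b[1] else NA_real_,
      k2 = if (p$n >= 2) p$k[2] else NA_real_,
      b2 = if (p$n >= 2) p$b[2] else NA_real_,
      residual_norm = res$fit$residual_norm,
      r_squared = res$fit$r_squared,
      converged = res$fit$converged,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no curve could be analyzed; first error: ", errors[[1L]])
  tab <- do.call(rbind, rows)

  feat_cols <- c("k0", "k1", "b1", "k2", "b2")
  complete <- stats::complete.cases(tab[, feat_cols])
  pca <- NULL
  if (sum(complete) >= 2L)
    pca <- tryCatch(pca_summary(tab[complete, feat_cols]), error = function(e) NULL)

  classification <- NULL
  if (!is.null(labels) && length(unique(tab$label[complete])) >= 2L) {
    sub <- tab[complete, ]
    tr <- unlist(lapply(split(seq_len(nrow(sub)), sub$label), function(ii)
      ii[sample.int(length(ii), max(1L, round(train_frac * length(ii))))]))
    te <- setdiff(seq_len(nrow(sub)), tr)
    model <- train_classifier(sub[tr, feat_cols], sub$label[tr])
    ev <- if (length(te)) evaluate_classifier(model, sub[te, feat_cols], sub$label[te])
          else list(accuracy = NA_real_, confusion = NULL, n_errors = NA_integer_)
    classification <- list(model = model, accuracy = ev$accuracy,
                           confusion = ev$confusion, n_test = length(te))
  }
  structure(list(curves = tab, pca = pca, classification = classification,
                 errors = errors, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d curve(s) analyzed, %d failed\n",
              nrow(x$curves), length(x$errors)))
  cat("Identified orders:\n")
  print(table(x$curves$order))
  if (!is.null(x$pca)) {
    cat("\n"); print(x$pca)
  }
  if (!is.null(x$classification))
    cat(sprintf("\nClassification accuracy on held-out curves: %.1f%% (%d test samples)\n",
                x$classification$accuracy, x$classification$n_test))
  invisible(x)
}

#' Demonstration run on synthetic cohorts of the four cell types
#'
#' Simulates `n_per_type` cells for each of the four cell types from the
#' published population statistics (20 cells of each type were measured in
#' the study, two indentations each), generates their relaxation curves, and
#' runs the full pipeline: order identification, parameter extraction, PCA
#' and classification.
#'
#' @param n_per_type synthetic cells per cell type (default 20).
#' @param noise_sd measurement noise as a fraction of the relaxation
#'   amplitude (default 0.01).
#' @param config a [run_config()]; its seed drives all randomness.
#' @return a `pipeline_result` (see [run_pipeline()]).
#' @export
demo_pipeline <- function(n_per_type = 20L, noise_sd = 0.01,
                          config = run_config()) {
  set.seed(config$seed)
  stats_tab <- cell_population_stats()
  curves <- list(); labels <- character()
  for (lab in stats_tab$label) {
    pop <- sample_population(lab, n_per_type)
    for (p in pop) {
      curves[[length(curves) + 1L]] <-
        generate_curve(p, fs = config$fs, noise_sd = noise_sd)
      labels <- c(labels, lab)
    }
  }
  run_pipeline(curves, config, labels)
}
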