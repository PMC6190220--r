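.as_param_matrix <- function(x) {
  X <- as.matrix(x)
  if (!is.numeric(X)) stop("parameter matrix must be numeric")
  if (anyNA(X)) stop("parameter matrix contains missing entries")
  X
}

#' Principal component analysis of cellular parameter vectors
#'
#' Eigen-decomposition of the correlation matrix of the sample-by-parameter
#' matrix (columns are standardized to unit variance first, so the eigenvalues
#' sum to the number of variables). Reports, per component: eigenvalue,
#' difference to the next eigenvalue, contribution rate
#' `lambda_j / sum(lambda) * 100` (%), and the cumulative total (%), plus the
#' per-sample component scores and the count of eigenvalues above 1 (the
#' Kaiser criterion, reported but driving no decision).
#'
#' @param x numeric matrix or data.frame, samples in rows, parameters in
#'   columns (canonical column order: k0, k1, b1, k2, b2).
#' @return A `pca_summary` object: list with `table` (the report
#'   data.frame), `eigenvalues`, `rotation`, `scores`, `kaiser`, `center`,
#'   `scale`.
#' @export
pca_summary <- function(x) {
  X <- .as_param_matrix(x)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant column(s): ", paste(bad, collapse = ", "))
  }
  Z <- scale(X)
  eig <- eigen(stats::cor(X), symmetric = TRUE)
  lambda <- eig$values
  contrib <- lambda / sum(lambda) * 100
  tab <- data.frame(
    component = seq_along(lambda),
    eigenvalue = lambda,
    difference = c(-diff(lambda), NA_real_),
    contribution = contrib,
    cumulative = cumsum(contrib)
  )
  structure(list(table = tab, eigenvalues = lambda, rotation = eig$vectors,
                 scores = Z %*% eig$vectors, kaiser = sum(lambda > 1),
                 center = attr(Z, "scaled:center"),
                 scale = attr(Z, "scaled:scale")),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, digits = 4, ...) {
  cat("Principal component analysis (correlation matrix)\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  cat(sprintf("Eigenvalues > 1 (Kaiser): %d\n", x$kaiser))
  invisible(x)
}

# --- two-hidden-layer backpropagation network -------------------------------
# No multi-hidden-layer perceptron ships with the environment, so the small
# network is implemented here: logistic hidden units, softmax output,
# cross-entropy loss, full-batch Adam.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmax <- function(X) {
  E <- exp(X - apply(X, 1L, max))
  E / rowSums(E)
}

.nn_init <- function(sizes) {
  W <- list(); b <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    W[[i]] <- matrix(rnorm(sizes[i] * sizes[i + 1L], sd = sqrt(2 / sizes[i])),
                     sizes[i], sizes[i + 1L])
    b[[i]] <- numeric(sizes[i + 1L])
  }
  list(W = W, b = b)
}

.nn_forward <- function(net, X) {
  L <- length(net$W)
  act <- vector("list", L + 1L)
  act[[1L]] <- X
  for (i in seq_len(L)) {
    z <- sweep(act[[i]] %*% net$W[[i]], 2L, net$b[[i]], "+")
    act[[i + 1L]] <- if (i < L) .sigmoid(z) else .softmax(z)
  }
  act
}

#' Train the backpropagation cell-type classifier
#'
#' Trains a feed-forward network on parameter vectors: 5 inputs, two hidden
#' layers of 20 and 40 logistic units, and a softmax output over the class
#' labels, fitted by full-batch Adam on the cross-entropy loss. Features are
#' standardized with statistics computed from the training set only, so the
#' classifier is invariant to affine rescaling of its inputs. With a
#' `validation_frac > 0` a stratified validation split is held out and the
#' weights with the lowest validation loss are kept (early stopping);
#' classes too small to split are trained without one.
#'
#' @param x training feature matrix (rows = samples, columns = the five
#'   parameters k0, k1, b1, k2, b2).
#' @param labels class label per row (factor or character).
#' @param hidden hidden layer sizes, default `c(20, 40)`.
#' @param seed optional integer seed (weight init and split).
#' @param epochs maximum training epochs, default 2000.
#' @param learn_rate Adam step size, default 0.01.
#' @param validation_frac fraction held out for early stopping, default 0.2.
#' @param patience epochs without validation improvement before stopping,
#'   default 300.
#' @return a `bp_classifier` object.
#' @export
train_classifier <- function(x, labels, hidden = c(20L, 40L), seed = NULL,
                             epochs = 2000L, learn_rate = 0.01,
                             validation_frac = 0.2, patience = 300L) {
  X <- .as_param_matrix(x)
  labels <- factor(labels)
  if (nrow(X) != length(labels)) stop("row/label count mismatch")
  if (any(table(labels) < 1L)) stop("every class needs at least one sample")
  if (!is.null(seed)) set.seed(seed)

  center <- colMeans(X)
  scl <- apply(X, 2L, sd); scl[scl == 0] <- 1
  Z <- scale(X, center, scl)
  classes <- levels(labels)
  Y <- outer(as.integer(labels), seq_along(classes), `==`) * 1

  # stratified validation split (skipped for tiny classes)
  val_idx <- integer()
  if (validation_frac > 0 && all(table(labels) >= 5L)) {
    for (cl in classes) {
      ii <- which(labels == cl)
      val_idx <- c(val_idx, ii[sample.int(length(ii), max(1L, round(validation_frac * length(ii))))])
    }
  }
  tr_idx <- setdiff(seq_len(nrow(Z)), val_idx)

  sizes <- c(ncol(Z), hidden, length(classes))
  net <- .nn_init(sizes)
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  ce <- function(P, Ym) -mean(rowSums(Ym * log(pmax(P, 1e-12))))

  Ztr <- Z[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  best <- list(loss = Inf, W = net$W, b = net$b, epoch = 0L)
  stall <- 0L
  n_tr <- nrow(Ztr)
  for (ep in seq_len(epochs)) {
    act <- .nn_forward(net, Ztr)
    delta <- (act[[L + 1L]] - Ytr) / n_tr          # softmax + CE gradient
    for (i in rev(seq_len(L))) {
      gW <- crossprod(act[[i]], delta)
      gb <- colSums(delta)
      if (i > 1L) {
        delta <- (delta %*% t(net$W[[i]])) * act[[i]] * (1 - act[[i]])
      }
      mW[[i]] <- beta1 * mW[[i]] + (1 - beta1) * gW
      vW[[i]] <- beta2 * vW[[i]] + (1 - beta2) * gW^2
      mb[[i]] <- beta1 * mb[[i]] + (1 - beta1) * gb
      vb[[i]] <- beta2 * vb[[i]] + (1 - beta2) * gb^2
      corr1 <- 1 - beta1^ep; corr2 <- 1 - beta2^ep
      net$W[[i]] <- net$W[[i]] - learn_rate * (mW[[i]] / corr1) /
        (sqrt(vW[[i]] / corr2) + eps)
      net$b[[i]] <- net$b[[i]] - learn_rate * (mb[[i]] / corr1) /
        (sqrt(vb[[i]] / corr2) + eps)
    }
    if (length(val_idx)) {
      Pv <- .nn_forward(net, Z[val_idx, , drop = FALSE])[[L + 1L]]
      lv <- ce(Pv, Y[val_idx, , drop = FALSE])
      if (lv < best$loss - 1e-6) {
        best <- list(loss = lv, W = net$W, b = net$b, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  }
  if (length(val_idx) && is.finite(best$loss)) {
    net$W <- best$W; net$b <- best$b
  }
  structure(list(net = net, classes = classes, center = center, scale = scl,
                 hidden = hidden, epochs_run = if (length(val_idx)) best$epoch else epochs),
            class = "bp_classifier")
}

#' Predict cell types with a trained classifier
#'
#' @param object a `bp_classifier` from [train_classifier()].
#' @param newdata feature matrix with the training column layout.
#' @param type `"class"` (default) for labels, `"prob"` for the softmax
#'   class-probability matrix.
#' @param ... unused.
#' @return factor of predicted labels, or a probability matrix.
#' @export
predict.bp_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  Z <- scale(.as_param_matrix(newdata), object$center, object$scale)
  P <- .nn_forward(object$net, Z)[[length(object$net$W) + 1L]]
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")], levels = object$classes)
}

#' Evaluate a classifier on labeled data
#'
#' @param model a `bp_classifier`.
#' @param x feature matrix.
#' @param labels true labels.
#' @return list with `accuracy` (percent correct), `confusion` (true x
#'   predicted contingency table) and `n_errors`.
#' @export
evaluate_classifier <- function(model, x, labels) {
  if (!length(labels) || !nrow(.as_param_matrix(x))) stop("empty test set")
  pred <- predict(model, x)
  correct <- as.character(pred) == as.character(labels)
  list(accuracy = 100 * mean(correct),
       confusion = table(truth = labels, predicted = pred),
       n_errors = sum(!correct))
}
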