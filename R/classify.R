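.CLASSES <- c("iStroke", "hStroke", "noStroke")

#' Feature extraction from a reciprocal S-matrix
#'
#' The 55 independent upper-triangle channels (canonical order), real
#' parts first then imaginary parts: a 110-dimensional real feature
#' vector.
#'
#' @param s An [smatrix].
#' @param tol Reciprocity tolerance; non-reciprocal matrices beyond this
#'   signal an ordering ambiguity and raise an error.
#' @return Numeric vector of length 110.
#' @export
extract_features <- function(s, tol = 1e-6) {
  stopifnot(inherits(s, "smatrix"))
  if (max(Mod(s$entries - t(s$entries))) > tol)
    stop("S-matrix not reciprocal within ", tol,
         "; channel ordering would be ambiguous")
  ch <- pack_channels(s)
  c(Re(ch), Im(ch))
}

#' Feature matrix of a dataset
#' @param dataset A `labeled_dataset`.
#' @return Numeric n x 110 matrix (rows = samples).
#' @export
feature_matrix <- function(dataset) {
  t(vapply(dataset$samples,
           function(s) extract_features(s$s_matrix), numeric(110)))
}

#' Fit a PCA basis on training features
#'
#' Mean-centered PCA (no variance scaling: real and imaginary S-parameter
#' features share units), keeping the top `n_components` components by
#' explained variance. Loading signs are fixed deterministically by
#' making each loading's largest-magnitude coordinate positive.
#'
#' @param x Numeric n x p training feature matrix, n > `n_components`.
#' @param n_components Number of components to keep (default 20).
#' @param scale. Standardize features to unit variance first (default
#'   FALSE).
#' @return An object of class `pca_basis` with `center`, `scale`,
#'   `rotation` (p x n_components) and `sdev`.
#' @export
fit_pca <- function(x, n_components = 20, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) <= n_components)
    stop("need more than ", n_components, " training samples, got ",
         nrow(x))
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(p$rotation))
  rot <- p$rotation[, 1:k, drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(center = p$center,
                 scale = if (isTRUE(scale.)) p$scale else FALSE,
                 rotation = rot, sdev = p$sdev[1:k]),
            class = "pca_basis")
}

#' Project features onto a fitted PCA basis
#'
#' Always uses the training mean (and scale, if any) and loadings; test
#' data never updates the basis.
#'
#' @param basis A `pca_basis`.
#' @param x Numeric n x p feature matrix.
#' @return n x n_components score matrix.
#' @export
project_pca <- function(basis, x) {
  stopifnot(inherits(basis, "pca_basis"))
  x <- as.matrix(x)
  x <- sweep(x, 2, basis$center)
  if (!isFALSE(basis$scale)) x <- sweep(x, 2, basis$scale, "/")
  x %*% basis$rotation
}

#' Train a Gaussian-kernel SVM with seeded cross-validated search
#'
#' One-vs-one multiclass SVM with RBF kernel
#' `exp(-||x - y||^2 / s^2)` (kernel scale `s`, i.e. libsvm
#' `gamma = 1 / s^2`) and box constraint `C`. The pair `(s, C)` is chosen
#' by k-fold cross-validated accuracy over a log-spaced grid: kernel
#' scales `s0 * 2^(-3..3)` around the median pairwise training distance
#' `s0`, and box constraints `10^(-1..3)`. Folds are stratified by class
#' and drawn from the given seed, so the selected pair is reproducible.
#' Ties go to the first grid point in row-major (scale, then cost) order.
#'
#' Degenerate training sets (any class with fewer than `k` members, or
#' too few samples to cross-validate) skip the search and use `s0` and
#' `C = 1`.
#'
#' @param x Numeric n x d matrix of (projected) training features.
#' @param labels Character or factor labels; all 3 classes must be
#'   present.
#' @param k Number of CV folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param kernel_scales,costs Optional explicit search grids.
#' @return An object of class `svm_model` with the fitted e1071 SVM, the
#'   selected `kernel_scale` and `cost`, the CV accuracy of the selected
#'   pair, and the class levels.
#' @export
train_svm <- function(x, labels, k = 5, seed = 1,
                      kernel_scales = NULL, costs = NULL) {
  x <- as.matrix(x)
  y <- factor(as.character(labels), levels = .CLASSES)
  if (anyNA(y)) stop("unknown labels: ",
                     paste(setdiff(unique(as.character(labels)), .CLASSES),
                           collapse = ", "))
  counts <- table(y)
  if (any(counts == 0))
    stop("all 3 classes must be present; counts: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))
  n <- nrow(x)
  set.seed(seed)
  dists <- stats::dist(if (n > 400) x[sample.int(n, 400), , drop = FALSE]
                       else x)
  s0 <- stats::median(dists)
  if (!is.finite(s0) || s0 <= 0) s0 <- 1
  if (is.null(kernel_scales)) kernel_scales <- s0 * 2^(-3:3)
  if (is.null(costs)) costs <- 10^(-1:3)
  cv_ok <- min(counts) >= k && n >= 2 * k
  best <- list(scale = s0, cost = 1, acc = NA_real_)
  if (cv_ok) {
    folds <- integer(n)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    best$acc <- -Inf
    for (s in kernel_scales) for (C in costs) {
      correct <- 0L
      for (f in seq_len(k)) {
        tr <- folds != f
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                          kernel = "radial", gamma = 1 / s^2, cost = C,
                          scale = FALSE)
        pred <- stats::predict(fit, x[!tr, , drop = FALSE])
        correct <- correct + sum(pred == y[!tr])
      }
      acc <- correct / n
      if (acc > best$acc) best <- list(scale = s, cost = C, acc = acc)
    }
  }
  fit <- e1071::svm(x, y, kernel = "radial", gamma = 1 / best$scale^2,
                    cost = best$cost, scale = FALSE)
  structure(list(fit = fit, kernel_scale = best$scale, cost = best$cost,
                 cv_accuracy = best$acc, classes = levels(y),
                 k = k, seed = seed),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf(
    "<svm_model> RBF, kernel scale %.4g, box constraint %.4g, CV acc %s\n",
    x$kernel_scale, x$cost,
    if (is.na(x$cv_accuracy)) "n/a" else sprintf("%.3f", x$cv_accuracy)))
  invisible(x)
}

#' Fit the full stroke classifier on a training dataset
#'
#' Feature extraction (110 features), PCA to `n_components`, then the
#' cross-validated Gaussian SVM. The returned model carries everything
#' needed to classify new S-matrices; evaluation never updates it.
#'
#' @param train A `labeled_dataset` (typically the M1 analog).
#' @param n_components PCA dimensionality (default 20).
#' @param k CV folds (default 5).
#' @param seed Integer seed for the hyperparameter search.
#' @param scale. Standardize features before PCA (default FALSE).
#' @return An object of class `stroke_classifier`.
#' @export
fit_classifier <- function(train, n_components = 20, k = 5, seed = 1,
                           scale. = FALSE) {
  stopifnot(inherits(train, "labeled_dataset"))
  X <- feature_matrix(train)
  pca <- fit_pca(X, n_components = n_components, scale. = scale.)
  Z <- project_pca(pca, X)
  svmfit <- train_svm(Z, dataset_labels(train), k = k, seed = seed)
  structure(list(pca = pca, svm = svmfit, n_components = n_components,
                 train_name = train$name, seed = seed),
            class = "stroke_classifier")
}

#' @export
print.stroke_classifier <- function(x, ...) {
  cat(sprintf("<stroke_classifier> PCA-%d + ", x$n_components))
  print(x$svm)
  invisible(x)
}

#' Predict stroke labels
#'
#' @param object A `stroke_classifier`.
#' @param newdata A `labeled_dataset`, an [smatrix], or a numeric n x 110
#'   feature matrix.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.stroke_classifier <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_dataset")) feature_matrix(newdata)
       else if (inherits(newdata, "smatrix"))
         matrix(extract_features(newdata), nrow = 1)
       else as.matrix(newdata)
  Z <- project_pca(object$pca, X)
  as.character(stats::predict(object$svm$fit, Z))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` computed from the row and column marginals.
#' A degenerate table with `p_e = 1` yields 0 with a warning.
#'
#' @param confusion Square matrix of nonnegative counts (rows = true,
#'   columns = predicted).
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("negative counts")
  n <- sum(cm)
  if (n <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("degenerate marginals (p_e = 1); kappa defined as 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Evaluate a classifier on a held-out dataset
#'
#' Predicts every sample of the test dataset and summarizes the 3 x 3
#' confusion matrix (rows = true, columns = predicted), overall accuracy,
#' per-class recall and Cohen's kappa. The model is read-only here: the
#' test set never influences PCA or SVM parameters.
#'
#' @param model A `stroke_classifier`.
#' @param test A `labeled_dataset` (typically the M2 analog).
#' @return An object of class `evaluation_report`.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "stroke_classifier"),
            inherits(test, "labeled_dataset"))
  truth <- dataset_labels(test)
  unseen <- setdiff(unique(truth), .CLASSES)
  if (length(unseen))
    stop("unseen label(s) in test data: ", paste(unseen, collapse = ", "))
  pred <- predict(model, test)
  cm <- table(factor(truth, levels = .CLASSES),
              factor(pred, levels = .CLASSES))
  cm <- unclass(matrix(as.integer(cm), 3, 3,
                       dimnames = list(true = .CLASSES,
                                       predicted = .CLASSES)))
  accuracy <- sum(diag(cm)) / sum(cm)
  recall <- diag(cm) / pmax(rowSums(cm), 1)
  names(recall) <- .CLASSES
  structure(list(confusion = cm, accuracy = accuracy, recall = recall,
                 kappa = cohens_kappa(cm), n = sum(cm)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n = %d, accuracy = %.3f, kappa = %.3f\n",
              x$n, x$accuracy, x$kappa))
  print(x$confusion)
  cat("per-class recall:",
      paste(names(x$recall), sprintf("%.3f", x$recall), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
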