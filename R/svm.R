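# One-vs-rest RBF-kernel SVM over an established max-margin solver (libsvm
# via e1071). The multi-class reduction is explicit one-vs-rest -- one binary
# machine per emotion -- so each class exposes a continuous decision score
# for ROC analysis; the predicted class is the arg-max of the three scores.

#' Train a one-vs-rest RBF-kernel SVM
#'
#' @param ds An `emotion_dataset` from [assemble_dataset()], or a list with
#'   elements `X` (matrix) and `y` (labels).
#' @param cost Soft-margin cost C (default 1).
#' @param gamma RBF width; default `1 / (n_features * var(X))` over all
#'   entries of `X`.
#' @return An `ovr_svm` classifier.
#' @export
train_svm_rbf <- function(ds, cost = 1, gamma = NULL) {
  X <- as.matrix(ds$X)
  y <- as.character(ds$y)
  classes <- intersect(EMOTION_LABELS, unique(y))
  if (length(classes) < 2) {
    abort("Need at least two classes to train a classifier.")
  }
  if (is.null(gamma)) {
    v <- var(as.vector(X))
    gamma <- if (v > 0) 1 / (ncol(X) * v) else 1
  }
  machines <- lapply(classes, function(cls) {
    yy <- factor(ifelse(y == cls, "yes", "no"), levels = c("yes", "no"))
    e1071::svm(X, yy, type = "C-classification", kernel = "radial",
               cost = cost, gamma = gamma, scale = FALSE)
  })
  names(machines) <- classes
  structure(list(machines = machines, classes = classes,
                 cost = cost, gamma = gamma, n_features = ncol(X)),
            class = "ovr_svm")
}

#' @export
print.ovr_svm <- function(x, ...) {
  cat(sprintf("<ovr_svm> %d one-vs-rest RBF machines (C=%g, gamma=%g, %d features)\n",
              length(x$machines), x$cost, x$gamma, x$n_features))
  invisible(x)
}

#' Predict emotions with a trained classifier
#'
#' Generic over the package's classifiers. Returns the arg-max class plus
#' the per-class continuous scores used for one-vs-rest ROC analysis.
#'
#' @param model A trained classifier (`ovr_svm` or `eeg_net`).
#' @param X Feature matrix with the training column count.
#' @return List with `class` (factor over the emotion labels) and `scores`
#'   (`n x 3` matrix, one column per label).
#' @export
predict_emotion <- function(model, X) {
  UseMethod("predict_emotion")
}

#' @export
predict_emotion.ovr_svm <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    abort(sprintf("Feature width %d does not match the %d training features.",
                  ncol(X), model$n_features))
  }
  scores <- vapply(model$classes, function(cls) {
    pr <- predict(model$machines[[cls]], X, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient so larger means more likely the target class
    if (colnames(dv)[1] == "yes/no") dv[, 1] else -dv[, 1]
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X),
                   dimnames = list(NULL, model$classes))
  full <- matrix(-Inf, nrow(X), length(EMOTION_LABELS),
                 dimnames = list(NULL, EMOTION_LABELS))
  full[, model$classes] <- scores
  cls <- factor(EMOTION_LABELS[max.col(full, ties.method = "first")],
                levels = EMOTION_LABELS)
  list(class = cls, scores = full)
}
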