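# Dataset assembly and model evaluation: stratified 5-fold cross-validation
# (subject-dependent) and leave-one-subject-out (subject-independent), with
# confusion-matrix metrics and one-vs-rest ROC/AUC.

#' Assemble a modelling dataset from feature tables
#'
#' Stacks one or more feature tables (same measure), optionally restricts the
#' columns to the adopted channels of an electrode selection (the
#' kernel-SVM path; the neural networks consume all channels), drops rows
#' with undefined features, and shuffles row order with a fixed seed.
#'
#' @param tables A `feature_table` or list of them.
#' @param selection Optional `electrode_selection`; its adopted channels
#'   become the feature columns. An empty adoption set is an error (skip
#'   that subject/measure instead).
#' @param seed Seed for the row shuffle.
#' @return An `emotion_dataset`: list with `X` (matrix), `y` (factor),
#'   `subject_id` (per row), `measure`.
#' @export
assemble_dataset <- function(tables, selection = NULL, seed = 1L) {
  if (is.data.frame(tables)) tables <- list(tables)
  measure <- attr(tables[[1]], "measure")
  tbl <- dplyr::bind_rows(lapply(tables, as.data.frame))
  channels <- setdiff(names(tbl), c("segment_id", "subject_id", "trial", "label"))
  if (!is.null(selection)) {
    keep <- adopted_channels(selection)
    if (length(keep) == 0) {
      abort(paste("The selection adopted no electrodes; skip this",
                  "subject/measure instead of assembling an empty dataset."))
    }
    channels <- intersect(channels, keep)
  }
  X <- as.matrix(tbl[, channels, drop = FALSE])
  ok <- stats::complete.cases(X)
  if (any(!ok)) {
    rlang::inform(sprintf("assemble_dataset: dropped %d row(s) with NA features.",
                          sum(!ok)))
  }
  with_local_seed(seed, {
    ord <- sample(which(ok))
    structure(
      list(X = X[ord, , drop = FALSE],
           y = factor(tbl$label[ord], levels = EMOTION_LABELS),
           subject_id = tbl$subject_id[ord],
           measure = measure),
      class = "emotion_dataset")
  })
}

#' @export
print.emotion_dataset <- function(x, ...) {
  cat(sprintf("<emotion_dataset> %d segments x %d features (%s) | %s\n",
              nrow(x$X), ncol(x$X), x$measure %||% "?",
              paste(sprintf("%s=%d", levels(x$y), table(x$y)), collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-class one-vs-rest confusion counts and Eq-style metrics
#'
#' @param tp,tn,fp,fn One-vs-rest counts.
#' @return One-row tibble with `accuracy = (TP+TN)/(TP+TN+FP+FN)`,
#'   `sensitivity = TP/(TP+FN)` and `specificity = TN/(TN+FP)`.
#' @export
ovr_metrics <- function(tp, tn, fp, fn) {
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Metrics from a 3x3 confusion matrix
#'
#' Rows are true labels, columns predictions. Overall accuracy is
#' `trace / total`; per-class sensitivity and specificity come from the
#' one-vs-rest reduction of the matrix ([ovr_metrics()]).
#'
#' @param cm 3x3 numeric matrix with dimnames over the emotion labels.
#' @return List with `accuracy` and a `per_class` tibble.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) == 0) abort("Confusion matrix is empty.")
  if (is.null(rownames(cm))) {
    dimnames(cm) <- list(EMOTION_LABELS[seq_len(nrow(cm))],
                         EMOTION_LABELS[seq_len(ncol(cm))])
  }
  total <- sum(cm)
  per_class <- purrr::map_dfr(rownames(cm), function(cls) {
    tp <- cm[cls, cls]
    fn <- sum(cm[cls, ]) - tp
    fp <- sum(cm[, cls]) - tp
    tn <- total - tp - fn - fp
    dplyr::bind_cols(tibble::tibble(class = cls), ovr_metrics(tp, tn, fp, fn))
  })
  list(accuracy = sum(diag(cm)) / total, per_class = per_class)
}

#' One-vs-rest ROC AUC per class
#'
#' For each emotion, the class's continuous score is swept against the
#' rest (trapezoid AUC via `pROC` with fixed direction, so
#' `AUC(-scores) = 1 - AUC(scores)`).
#'
#' @param scores `n x 3` score matrix (columns named by label).
#' @param y True labels.
#' @return Named numeric vector of per-class AUCs; `NA` for a class absent
#'   from `y` (undefined).
#' @export
roc_auc_ovr <- function(scores, y) {
  y <- as.character(y)
  if (length(unique(y)) < 2) {
    return(setNames(rep(NA_real_, length(EMOTION_LABELS)), EMOTION_LABELS))
  }
  vapply(EMOTION_LABELS, function(cls) {
    pos <- y == cls
    if (!any(pos) || all(pos)) return(NA_real_)
    s <- scores[, cls]
    if (!any(is.finite(s))) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(
      response = factor(pos, levels = c(FALSE, TRUE)),
      predictor = s, levels = c(FALSE, TRUE), direction = "<",
      quiet = TRUE)))
  }, 0)
}

new_eval_report <- function(scheme, folds, cm, scores, y) {
  met <- confusion_metrics(cm)
  structure(
    list(scheme = scheme,
         accuracy = mean(folds$accuracy),
         pooled_accuracy = met$accuracy,
         per_class = met$per_class,
         auc = roc_auc_ovr(scores, y),
         confusion = cm,
         folds = folds),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s | mean accuracy %.4f over %d folds\n",
              x$scheme, x$accuracy, nrow(x$folds)))
  cat("  per-class AUC:",
      paste(sprintf("%s=%.3f", names(x$auc), x$auc), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(scheme = x$scheme), x$per_class,
                   tibble::tibble(auc = unname(x$auc[x$per_class$class])))
}

#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, accuracy = x$accuracy,
                 pooled_accuracy = x$pooled_accuracy,
                 mean_auc = mean(x$auc, na.rm = TRUE),
                 n_folds = nrow(x$folds))
}

stratified_folds <- function(y, k, seed) {
  with_local_seed(seed, {
    fold <- integer(length(y))
    for (ix in split(seq_along(y), y)) {
      fold[sample(ix)] <- rep_len(seq_len(k), length(ix))
    }
    fold
  })
}

#' Stratified k-fold cross-validation
#'
#' Splits the dataset into `k` label-stratified folds; each fold serves once
#' as the test set while a model is trained on the rest. The reported
#' accuracy is the average of the fold accuracies; the confusion matrix and
#' ROC scores are pooled over folds.
#'
#' @param ds An `emotion_dataset`.
#' @param trainer Function `f(ds) -> model` with a [predict_emotion()]
#'   method (e.g. `train_svm_rbf`, or `\(d) train_net(d, spec)`).
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return An `eval_report`.
#' @export
crossval_5fold <- function(ds, trainer, k = 5, seed = 1L) {
  y <- ds$y
  if (min(table(y)) < k) {
    abort(sprintf("Need at least %d rows per class for %d-fold CV.", k, k))
  }
  fold <- stratified_folds(y, k, seed)
  cm <- matrix(0, 3, 3, dimnames = list(EMOTION_LABELS, EMOTION_LABELS))
  scores <- matrix(NA_real_, length(y), 3,
                   dimnames = list(NULL, EMOTION_LABELS))
  folds <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- fold != f
    model <- trainer(list(X = ds$X[tr, , drop = FALSE], y = y[tr]))
    pr <- predict_emotion(model, ds$X[!tr, , drop = FALSE])
    cm <<- cm + table(factor(y[!tr], levels = EMOTION_LABELS),
                      factor(pr$class, levels = EMOTION_LABELS))
    scores[!tr, ] <<- pr$scores
    tibble::tibble(fold = f, n_test = sum(!tr),
                   accuracy = mean(as.character(pr$class) ==
                                     as.character(y[!tr])))
  })
  new_eval_report("5fold", folds, cm, scores, y)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, a single pooled model is trained on all remaining
#' subjects and tested on the held-out subject's segments, measuring
#' subject-independent generalization.
#'
#' @param datasets List of per-subject `emotion_dataset`s (same measure and
#'   feature columns).
#' @param trainer As in [crossval_5fold()].
#' @return An `eval_report` with one fold row per held-out subject.
#' @export
loso <- function(datasets, trainer) {
  if (length(datasets) < 2) {
    abort("Leave-one-subject-out needs at least 2 subjects.")
  }
  subjects <- vapply(datasets, function(d) as.character(d$subject_id[1]), "")
  cm <- matrix(0, 3, 3, dimnames = list(EMOTION_LABELS, EMOTION_LABELS))
  all_scores <- list(); all_y <- list()
  folds <- purrr::map_dfr(seq_along(datasets), function(i) {
    train_X <- do.call(rbind, lapply(datasets[-i], `[[`, "X"))
    train_y <- factor(unlist(lapply(datasets[-i], function(d) as.character(d$y))),
                      levels = EMOTION_LABELS)
    model <- trainer(list(X = train_X, y = train_y))
    held <- datasets[[i]]
    pr <- predict_emotion(model, held$X)
    cm <<- cm + table(factor(held$y, levels = EMOTION_LABELS),
                      factor(pr$class, levels = EMOTION_LABELS))
    all_scores[[i]] <<- pr$scores
    all_y[[i]] <<- as.character(held$y)
    tibble::tibble(fold = i, subject_id = subjects[i], n_test = nrow(held$X),
                   accuracy = mean(as.character(pr$class) ==
                                     as.character(held$y)))
  })
  new_eval_report("loso", folds, cm,
                  do.call(rbind, all_scores),
                  unlist(all_y))
}
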