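toy_tables <- function() {
  rec <- small_strong_session()
  extract_features(segment(rec), "SAE")
}

test_that("dataset assembly applies electrode selections and shuffles reproducibly", {
  ft <- toy_tables()
  sel <- select_electrodes(ft)
  fake_sel <- tibble::tibble(
    channel = c("AF3", "AF4", "FT7", "FT8", "T7", "T8", "TP7", "TP8"),
    verdict = c("reject", "adopt", "reject", "adopt",
                "reject", "adopt", "reject", "adopt"))
  ds4 <- assemble_dataset(ft, fake_sel, seed = 1)
  expect_equal(colnames(ds4$X), c("AF4", "FT8", "T8", "TP8"))
  ds8 <- assemble_dataset(ft, NULL, seed = 1)
  expect_equal(ncol(ds8$X), 8)
  expect_identical(assemble_dataset(ft, NULL, seed = 1)$X, ds8$X)
  none <- tibble::tibble(channel = "T8", verdict = "reject")
  expect_error(assemble_dataset(ft, none), "adopted no electrodes")
})

test_that("confusion metrics match the one-vs-rest worked arithmetic", {
  perfect <- diag(c(10, 20, 30))
  met <- confusion_metrics(perfect)
  expect_equal(met$accuracy, 1)
  expect_true(all(met$per_class$sensitivity == 1))
  expect_true(all(met$per_class$specificity == 1))

  # TP=50, FN=10, FP=5, TN=35 -> accuracy 0.85, sens 0.8333, spec 0.875
  m <- ovr_metrics(tp = 50, tn = 35, fp = 5, fn = 10)
  expect_equal(m$accuracy, 0.85)
  expect_equal(round(m$sensitivity, 4), 0.8333)
  expect_equal(m$specificity, 0.875)

  all_neg <- matrix(0, 3, 3,
                    dimnames = list(c("negative", "neutral", "positive"),
                                    c("negative", "neutral", "positive")))
  all_neg[, "negative"] <- c(10, 10, 10)
  met2 <- confusion_metrics(all_neg)
  expect_equal(met2$per_class$sensitivity,
               c(1, 0, 0))
  expect_error(confusion_metrics(matrix(0, 3, 3)), "empty")
})

test_that("confusion metrics agree with naive element counting on random matrices", {
  withr::with_seed(40, {
    for (i in 1:20) {
      cm <- matrix(rpois(9, 20), 3,
                   dimnames = list(c("negative", "neutral", "positive"),
                                   c("negative", "neutral", "positive")))
      met <- confusion_metrics(cm)
      expect_equal(met$accuracy, sum(diag(cm)) / sum(cm))
      for (k in 1:3) {
        cls <- rownames(cm)[k]
        tp <- cm[k, k]; fn <- sum(cm[k, -k]); fp <- sum(cm[-k, k])
        tn <- sum(cm[-k, -k])
        row <- met$per_class[met$per_class$class == cls, ]
        expect_equal(row$sensitivity, tp / (tp + fn))
        expect_equal(row$specificity, tn / (tn + fp))
      }
    }
  })
})

test_that("one-vs-rest AUC behaves at the extremes and obeys score symmetry", {
  y <- factor(rep(c("negative", "neutral", "positive"), each = 20))
  onehot <- matrix(0, 60, 3,
                   dimnames = list(NULL, c("negative", "neutral", "positive")))
  onehot[cbind(1:60, as.integer(y))] <- 1
  expect_equal(unname(roc_auc_ovr(onehot, y)), c(1, 1, 1))

  withr::with_seed(41, {
    y2 <- factor(sample(c("negative", "neutral", "positive"), 2000,
                        replace = TRUE))
    sc <- matrix(rnorm(6000), 2000,
                 dimnames = list(NULL, c("negative", "neutral", "positive")))
    aucs <- roc_auc_ovr(sc, y2)
    expect_true(all(abs(aucs - 0.5) < 0.05))
    expect_equal(unname(roc_auc_ovr(sc, y2) + roc_auc_ovr(-sc, y2)),
                 rep(1, 3), tolerance = 1e-10)
  })
  expect_true(all(is.na(roc_auc_ovr(onehot, rep("neutral", 60)))))

  # Mann-Whitney identity oracle: AUC = U / (n_pos * n_neg)
  withr::with_seed(43, {
    y3 <- rep(c("negative", "neutral"), c(30, 50))
    s <- rnorm(80)
    sc3 <- matrix(0, 80, 3,
                  dimnames = list(NULL, c("negative", "neutral", "positive")))
    sc3[, "negative"] <- s
    u <- sum(rank(s)[y3 == "negative"]) - 30 * 31 / 2
    expect_equal(unname(roc_auc_ovr(sc3, y3)["negative"]), u / (30 * 50),
                 tolerance = 1e-10)
  })
})

test_that("stratified folds are disjoint, exhaustive and balanced", {
  ft <- toy_tables()
  ds <- assemble_dataset(ft, NULL, seed = 2)
  fold <- eegentropy:::stratified_folds(ds$y, 5, seed = 3)
  expect_setequal(unique(fold), 1:5)
  expect_equal(length(fold), length(ds$y))
  per_fold_class <- table(fold, ds$y)
  expect_lte(max(per_fold_class) - min(per_fold_class), 1)
  expect_error(crossval_5fold(list(X = matrix(rnorm(12), 6),
                                   y = factor(rep(c("negative", "neutral",
                                                    "positive"), 2))),
                              train_svm_rbf),
               "at least 5")
})

test_that("5-fold evaluation recovers a separable effect end to end", {
  ft <- toy_tables()
  ds <- assemble_dataset(ft, NULL, seed = 2)
  rep5 <- crossval_5fold(ds, train_svm_rbf, seed = 2)
  expect_s3_class(rep5, "eval_report")
  expect_gte(rep5$accuracy, 0.9)
  expect_equal(sum(rep5$confusion), nrow(ds$X))
  expect_equal(nrow(rep5$folds), 5)
  expect_equal(rep5$pooled_accuracy,
               sum(diag(rep5$confusion)) / sum(rep5$confusion))
  td <- tidy(rep5)
  expect_equal(nrow(td), 3)
  gl <- glance(rep5)
  expect_equal(gl$accuracy, rep5$accuracy)
})

test_that("leave-one-subject-out trains pooled models and needs 2+ subjects", {
  cfg <- synth_config(n_subjects = 2, trial_duration = 8,
                      n_trials_per_class = 5,
                      class_complexity = strong_class_effect(), seed = 44)
  dss <- lapply(c("S01", "S02"), function(sid) {
    assemble_dataset(extract_features(segment(bandpass(
      generate_session(cfg, sid))), "SAE"), seed = 1)
  })
  repl <- loso(dss, train_svm_rbf)
  expect_equal(repl$scheme, "loso")
  expect_equal(nrow(repl$folds), 2)
  expect_gt(repl$accuracy, 0.5)  # shared class effect generalizes
  expect_error(loso(dss[1], train_svm_rbf), "at least 2")
})
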