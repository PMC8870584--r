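test_that("subject folds partition, balance and reproduce", {
  subj <- data.frame(
    subject_id = c(sprintf("hc%02d", 1:16), rep(sprintf("pd%02d", 1:15), 2)),
    class_label = c(rep(0L, 16L), rep(1L, 15L), rep(2L, 15L)))
  f <- make_subject_folds(subj, k = 4L, seed = 1)
  expect_equal(nrow(f), 31L)
  expect_true(all(table(f$subject_id) == 1L))       # partition
  expect_true(all(table(f$fold) %in% c(7L, 8L)))    # pigeonhole on 31/4
  # class balance: HC spread 4 per fold
  hc <- f[grepl("^hc", f$subject_id), ]
  expect_true(all(table(hc$fold) == 4L))
  # determinism
  f2 <- make_subject_folds(subj, k = 4L, seed = 1)
  expect_identical(f, f2)
  expect_false(identical(f$fold, make_subject_folds(subj, 4L, seed = 2)$fold))
  # leave-one-subject-out
  loso <- make_subject_folds(subj, k = 31L, seed = 1)
  expect_equal(sort(unique(loso$fold)), 1:31)
  expect_error(make_subject_folds(subj, k = 32L, seed = 1), "number of subjects")
})

test_that("confusion matrices count correctly, including fixtures and edge cases", {
  cm <- confusion_matrix(rep(1L, 10L), rep(1L, 10L), 2L)
  expect_equal(unname(cm), matrix(c(0L, 0L, 0L, 10L), 2))

  empty <- confusion_matrix(integer(), integer(), 3L)
  expect_true(all(empty == 0L))
  expect_equal(dim(empty), c(3L, 3L))

  y_t <- c(0L, 0L, 1L, 2L, 2L, 2L)
  y_p <- c(0L, 1L, 1L, 2L, 0L, 2L)
  cm3 <- confusion_matrix(y_t, y_p, 3L)
  expect_equal(unname(cm3),
               matrix(c(1L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 2L), 3L))
  expect_equal(sum(cm3), 6L)

  ref <- reference_confusions()
  expect_equal(unname(ref$CP5), matrix(c(3077L, 2L, 3L, 2984L), 2))
  expect_error(confusion_matrix(c(0L, 3L), c(0L, 0L), 2L), "0..1")
  expect_error(confusion_matrix(0L, c(0L, 1L), 2L), "lengths")
})

test_that("accuracy/sensitivity/specificity equal exhaustive direct counting", {
  # every 2x2 confusion matrix with entries 0..20, against label-vector
  # reconstruction and explicit counting
  grid <- expand.grid(tn = 0:20, fp = 0:20, fn = 0:20, tp = 0:20)
  grid <- grid[rowSums(grid) > 0, ]
  bad <- 0L
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    y_true <- rep(c(0L, 0L, 1L, 1L), times = c(g$tn, g$fp, g$fn, g$tp))
    y_pred <- rep(c(0L, 1L, 0L, 1L), times = c(g$tn, g$fp, g$fn, g$tp))
    m <- classification_metrics(confusion_matrix(y_true, y_pred, 2L))
    sens <- if (g$fn + g$tp == 0) NA_real_
            else sum(y_true == 1L & y_pred == 1L) / sum(y_true == 1L)
    spec <- if (g$tn + g$fp == 0) NA_real_
            else sum(y_true == 0L & y_pred == 0L) / sum(y_true == 0L)
    if (!identical(m$accuracy, mean(y_true == y_pred)) ||
        !identical(m$sensitivity, sens) ||
        !identical(m$specificity, spec)) {
      bad <- bad + 1L
      if (bad == 1L)
        fail(sprintf("mismatch at tn=%d fp=%d fn=%d tp=%d",
                     g$tn, g$fp, g$fn, g$tp))
    }
  }
  expect_identical(bad, 0L)
})

test_that("three-class metrics are one-vs-rest with macro averages", {
  cm <- matrix(c(8L, 1L, 0L,
                 2L, 7L, 1L,
                 0L, 2L, 9L), 3L, byrow = TRUE)
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 24 / 30)
  expect_equal(m$per_class$sensitivity, c(8 / 9, 7 / 10, 9 / 11))
  # specificity class 0: 21 true negatives minus the 2 predicted as class 0
  expect_equal(m$per_class$specificity[1L], 19 / 21)
  expect_equal(m$sensitivity, mean(m$per_class$sensitivity))

  perfect <- diag(c(5L, 6L, 7L))
  mp <- classification_metrics(perfect)
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$sensitivity, 1)
  expect_equal(mp$specificity, 1)

  no_pos <- matrix(c(4L, 1L, 0L, 0L), 2L, byrow = TRUE)
  expect_true(is.na(classification_metrics(no_pos)$sensitivity))
})

test_that("weighted kappa: perfect, chance, fixtures and brute-force agreement", {
  expect_equal(quadratic_weighted_kappa(diag(c(10L, 20L))), 1)
  expect_equal(quadratic_weighted_kappa(diag(c(3L, 4L, 5L))), 1)

  # independence with matched marginals: c equals the marginal product
  indep <- matrix(c(100L, 100L, 100L, 100L), 2L)
  expect_equal(quadratic_weighted_kappa(indep), 0)
  indep3 <- outer(c(2L, 3L, 5L), c(4L, 2L, 4L))
  expect_equal(quadratic_weighted_kappa(indep3), 0)

  for (cm in reference_confusions()) {
    expect_equal(quadratic_weighted_kappa(cm), brute_kappa(cm),
                 tolerance = 1e-12)
    expect_equal(quadratic_weighted_kappa(cm, "linear"),
                 brute_kappa(cm, quadratic = FALSE), tolerance = 1e-12)
  }
  cm3 <- matrix(c(50L, 3L, 1L, 4L, 40L, 2L, 0L, 5L, 45L), 3L, byrow = TRUE)
  expect_equal(quadratic_weighted_kappa(cm3), brute_kappa(cm3),
               tolerance = 1e-12)

  # moving diagonal mass off-diagonal lowers K
  base <- matrix(c(40L, 10L, 10L, 40L), 2L)
  worse <- matrix(c(35L, 15L, 10L, 40L), 2L)
  expect_lt(quadratic_weighted_kappa(worse), quadratic_weighted_kappa(base))

  degenerate <- matrix(c(7L, 0L, 0L, 0L), 2L)
  k <- quadratic_weighted_kappa(degenerate)
  expect_true(is.na(k))
  expect_match(attr(k, "reason"), "degenerate")
})

test_that("AUC equals the pairwise rank statistic, with tie and edge conventions", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)

  for (rep_i in 1:5) {
    sc <- withr::with_seed(100 + rep_i,
                           sample(seq(0, 1, by = 0.1), 40, replace = TRUE))
    lab <- withr::with_seed(200 + rep_i, rbinom(40, 1, 0.4))
    if (length(unique(lab)) < 2L) next
    expect_equal(roc_auc(sc, lab)$auc, rank_auc(sc, lab), tolerance = 1e-12)
  }

  single <- roc_auc(runif(5), rep(1, 5))
  expect_true(is.na(single$auc))
  expect_match(single$reason, "single class")
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  sc <- withr::with_seed(42, runif(60))
  lab <- withr::with_seed(43, rbinom(60, 1, 0.5))
  ours <- roc_auc(sc, lab)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("cross-validation: subject-wise, fresh models, complete reports", {
  ts <- make_band_tileset(n_subjects_per_class = 4L, tiles_per_subject = 6L,
                          size = 16L, classes = c(0L, 1L), seed = 31)
  cv <- cross_validate(ts, "hc_vs_off", k = 2L, spec = smoke_spec(),
                       config = train_config(batch_size = 8L,
                                             learning_rate = 0.1,
                                             epochs = 10L, seed = 1),
                       seed = 7)
  expect_s3_class(cv, "pw_cv")
  expect_equal(nrow(cv$predictions), length(ts))
  expect_true(audit_subject_folds(cv))
  # validation subjects disjoint from training subjects in every fold
  for (f in seq_len(2L)) {
    va_subj <- unique(cv$predictions$subject_id[cv$predictions$fold == f])
    tr_subj <- setdiff(unique(ts$info$subject_id), va_subj)
    expect_length(intersect(va_subj, tr_subj), 0L)
  }
  expect_named(cv$mean_folds,
               c("accuracy", "sensitivity", "specificity", "kappa", "auc"))
  expect_equal(nrow(cv$per_fold), 2L)
  expect_equal(sum(cv$pooled$confusion), length(ts))
  # the band pattern is easy: the classifier should beat chance comfortably
  expect_gt(cv$pooled$accuracy, 0.8)

  expect_error(cross_validate(ts, "three_class", k = 2L), "needs classes")
  expect_error(cross_validate(ts, "hc_vs_off", k = 50L, spec = smoke_spec()),
               "number of subjects")
})

test_that("three-class cross-validation reports per-class views", {
  ts <- make_band_tileset(n_subjects_per_class = 3L, tiles_per_subject = 4L,
                          size = 16L, classes = 0:2, seed = 33)
  cv <- cross_validate(ts, "three_class", k = 2L,
                       spec = smoke_spec(n_classes = 3L),
                       config = train_config(batch_size = 8L,
                                             learning_rate = 0.1,
                                             epochs = 8L, seed = 1),
                       seed = 9)
  expect_equal(nrow(cv$pooled$per_class), 3L)
  expect_true(all(c("sensitivity", "specificity") %in%
                    names(cv$pooled$per_class)))
  expect_true(is.finite(cv$pooled_auc))
  expect_true(all(sprintf("p%d", 0:2) %in% names(cv$predictions)))
})

test_that("subject-level label permutation keeps tiles together", {
  ts <- make_band_tileset(n_subjects_per_class = 4L, tiles_per_subject = 3L,
                          seed = 35)
  pt <- permute_subject_labels(ts, seed = 1)
  lab <- tapply(pt$info$class_label, pt$info$subject_id, unique)
  expect_true(all(lengths(lab) == 1L))  # one label per subject
  expect_equal(sort(as.integer(unlist(lab))),
               sort(as.integer(unlist(
                 tapply(ts$info$class_label, ts$info$subject_id, unique)))))
})
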