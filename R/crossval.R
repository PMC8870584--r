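experiment_classes <- function(experiment) {
  switch(experiment,
         hc_vs_off = c(0L, 1L),
         off_vs_on = c(1L, 2L),
         three_class = 0:2,
         stop_invalid("unknown experiment '%s'", experiment))
}

#' Subject-wise cross-validated evaluation of the tile classifier
#'
#' Runs one of the three screening experiments: `"hc_vs_off"` (healthy
#' controls versus PD off medication), `"off_vs_on"` (PD off versus on
#' medication) or `"three_class"`. Tiles are restricted to the experiment's
#' classes and relabelled `0:(L-1)` in that order (the second class is the
#' positive one in the binary experiments). For every fold a freshly
#' initialized model is trained on the training subjects' tiles and
#' evaluated on the held-out subjects' tiles; no subject appears on both
#' sides of a fold. Reports per-fold metrics, their cross-fold means, and
#' metrics of the pooled confusion matrix, plus the full per-tile
#' prediction log.
#'
#' @param tiles A `pw_tileset` containing the experiment's classes.
#' @param experiment One of `"hc_vs_off"`, `"off_vs_on"`, `"three_class"`.
#' @param k Number of folds (default 4; the study also uses 10).
#' @param spec A `pw_cnn_spec`; defaults to the full 20-layer architecture with the
#'   experiment's class count.
#' @param config A [train_config()].
#' @param seed Seed controlling fold assignment and per-fold model
#'   initialization.
#' @param threshold Binary decision threshold (see [predict.pw_cnn()]).
#' @param verbose Print per-fold progress.
#' @return Object of class `pw_cv`; see Details.
#' @export
cross_validate <- function(tiles,
                           experiment = c("hc_vs_off", "off_vs_on",
                                          "three_class"),
                           k = 4L, spec = NULL, config = train_config(),
                           seed = 1L, threshold = 0.5, verbose = FALSE) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(tiles, "pw_tileset"))
  classes <- experiment_classes(experiment)
  present <- unique(tiles$info$class_label)
  if (!all(classes %in% present))
    stop_invalid("experiment '%s' needs classes %s; tile set has %s",
                 experiment, paste(classes, collapse = ","),
                 paste(sort(present), collapse = ","))
  ts <- tiles[tiles$info$class_label %in% classes]
  y <- match(ts$info$class_label, classes) - 1L
  L <- length(classes)
  if (is.null(spec)) spec <- cnn_spec("deep", n_classes = L)
  if (spec$n_classes != L)
    stop_invalid("spec has %d classes but experiment '%s' needs %d",
                 spec$n_classes, experiment, L)
  folds <- make_subject_folds(
    data.frame(subject_id = ts$info$subject_id, class_label = y), k,
    seed = seed)
  fold_of <- folds$fold[match(ts$info$subject_id, folds$subject_id)]
  per_fold <- NULL
  predictions <- NULL
  for (f in seq_len(k)) {
    va <- which(fold_of == f)
    tr <- which(fold_of != f)
    stopifnot(length(intersect(ts$info$subject_id[tr],
                               ts$info$subject_id[va])) == 0L)
    if (verbose)
      message(sprintf("fold %d/%d: %d train / %d validation tiles",
                      f, k, length(tr), length(va)))
    model <- build_cnn(spec, seed = seed + f)
    cfg <- config
    cfg$seed <- config$seed + f
    model <- train_cnn(model, ts$tiles[, , tr, drop = FALSE], y[tr],
                       config = cfg)
    probs <- forward_cnn(model, ts$tiles[, , va, drop = FALSE])
    pred <- decide_labels(probs, threshold)
    sc <- as.data.frame(probs)
    names(sc) <- sprintf("p%d", seq_len(L) - 1L)
    predictions <- rbind(predictions, cbind(
      data.frame(fold = f,
                 subject_id = ts$info$subject_id[va],
                 channel = ts$info$channel[va],
                 tile_index = ts$info$tile_index[va],
                 true = y[va], predicted = pred), sc))
    cm <- confusion_matrix(y[va], pred, L)
    m <- classification_metrics(cm)
    auc <- if (L == 2L) roc_auc(probs[, 2L], y[va])$auc
           else macro_ovr_auc(probs, y[va])
    per_fold <- rbind(per_fold, data.frame(
      fold = f, n = m$n, accuracy = m$accuracy,
      sensitivity = m$sensitivity, specificity = m$specificity,
      kappa = as.numeric(quadratic_weighted_kappa(cm)), auc = auc))
  }
  pooled_cm <- confusion_matrix(predictions$true, predictions$predicted, L)
  pooled <- classification_metrics(pooled_cm)
  pooled_auc <- if (L == 2L) roc_auc(predictions$p1, predictions$true)$auc
                else macro_ovr_auc(as.matrix(
                  predictions[sprintf("p%d", seq_len(L) - 1L)]),
                  predictions$true)
  mean_folds <- colMeans(per_fold[c("accuracy", "sensitivity",
                                    "specificity", "kappa", "auc")])
  structure(list(experiment = experiment, k = k, classes = classes,
                 per_fold = per_fold, mean_folds = mean_folds,
                 pooled = pooled,
                 pooled_kappa = as.numeric(quadratic_weighted_kappa(pooled_cm)),
                 pooled_auc = pooled_auc,
                 predictions = predictions, folds = folds,
                 threshold = threshold, seed = seed),
            class = "pw_cv")
}

#' @export
print.pw_cv <- function(x, ...) {
  cat(sprintf("<pw_cv> %s, %d-fold subject-wise (%d tiles, %d subjects)\n",
              x$experiment, x$k, nrow(x$predictions),
              nrow(x$folds)))
  cat(sprintf("  mean of folds: accuracy %.4f  sensitivity %.4f  specificity %.4f  kappa %.3f  AUC %.4f\n",
              x$mean_folds["accuracy"], x$mean_folds["sensitivity"],
              x$mean_folds["specificity"], x$mean_folds["kappa"],
              x$mean_folds["auc"]))
  cat(sprintf("  pooled:        accuracy %.4f  sensitivity %.4f  specificity %.4f  kappa %.3f  AUC %.4f\n",
              x$pooled$accuracy, x$pooled$sensitivity, x$pooled$specificity,
              x$pooled_kappa, x$pooled_auc))
  invisible(x)
}

#' Audit a cross-validation run for subject leakage
#'
#' Re-derives fold membership from the per-tile prediction log and asserts
#' that every subject was evaluated in exactly one fold.
#'
#' @param cv A `pw_cv`.
#' @return `TRUE` invisibly; stops on any leakage.
#' @export
audit_subject_folds <- function(cv) {
  stopifnot(inherits(cv, "pw_cv"))
  per_subject <- tapply(cv$predictions$fold, cv$predictions$subject_id,
                        function(f) length(unique(f)))
  if (any(per_subject != 1L))
    stop_invalid("subject(s) evaluated in more than one fold: %s",
                 paste(names(per_subject)[per_subject != 1L], collapse = ", "))
  invisible(TRUE)
}

#' Permute class labels across subjects
#'
#' Reassigns the subject-level class labels by a seeded permutation while
#' keeping each subject's tiles together, for permutation-null control
#' experiments. Requires each subject to carry a single class.
#'
#' @param tiles A `pw_tileset`.
#' @param seed Permutation seed.
#' @return A `pw_tileset` with permuted `class_label`s.
#' @export
permute_subject_labels <- function(tiles, seed = 1L) {
  stopifnot(inherits(tiles, "pw_tileset"))
  lab <- tapply(tiles$info$class_label, tiles$info$subject_id,
                function(z) unique(z))
  if (any(vapply(lab, length, integer(1)) != 1L))
    stop_invalid("each subject must carry a single class label")
  ids <- names(lab)
  newlab <- with_seed(seed, sample(unlist(lab)))
  tiles$info$class_label <-
    newlab[match(tiles$info$subject_id, ids)]
  tiles
}

#' Subject-level accuracy summary of a cross-validation run
#'
#' Pools the prediction log by subject and reports each subject's tile-level
#' accuracy plus the cluster-aware standard error of the overall accuracy
#' (tiles within a subject are strongly correlated, so the effective sample
#' size is the number of subjects).
#'
#' @param cv A `pw_cv`.
#' @return List with `per_subject` (data frame) and `se` (standard error of
#'   the mean subject accuracy).
#' @export
subject_accuracy <- function(cv) {
  stopifnot(inherits(cv, "pw_cv"))
  acc <- tapply(cv$predictions$true == cv$predictions$predicted,
                cv$predictions$subject_id, mean)
  per_subject <- data.frame(subject_id = names(acc),
                            accuracy = as.numeric(acc))
  list(per_subject = per_subject,
       mean = mean(per_subject$accuracy),
       se = stats::sd(per_subject$accuracy) / sqrt(nrow(per_subject)))
}
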