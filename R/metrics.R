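#' Subject-wise fold assignment
#'
#' Assigns whole subjects to folds so that no subject contributes tiles to
#' both the training and validation side of any fold. Subjects are grouped
#' by the set of classes they carry (PD subjects carry both an OFF and an ON
#' recording), shuffled under the seed, and dealt round-robin within each
#' group so folds stay approximately class-balanced.
#'
#' @param subjects Data frame with columns `subject_id` and `class_label`
#'   (repeated rows per subject are fine, e.g. one per tile).
#' @param k Number of folds (`2 <= k <=` number of subjects;
#'   `k = n` gives leave-one-subject-out).
#' @param seed Shuffling seed.
#' @return Object of class `pw_folds`: data frame `subject_id`, `stratum`,
#'   `fold`, with attributes `k` and `seed`.
#' @export
make_subject_folds <- function(subjects, k, seed = 1L) {
  if (!all(c("subject_id", "class_label") %in% names(subjects)))
    stop_invalid("subjects needs columns subject_id and class_label")
  strata <- tapply(subjects$class_label, subjects$subject_id,
                   function(z) paste(sort(unique(z)), collapse = "+"))
  ids <- names(strata)
  if (k < 2L || k > length(ids))
    stop_invalid("k must lie in 2..%d (number of subjects); got %s",
                 length(ids), k)
  out <- NULL
  with_seed(seed, {
    counter <- 0L
    for (s in sort(unique(strata))) {
      grp <- sample(ids[strata == s])
      fold <- ((counter + seq_along(grp) - 1L) %% k) + 1L
      counter <- counter + length(grp)
      out <- rbind(out, data.frame(subject_id = grp, stratum = s,
                                   fold = fold))
    }
  })
  out <- out[order(out$subject_id), ]
  rownames(out) <- NULL
  attr(out, "k") <- as.integer(k)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("pw_folds", "data.frame")
  out
}

#' Confusion matrix from label vectors
#'
#' @param y_true,y_pred Integer labels in `0:(n_classes-1)`.
#' @param n_classes Number of classes L (2 or 3 in the screening
#'   experiments).
#' @return L x L integer matrix, rows = ground truth, columns = prediction,
#'   `counts[i, j]` = number of tiles with true class i predicted as j.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred))
    stop_invalid("y_true and y_pred lengths differ")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  L <- as.integer(n_classes)
  if (length(y_true) && (any(y_true < 0L | y_true >= L) ||
                         any(y_pred < 0L | y_pred >= L)))
    stop_invalid("labels must lie in 0..%d", L - 1L)
  counts <- tabulate(y_true * L + y_pred + 1L, nbins = L * L)
  matrix(counts, L, L, byrow = TRUE,
         dimnames = list(truth = 0:(L - 1L), prediction = 0:(L - 1L)))
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' Binary case (labels 0 = negative/HC, 1 = positive/PD):
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP). Three-class models report per-class
#' one-vs-rest sensitivity/specificity and their macro averages. A zero
#' denominator (no positives or no negatives) yields `NA`, not 0.
#'
#' @param cm Square confusion matrix (rows truth, columns prediction).
#' @return Object of class `pw_metrics`: `accuracy`, `sensitivity`,
#'   `specificity`, `misclassified`, `n`, `per_class` (for L > 2),
#'   `confusion`.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(cm)
  L <- nrow(cm)
  total <- sum(cm)
  if (total == 0) stop_invalid("empty confusion matrix")
  acc <- sum(diag(cm)) / total
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  if (L == 2L) {
    tn <- cm[1L, 1L]; fp <- cm[1L, 2L]; fn <- cm[2L, 1L]; tp <- cm[2L, 2L]
    sens <- safe_div(tp, tp + fn)
    spec <- safe_div(tn, tn + fp)
    per_class <- NULL
  } else {
    rs <- rowSums(cm); cs <- colSums(cm)
    sens_c <- vapply(seq_len(L), function(i) safe_div(cm[i, i], rs[i]),
                     numeric(1))
    spec_c <- vapply(seq_len(L), function(i)
      safe_div(total - rs[i] - cs[i] + cm[i, i], total - rs[i]), numeric(1))
    per_class <- data.frame(class = 0:(L - 1L), sensitivity = sens_c,
                            specificity = spec_c)
    sens <- mean(sens_c); spec <- mean(spec_c)
  }
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 misclassified = total - sum(diag(cm)), n = total,
                 per_class = per_class, confusion = cm),
            class = "pw_metrics")
}

#' @export
print.pw_metrics <- function(x, ...) {
  cat(sprintf("<pw_metrics> n=%d  accuracy %.4f  sensitivity %.4f  specificity %.4f  (%d misclassified)\n",
              x$n, x$accuracy, x$sensitivity, x$specificity,
              x$misclassified))
  invisible(x)
}

#' Weighted Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `K = 1 - sum(w * c) / sum(w * p)` where `c` is
#' the observed confusion matrix normalized to proportions, `p` is the outer
#' product of its row and column marginal distributions (the agreement
#' expected by chance), and the disagreement weights are
#' `w(i, j) = (i - j)^2` (quadratic, the default) or `|i - j|` (linear).
#' K = 1 for perfect agreement; K = 0 when observed agreement equals
#' chance.
#'
#' @param cm Square confusion matrix.
#' @param weighting `"quadratic"` (default) or `"linear"`.
#' @return Kappa score (<= 1), or `NA` with a `reason` attribute when all
#'   mass sits in one cell so the chance disagreement is zero.
#' @export
quadratic_weighted_kappa <- function(cm, weighting = c("quadratic", "linear")) {
  weighting <- match.arg(weighting)
  cm <- as.matrix(cm)
  L <- nrow(cm)
  total <- sum(cm)
  if (total == 0) stop_invalid("empty confusion matrix")
  cn <- cm / total
  p <- outer(rowSums(cn), colSums(cn))
  idx <- 0:(L - 1L)
  w <- outer(idx, idx, function(i, j)
    if (weighting == "quadratic") (i - j)^2 else abs(i - j))
  denom <- sum(w * p)
  if (denom == 0)
    return(structure(NA_real_,
                     reason = "degenerate marginals: all mass in one class"))
  1 - sum(w * cn) / denom
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores, records the
#' true/false positive rates, and integrates by the trapezoidal rule. With
#' ties handled by the trapezoid this equals the rank statistic: the
#' probability that a random positive outscores a random negative, ties
#' counted one half.
#'
#' @param scores Positive-class probabilities (or any monotone score).
#' @param labels Binary ground truth; `positive_class` marks the positives.
#' @param positive_class Label treated as positive (default 1).
#' @return Object of class `pw_roc`: `curve` (threshold, fpr, tpr), `auc`,
#'   `n_pos`, `n_neg`. With single-class labels, `auc` is `NA` with a
#'   `reason` field.
#' @export
roc_auc <- function(scores, labels, positive_class = 1L) {
  pos <- labels == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    return(structure(list(curve = NULL, auc = NA_real_,
                          reason = "labels contain a single class",
                          n_pos = n_pos, n_neg = n_neg), class = "pw_roc"))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  tps <- cumsum(y); fps <- cumsum(!y)
  last <- c(s[-1L] != s[-length(s)], TRUE)  # last index of each tie group
  tpr <- c(0, tps[last] / n_pos)
  fpr <- c(0, fps[last] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(curve = data.frame(threshold = c(Inf, s[last]),
                                    fpr = fpr, tpr = tpr),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "pw_roc")
}

#' @export
print.pw_roc <- function(x, ...) {
  if (is.na(x$auc)) cat("<pw_roc> undefined:", x$reason, "\n")
  else cat(sprintf("<pw_roc> AUC %.4f (%d positives, %d negatives)\n",
                   x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

# macro one-vs-rest AUC for multi-class probability matrices
macro_ovr_auc <- function(probs, y) {
  aucs <- vapply(seq_len(ncol(probs)), function(c1)
    roc_auc(probs[, c1], as.integer(y == c1 - 1L))$auc, numeric(1))
  mean(aucs)
}
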