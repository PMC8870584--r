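#' Bundled reference confusion matrices
#'
#' Published 4-fold cross-validation confusion matrices of a CWT-CNN
#' resting-state-EEG Parkinson's screen (HC versus PD off medication) at
#' three analysis channels, bundled as a worked example for the metric
#' functions: the CP5 matrix reproduces the reported 99.9% accuracy,
#' sensitivity and specificity, and the Fp1 matrix the 57 misclassified
#' tiles.
#'
#' @return Named list of 2x2 integer matrices (rows truth HC/PD, columns
#'   prediction HC/PD) for channels Fp1, CP5 and Fp2.
#' @export
#' @examples
#' cm <- reference_confusions()$CP5
#' classification_metrics(cm)
reference_confusions <- function() {
  path <- system.file("extdata", "reference_confusion.csv",
                      package = "parkwave", mustWork = TRUE)
  df <- utils::read.csv(path)
  out <- list()
  for (ch in unique(df$channel)) {
    sub <- df[df$channel == ch, ]
    m <- as.matrix(sub[c("pred_hc", "pred_pd")])
    dimnames(m) <- list(truth = c("0", "1"), prediction = c("0", "1"))
    out[[ch]] <- m
  }
  out
}
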