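# Independent oracles kept deliberately separate from the implementation.

# Direct O(n * K) time-domain Morlet correlation (same truncated kernel as
# the analysis wavelet, summed explicitly) -- oracle for the FFT-based CWT.
direct_morlet_cwt <- function(x, scales, omega0 = 6, support_sigmas = 4) {
  n <- length(x)
  out <- matrix(0, length(scales), n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    K <- ceiling(support_sigmas * s)
    k <- (-K):K
    u <- k / s
    h <- pi^(-0.25) * exp(-1i * omega0 * u - u^2 / 2) / sqrt(s)
    for (tau in seq_len(n)) {
      idx <- tau + k
      ok <- idx >= 1 & idx <= n
      out[si, tau] <- Mod(sum(x[idx[ok]] * h[ok]))
    }
  }
  out
}

# O(n^2) pairwise rank statistic: P(score_pos > score_neg) + 0.5 P(tie)
rank_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# brute-force weighted kappa by explicit double summation
brute_kappa <- function(cm, quadratic = TRUE) {
  L <- nrow(cm)
  total <- sum(cm)
  cn <- cm / total
  r <- rowSums(cn); q <- colSums(cn)
  num <- 0; den <- 0
  for (i in 1:L) for (j in 1:L) {
    w <- if (quadratic) (i - j)^2 else abs(i - j)
    num <- num + w * cn[i, j]
    den <- den + w * r[i] * q[j]
  }
  unname(1 - num / den)
}

# quick synthetic tile set: class-dependent horizontal band intensity over
# noise, mimicking the scalogram geometry without the CWT cost
make_band_tileset <- function(n_subjects_per_class = 4L, tiles_per_subject = 6L,
                              size = 32L, classes = c(0L, 1L), seed = 1L,
                              contrast = 0.5) {
  withr::with_seed(seed, {
    n <- n_subjects_per_class * tiles_per_subject * length(classes)
    tiles <- array(0, c(size, size, n))
    info <- NULL
    i <- 0L
    for (cl in classes) {
      for (s in seq_len(n_subjects_per_class)) {
        sid <- sprintf("c%d_s%02d", cl, s)
        for (t in seq_len(tiles_per_subject)) {
          i <- i + 1L
          base <- matrix(runif(size * size, 0, 0.4), size)
          rows <- seq_len(size %/% 4L) + (match(cl, classes) - 1L) * (size %/% 4L)
          base[rows, ] <- pmin(base[rows, ] + contrast, 1)
          tiles[, , i] <- base
          info <- rbind(info, data.frame(subject_id = sid, channel = "Fp1",
                                         class_label = cl, tile_index = t))
        }
      }
    }
    tileset(tiles, info)
  })
}

# tiny architecture for fast gradient checks and Grad-CAM oracles
tiny_spec <- function(n_classes = 2L) {
  cnn_spec(n_classes = n_classes, input_size = 16L,
           blocks = list(cnn_block(1L, 3L, 2L, 2L)), head = 4L)
}

# slightly wider variant with enough capacity for quick end-to-end smoke runs
smoke_spec <- function(n_classes = 2L) {
  cnn_spec(n_classes = n_classes, input_size = 16L,
           blocks = list(cnn_block(1L, 3L, 4L, 2L)), head = 8L)
}

# planted-feature experiment for Grad-CAM localization: a 32x32 block at
# rows/cols 33:64 (1/16 of the tile area) on a black background, dim in
# class 0 and bright in class 1. The intensity ranges overlap slightly so
# the regularized optimum stays interior (a saturated, perfectly separated
# toy leaves the head at its random initialization, which swamps the
# global-average-pooled gradients).
planted_block_tiles <- function(n_per_class = 120L, seed = 1L) {
  withr::with_seed(seed, {
    tiles <- array(0, c(128L, 128L, 2L * n_per_class))
    for (i in seq_len(n_per_class)) {
      tiles[33:64, 33:64, i] <-
        runif(1, 0.05, 0.5) + runif(32 * 32, 0, 0.05)
      tiles[33:64, 33:64, n_per_class + i] <-
        runif(1, 0.45, 0.9) + runif(32 * 32, 0, 0.05)
    }
    pmin(tiles, 1)
  })
}

# conv-first detector for the planted-feature task (the reduced preset's
# pooling stem would erase fine structure before any convolution sees it)
detector_spec <- function() {
  cnn_spec(n_classes = 2L, input_size = 128L,
           blocks = list(cnn_block(1L, 5L, 8L, 4L),
                         cnn_block(1L, 3L, 16L, 4L)),
           head = 16L)
}

# fraction of top-decile heat mass inside the planted block, per tile.
# The class-1 map is used; when class-1 evidence is encoded inhibitorily
# (a binary SoftMax only identifies the logit difference) the class-0 map
# carries it instead. Tiles where both rectified maps are empty come back
# as NA.
block_heat_fractions <- function(det, tiles, idx) {
  vapply(idx, function(i) {
    up <- gradcam_map(det, tiles[, , i], 1L)$upsampled
    if (max(up) == 0) up <- gradcam_map(det, tiles[, , i], 0L)$upsampled
    if (max(up) == 0) return(NA_real_)
    hot <- up >= stats::quantile(up, 0.9)
    sum(up[hot & row(up) %in% 33:64 & col(up) %in% 33:64]) / sum(up[hot])
  }, numeric(1))
}
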