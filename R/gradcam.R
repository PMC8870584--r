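# head-only forward from a pooled activation map; used by Grad-CAM and by
# its finite-difference oracle
pw_head_logits <- function(model, A) {
  stopifnot(inherits(model, "pw_cnn"))
  if (!all(dim(A) == model$feat_shape))
    stop_invalid("activation map must be %s",
                 paste(model$feat_shape, collapse = "x"))
  Xf <- matrix(as.vector(A), nrow = 1L)
  drop(nn_head_forward(model, Xf)$logits)
}

# analytic gradient of the class score wrt the pooled activations
pw_head_grad <- function(model, A, class_index, use_probability = FALSE) {
  Xf <- matrix(as.vector(A), nrow = 1L)
  hd <- nn_head_forward(model, Xf, keep = TRUE)
  p <- softmax_rows(hd$logits)
  L <- model$n_classes
  d <- if (use_probability) {
    pc <- p[1L, class_index + 1L]
    matrix(pc * ((seq_len(L) == class_index + 1L) - p[1L, ]), nrow = 1L)
  } else {
    matrix(as.numeric(seq_len(L) == class_index + 1L), nrow = 1L)
  }
  nd <- length(model$dense)
  for (j in rev(seq_len(nd))) {
    X <- hd$inputs[[j]]
    d <- d %*% t(model$dense[[j]]$W)
    if (j > 1L) d[X <= 0] <- 0
  }
  array(d, model$feat_shape)
}

#' Grad-CAM class-discriminative heat map for one tile
#'
#' Gradient-weighted class activation mapping at the network's last
#' max-pooling layer (the final non-fully-connected layer; a 16x16x128
#' feature map for the default architecture). Each feature map `k` is
#' weighted by the spatial mean of the gradient of the class score with
#' respect to its activations (`w_k = (1/S) sum_ij dy_c / dA_k[i, j]`, `S`
#' the map size); the weighted sum over feature maps is rectified by a ReLU
#' to give the heat map, which is then bilinearly upsampled to the tile size
#' and min-max scaled to `[0, 1]` (an all-zero map stays zero). The class
#' score is the pre-SoftMax logit by default.
#'
#' @param model A `pw_cnn`.
#' @param tile A single tile (matrix, values in `[0, 1]`).
#' @param class_index Target class in `0:(n_classes-1)`.
#' @param use_probability Use the post-SoftMax probability as the class
#'   score instead of the logit.
#' @return Object of class `pw_heatmap`: `weights` (one per feature map),
#'   `map` (nonnegative, at feature-map resolution), `upsampled`
#'   (tile-sized, in `[0, 1]`), `activations`, `class_index`.
#' @export
gradcam_map <- function(model, tile, class_index, use_probability = FALSE) {
  stopifnot(inherits(model, "pw_cnn"))
  class_index <- as.integer(class_index)
  if (class_index < 0L || class_index >= model$n_classes)
    stop_invalid("class_index must lie in 0..%d", model$n_classes - 1L)
  x <- as_input_batch(tile, model$spec$input_size)
  if (dim(x)[4L] != 1L) stop_invalid("gradcam_map takes a single tile")
  A <- nn_feature_forward(model, x)$A
  A <- array(A, dim(A)[1:3])
  dA <- pw_head_grad(model, A, class_index, use_probability)
  w <- apply(dA, 3L, mean)
  map <- matrix(0, dim(A)[1L], dim(A)[2L])
  for (k in seq_along(w)) map <- map + w[k] * A[, , k]
  map <- pmax(map, 0)
  up <- bilinear_upsample(map, model$spec$input_size, model$spec$input_size)
  rng <- range(up)
  if (rng[2L] > rng[1L]) up <- (up - rng[1L]) / (rng[2L] - rng[1L])
  else up[] <- 0
  structure(list(class_index = class_index, weights = w, map = map,
                 upsampled = up, activations = A,
                 use_probability = use_probability),
            class = "pw_heatmap")
}

#' @export
print.pw_heatmap <- function(x, ...) {
  cat(sprintf("<pw_heatmap> class %d: %dx%d map over %d feature maps, peak %.3g\n",
              x$class_index, nrow(x$map), ncol(x$map), length(x$weights),
              max(x$map)))
  invisible(x)
}

#' Bilinear upsampling of a matrix
#'
#' Center-aligned bilinear interpolation, as used to stretch a feature-map
#' resolution heat map over the input tile.
#'
#' @param m Numeric matrix.
#' @param out_h,out_w Output dimensions.
#' @return `out_h` x `out_w` matrix.
#' @export
bilinear_upsample <- function(m, out_h, out_w = out_h) {
  interp_weights <- function(n_in, n_out) {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    lo <- floor(src)
    fr <- src - lo
    W <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      l <- lo[i] + 1L
      h <- min(l + 1L, n_in)
      W[i, l] <- W[i, l] + (1 - fr[i])
      W[i, h] <- W[i, h] + fr[i]
    }
    W
  }
  interp_weights(nrow(m), out_h) %*% m %*% t(interp_weights(ncol(m), out_w))
}

#' Render a heat-map overlay on its tile
#'
#' Color-maps the upsampled heat map (dark blue through red) and
#' alpha-blends it over the grayscale tile; optionally written as an RGB
#' PNG.
#'
#' @param heatmap A `pw_heatmap`.
#' @param tile The tile the map was computed from (matrix in `[0, 1]`).
#' @param out_path Optional PNG output path.
#' @param alpha Blend weight of the color layer.
#' @return Invisibly, the H x W x 3 RGB array.
#' @export
overlay_heatmap <- function(heatmap, tile, out_path = NULL, alpha = 0.45) {
  stopifnot(inherits(heatmap, "pw_heatmap"))
  tile <- as.matrix(tile)
  if (!all(dim(tile) == dim(heatmap$upsampled)))
    stop_invalid("tile (%s) and heat map (%s) sizes differ",
                 paste(dim(tile), collapse = "x"),
                 paste(dim(heatmap$upsampled), collapse = "x"))
  ramp <- grDevices::colorRamp(c("#000080", "#0000FF", "#00FFFF",
                                 "#FFFF00", "#FF0000"))
  cols <- ramp(as.vector(heatmap$upsampled)) / 255
  h <- nrow(tile); w <- ncol(tile)
  out <- array(0, c(h, w, 3L))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * tile + alpha * matrix(cols[, ch], h, w)
  if (!is.null(out_path)) png::writePNG(out, out_path)
  invisible(out)
}
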