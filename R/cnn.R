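#' Convolutional block description
#'
#' A block is `n_conv` convolution+ReLU layers (square `kernel`, `depth`
#' filters, stride 1, same padding) followed by one `pool` x `pool` max-pool
#' (no padding). `n_conv = 0` gives a pooling-only block (used by the
#' reduced preset as an input-downsampling stem).
#'
#' @param n_conv Number of convolution layers in the block.
#' @param kernel Odd kernel edge length (ignored when `n_conv = 0`).
#' @param depth Number of filters (ignored when `n_conv = 0`).
#' @param pool Max-pool edge length.
#' @return A list describing the block.
#' @export
cnn_block <- function(n_conv, kernel = NA_integer_, depth = NA_integer_,
                      pool = 2L) {
  if (n_conv > 0L) {
    if (is.na(kernel) || kernel %% 2L != 1L)
      stop_invalid("kernel must be odd for same padding (got %s)", kernel)
    if (is.na(depth) || depth < 1L) stop_invalid("depth must be >= 1")
  }
  list(n_conv = as.integer(n_conv), kernel = as.integer(kernel),
       depth = as.integer(depth), pool = as.integer(pool))
}

#' Architecture of the tile classifier
#'
#' The `"deep"` preset is the 20-layer network used throughout the
#' pipeline: three blocks of four convolution+ReLU layers (11x11 depth 32,
#' 9x9 depth 64, 7x7 depth 128, all same padding) each closed by a 2x2
#' max-pool, then fully connected ReLU layers of widths 128, 64, 32, 16 and
#' a final SoftMax layer. Spatial sizes run 128 -> 64 -> 32 -> 16, so the
#' head sees a 16x16x128 feature map. The `"small"` preset is a
#' reduced-scale network of the same pattern (a 4x4 pooling stem, then
#' 5x5/12 and 3x3/16 conv blocks) for desk-scale experiments.
#'
#' @param preset `"deep"` (default) or `"small"`; ignored when `blocks` is
#'   supplied.
#' @param n_classes Number of output classes, 2 or 3 (the screening
#'   experiments); other values require `allow_other_classes = TRUE` and
#'   produce a warning.
#' @param input_size Input tile edge length (default 128).
#' @param blocks Optional list of [cnn_block()] descriptions.
#' @param head Optional integer vector of fully connected ReLU widths.
#' @param allow_other_classes Permit `n_classes` outside `{2, 3}`.
#' @return An object of class `pw_cnn_spec`.
#' @export
#' @examples
#' spec <- cnn_spec("deep", n_classes = 2)
#' cnn_audit(spec)
cnn_spec <- function(preset = c("deep", "small"), n_classes = 2L,
                     input_size = 128L, blocks = NULL, head = NULL,
                     allow_other_classes = FALSE) {
  preset <- match.arg(preset)
  n_classes <- as.integer(n_classes)
  if (!n_classes %in% c(2L, 3L)) {
    if (!allow_other_classes)
      stop_invalid("n_classes must be 2 or 3 (got %d); set allow_other_classes = TRUE to override",
                   n_classes)
    warning(sprintf("using %d classes, outside the standard 2/3-class experiments",
                    n_classes))
  }
  if (is.null(blocks)) {
    blocks <- switch(preset,
      deep = list(cnn_block(4L, 11L, 32L, 2L),
                   cnn_block(4L, 9L, 64L, 2L),
                   cnn_block(4L, 7L, 128L, 2L)),
      small = list(cnn_block(0L, pool = 4L),
                   cnn_block(1L, 5L, 12L, 2L),
                   cnn_block(1L, 3L, 16L, 2L)))
  }
  if (is.null(head)) head <- switch(preset, deep = c(128L, 64L, 32L, 16L),
                                    small = 32L)
  pool_total <- prod(vapply(blocks, `[[`, integer(1), "pool"))
  if (input_size %% pool_total != 0L)
    stop_invalid("input_size %d is not divisible by the total pooling factor %d",
                 input_size, pool_total)
  structure(list(input_size = as.integer(input_size), blocks = blocks,
                 head = as.integer(head), n_classes = n_classes,
                 preset = preset),
            class = "pw_cnn_spec")
}

#' Shape and layer-count audit of an architecture
#'
#' Walks the specification arithmetic (no weights needed) and returns the
#' spatial-size chain together with the layer accounting: the deep preset
#' counts 12 convolution + 3 pooling + 5 fully connected layers = 20.
#'
#' @param spec A `pw_cnn_spec`.
#' @return Data frame of stages with columns `stage`, `out_size`, `depth`;
#'   attributes `n_conv`, `n_pool`, `n_fc`, `n_layers`.
#' @export
cnn_audit <- function(spec) {
  stopifnot(inherits(spec, "pw_cnn_spec"))
  size <- spec$input_size
  depth <- 1L
  rows <- data.frame(stage = "input", out_size = size, depth = depth)
  n_conv <- 0L; n_pool <- 0L
  for (b in spec$blocks) {
    if (b$n_conv > 0L) {
      depth <- b$depth
      n_conv <- n_conv + b$n_conv
      rows <- rbind(rows, data.frame(
        stage = sprintf("conv%dx%d x%d", b$kernel, b$kernel, b$n_conv),
        out_size = size, depth = depth))
    }
    size <- size %/% b$pool
    n_pool <- n_pool + 1L
    rows <- rbind(rows, data.frame(
      stage = sprintf("maxpool%dx%d", b$pool, b$pool),
      out_size = size, depth = depth))
  }
  for (wd in spec$head)
    rows <- rbind(rows, data.frame(stage = sprintf("fc%d", wd),
                                   out_size = 1L, depth = wd))
  rows <- rbind(rows, data.frame(stage = sprintf("fc%d+softmax", spec$n_classes),
                                 out_size = 1L, depth = spec$n_classes))
  n_fc <- length(spec$head) + 1L
  structure(rows, n_conv = n_conv, n_pool = n_pool, n_fc = n_fc,
            n_layers = n_conv + n_pool + n_fc)
}

#' Tabular architecture descriptor
#'
#' Field-for-field description of the network in the conventional table
#' layout: layer type, layer size, depth, repeat count and padding
#' properties.
#'
#' @param spec A `pw_cnn_spec`.
#' @return Data frame with columns `layer`, `layer_size`, `layer_depth`,
#'   `n_layers`, `properties`.
#' @export
describe_cnn <- function(spec) {
  stopifnot(inherits(spec, "pw_cnn_spec"))
  rows <- list(data.frame(
    layer = "Input",
    layer_size = sprintf("%dx%d", spec$input_size, spec$input_size),
    layer_depth = 1L, n_layers = 1L, properties = "-"))
  depth <- 1L
  for (b in spec$blocks) {
    if (b$n_conv > 0L) {
      depth <- b$depth
      rows[[length(rows) + 1L]] <- data.frame(
        layer = "Convolutional / ReLU",
        layer_size = sprintf("%dx%d", b$kernel, b$kernel),
        layer_depth = depth, n_layers = b$n_conv,
        properties = "Same Padding")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      layer = "MaxPooling", layer_size = sprintf("%dx%d", b$pool, b$pool),
      layer_depth = depth, n_layers = 1L, properties = "No Padding")
  }
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "Fully Connected / ReLU",
    layer_size = paste(spec$head, collapse = ", "),
    layer_depth = 1L, n_layers = length(spec$head), properties = "-")
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "Fully Connected / SoftMax",
    layer_size = as.character(spec$n_classes),
    layer_depth = 1L, n_layers = 1L, properties = "-")
  do.call(rbind, rows)
}

#' @export
print.pw_cnn_spec <- function(x, ...) {
  a <- cnn_audit(x)
  cat(sprintf("<pw_cnn_spec> '%s': input %dx%dx1, %d conv + %d pool + %d fc = %d layers, %d classes\n",
              x$preset, x$input_size, x$input_size, attr(a, "n_conv"),
              attr(a, "n_pool"), attr(a, "n_fc"), attr(a, "n_layers"),
              x$n_classes))
  invisible(x)
}

#' Build (initialize) a tile classifier
#'
#' He-uniform initialization for convolution and fully connected weights
#' (`U(-sqrt(6/fan_in), sqrt(6/fan_in))`), zero biases; deterministic for a
#' fixed seed.
#'
#' @param spec A `pw_cnn_spec`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `pw_cnn` (untrained).
#' @export
build_cnn <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "pw_cnn_spec"))
  with_seed(seed, {
    ops <- list()
    in_c <- 1L
    size <- spec$input_size
    for (b in spec$blocks) {
      if (b$n_conv > 0L) {
        for (j in seq_len(b$n_conv)) {
          fan_in <- in_c * b$kernel^2
          lim <- sqrt(6 / fan_in)
          w <- array(stats::runif(b$depth * in_c * b$kernel^2, -lim, lim),
                     c(b$depth, in_c, b$kernel, b$kernel))
          ops[[length(ops) + 1L]] <- list(type = "conv", w = w,
                                          b = numeric(b$depth))
          in_c <- b$depth
        }
      }
      ops[[length(ops) + 1L]] <- list(type = "pool", p = b$pool)
      size <- size %/% b$pool
    }
    feat_dim <- size * size * in_c
    dense <- list()
    dims <- c(feat_dim, spec$head, spec$n_classes)
    for (j in seq_len(length(dims) - 1L)) {
      lim <- sqrt(6 / dims[j])
      dense[[j]] <- list(W = matrix(stats::runif(dims[j] * dims[j + 1L],
                                                 -lim, lim),
                                    dims[j], dims[j + 1L]),
                         b = numeric(dims[j + 1L]))
    }
    structure(list(spec = spec, ops = ops, dense = dense,
                   n_classes = spec$n_classes,
                   feat_shape = c(size, size, in_c),
                   seed = as.integer(seed), trained = FALSE,
                   history = NULL),
              class = "pw_cnn")
  })
}

#' @export
print.pw_cnn <- function(x, ...) {
  npar <- sum(vapply(x$ops, function(o)
    if (o$type == "conv") length(o$w) + length(o$b) else 0, numeric(1))) +
    sum(vapply(x$dense, function(d) length(d$W) + length(d$b), numeric(1)))
  cat(sprintf("<pw_cnn> %s preset, %s, %s parameters\n", x$spec$preset,
              if (isTRUE(x$trained)) "trained" else "untrained",
              format(npar, big.mark = ",")))
  invisible(x)
}

# ---- internal forward / backward ------------------------------------------

# tiles: (H, W, N) array or (H, W, 1, N); returns (H, W, 1, N)
as_input_batch <- function(tiles, input_size) {
  d <- dim(tiles)
  if (is.matrix(tiles)) { tiles <- array(tiles, c(d, 1L)); d <- dim(tiles) }
  if (length(d) == 3L) { dim(tiles) <- c(d[1L], d[2L], 1L, d[3L]) }
  d <- dim(tiles)
  if (d[1L] != input_size || d[2L] != input_size || d[3L] != 1L)
    stop_invalid("tiles must be %dx%dx1 (got %s)", input_size, input_size,
                 paste(d, collapse = "x"))
  tiles
}

# convolutional trunk; returns final pooled activations and (optionally) caches
nn_feature_forward <- function(model, x, keep = FALSE) {
  caches <- if (keep) vector("list", length(model$ops)) else NULL
  for (i in seq_along(model$ops)) {
    op <- model$ops[[i]]
    if (op$type == "conv") {
      z <- conv2d_forward_cpp(x, op$w, op$b)
      mask <- z > 0
      z[!mask] <- 0
      if (keep) caches[[i]] <- list(x = x, mask = mask)
      x <- z
    } else {
      mp <- maxpool_forward_cpp(x, op$p)
      if (keep) caches[[i]] <- list(idx = mp$idx, h = dim(x)[1L],
                                    w = dim(x)[2L])
      x <- mp$out
    }
  }
  list(A = x, caches = caches)
}

flatten_features <- function(A) {
  d <- dim(A)
  t(matrix(A, d[1L] * d[2L] * d[3L], d[4L]))
}

nn_head_forward <- function(model, X, keep = FALSE) {
  nd <- length(model$dense)
  inputs <- if (keep) vector("list", nd) else NULL
  for (j in seq_len(nd)) {
    if (keep) inputs[[j]] <- X
    Z <- sweep(X %*% model$dense[[j]]$W, 2L, model$dense[[j]]$b, "+")
    X <- if (j < nd) relu(Z) else Z
  }
  list(logits = X, inputs = inputs)
}

nn_forward <- function(model, x, keep = FALSE) {
  ft <- nn_feature_forward(model, x, keep = keep)
  Xf <- flatten_features(ft$A)
  hd <- nn_head_forward(model, Xf, keep = keep)
  list(logits = hd$logits, probs = softmax_rows(hd$logits),
       A = ft$A, conv_caches = ft$caches, head_inputs = hd$inputs)
}

# gradient of mean loss wrt all parameters, given dlogits (N x L)
nn_backward <- function(model, fw, dlogits) {
  nd <- length(model$dense)
  dW <- vector("list", nd); db <- vector("list", nd)
  d <- dlogits
  for (j in rev(seq_len(nd))) {
    X <- fw$head_inputs[[j]]
    dW[[j]] <- crossprod(X, d)
    db[[j]] <- colSums(d)
    if (j > 1L) {
      d <- d %*% t(model$dense[[j]]$W)
      d[X <= 0] <- 0  # ReLU mask: X is the post-ReLU input to layer j
    } else {
      d <- d %*% t(model$dense[[1L]]$W)
    }
  }
  dA <- t(d)
  dim(dA) <- dim(fw$A)
  gconv <- vector("list", length(model$ops))
  for (i in rev(seq_along(model$ops))) {
    op <- model$ops[[i]]
    cache <- fw$conv_caches[[i]]
    if (op$type == "pool") {
      dA <- maxpool_backward_cpp(cache$idx, dA, cache$h, cache$w)
    } else {
      dA[!cache$mask] <- 0
      g <- conv2d_backward_cpp(cache$x, op$w, dA)
      gconv[[i]] <- list(dw = g$dw, db = g$db)
      dA <- g$dx
    }
  }
  list(conv = gconv, dense_W = dW, dense_b = db)
}

#' Training configuration
#'
#' Defaults follow the study regime: mini-batches of 50 tiles, plain
#' stochastic gradient descent at learning rate 1e-5, cross-entropy loss on
#' the SoftMax outputs, 40 epochs. All values can be overridden (reduced-
#' scale experiments use fewer epochs at an elevated learning rate).
#'
#' @param batch_size Mini-batch size.
#' @param learning_rate SGD learning rate.
#' @param epochs Number of passes over the training tiles.
#' @param momentum SGD momentum (0 = plain SGD, the default).
#' @param weight_decay L2 penalty coefficient (0 = plain SGD, the default;
#'   nonzero values shrink weights that receive no gradient, which sharpens
#'   gradient-based attribution on small networks).
#' @param seed Seed for mini-batch shuffling.
#' @param verbose Print per-epoch loss/accuracy.
#' @return A list of class `pw_train_config`.
#' @export
train_config <- function(batch_size = 50L, learning_rate = 1e-5,
                         epochs = 40L, momentum = 0, weight_decay = 0,
                         seed = 1L, verbose = FALSE) {
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 momentum = momentum, weight_decay = weight_decay,
                 seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pw_train_config")
}

#' Train the tile classifier
#'
#' Minimizes the cross-entropy of the SoftMax outputs by mini-batch
#' stochastic gradient descent. Tiles are shuffled each epoch (seeded); the
#' final short batch is used, not dropped. Reproducible for fixed seeds.
#'
#' @param model A `pw_cnn` from [build_cnn()].
#' @param tiles A `pw_tileset`, or a (H, W, N) array with `labels` given.
#' @param labels Integer labels in `0:(n_classes-1)`; taken from the tile
#'   set's provenance when `tiles` is a `pw_tileset`.
#' @param config A [train_config()].
#' @return The trained model, with a `history` data frame (per-epoch mean
#'   training loss and accuracy).
#' @export
train_cnn <- function(model, tiles, labels = NULL, config = train_config()) {
  stopifnot(inherits(model, "pw_cnn"))
  if (inherits(tiles, "pw_tileset")) {
    labels <- tiles$info$class_label
    tiles <- tiles$tiles
  }
  x <- as_input_batch(tiles, model$spec$input_size)
  y <- as.integer(labels)
  n <- dim(x)[4L]
  if (length(y) != n) stop_invalid("labels length != number of tiles")
  if (any(y < 0L | y >= model$n_classes))
    stop_invalid("labels must lie in 0..%d", model$n_classes - 1L)
  if (length(unique(y)) < 2L)
    stop_invalid("training set contains a single class; need at least two")
  lr <- config$learning_rate
  mom <- config$momentum
  wd <- if (is.null(config$weight_decay)) 0 else config$weight_decay
  vel <- NULL
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        yb <- y[idx]
        B <- length(idx)
        fw <- nn_forward(model, xb, keep = TRUE)
        pt <- fw$probs[cbind(seq_len(B), yb + 1L)]
        loss <- -mean(log(pmax(pt, 1e-300)))
        if (!is.finite(loss))
          stop_invalid("non-finite training loss at epoch %d", epoch)
        tot_loss <- tot_loss + loss * B
        tot_correct <- tot_correct +
          sum(max.col(fw$probs, ties.method = "first") - 1L == yb)
        dlogits <- fw$probs
        dlogits[cbind(seq_len(B), yb + 1L)] <-
          dlogits[cbind(seq_len(B), yb + 1L)] - 1
        dlogits <- dlogits / B
        gr <- nn_backward(model, fw, dlogits)
        if (wd > 0) {  # L2 penalty on weights (not biases)
          for (i in seq_along(model$ops))
            if (model$ops[[i]]$type == "conv")
              gr$conv[[i]]$dw <- gr$conv[[i]]$dw + wd * model$ops[[i]]$w
          for (j in seq_along(model$dense))
            gr$dense_W[[j]] <- gr$dense_W[[j]] + wd * model$dense[[j]]$W
        }
        if (mom > 0 && is.null(vel)) {
          vel <- list(conv = lapply(gr$conv, function(g)
                        if (is.null(g)) NULL
                        else list(dw = g$dw * 0, db = g$db * 0)),
                      dense_W = lapply(gr$dense_W, function(g) g * 0),
                      dense_b = lapply(gr$dense_b, function(g) g * 0))
        }
        for (i in seq_along(model$ops)) {
          if (model$ops[[i]]$type != "conv") next
          if (mom > 0) {
            vel$conv[[i]]$dw <- mom * vel$conv[[i]]$dw + gr$conv[[i]]$dw
            vel$conv[[i]]$db <- mom * vel$conv[[i]]$db + gr$conv[[i]]$db
            model$ops[[i]]$w <- model$ops[[i]]$w - lr * vel$conv[[i]]$dw
            model$ops[[i]]$b <- model$ops[[i]]$b - lr * vel$conv[[i]]$db
          } else {
            model$ops[[i]]$w <- model$ops[[i]]$w - lr * gr$conv[[i]]$dw
            model$ops[[i]]$b <- model$ops[[i]]$b - lr * gr$conv[[i]]$db
          }
        }
        for (j in seq_along(model$dense)) {
          if (mom > 0) {
            vel$dense_W[[j]] <- mom * vel$dense_W[[j]] + gr$dense_W[[j]]
            vel$dense_b[[j]] <- mom * vel$dense_b[[j]] + gr$dense_b[[j]]
            model$dense[[j]]$W <- model$dense[[j]]$W - lr * vel$dense_W[[j]]
            model$dense[[j]]$b <- model$dense[[j]]$b - lr * vel$dense_b[[j]]
          } else {
            model$dense[[j]]$W <- model$dense[[j]]$W - lr * gr$dense_W[[j]]
            model$dense[[j]]$b <- model$dense[[j]]$b - lr * gr$dense_b[[j]]
          }
        }
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = tot_loss / n, accuracy = tot_correct / n))
      if (config$verbose)
        message(sprintf("epoch %2d: loss %.4f, accuracy %.3f",
                        epoch, tot_loss / n, tot_correct / n))
    }
  })
  model$trained <- TRUE
  model$history <- history
  model
}

#' Class probabilities for a batch of tiles
#'
#' @param model A `pw_cnn`.
#' @param tiles A `pw_tileset` or (H, W, N) array with values in `[0, 1]`.
#' @param batch_size Forward-pass chunk size.
#' @return N x n_classes matrix of SoftMax probabilities (rows sum to 1).
#' @export
forward_cnn <- function(model, tiles, batch_size = 128L) {
  stopifnot(inherits(model, "pw_cnn"))
  if (inherits(tiles, "pw_tileset")) tiles <- tiles$tiles
  x <- as_input_batch(tiles, model$spec$input_size)
  n <- dim(x)[4L]
  out <- matrix(0, n, model$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- nn_forward(model, x[, , , idx, drop = FALSE])$probs
  }
  out
}

#' Predict class labels for tiles
#'
#' Binary models label a tile 1 (PD) when the positive-class probability is
#' `>= threshold` (default 0.5, ties included); multi-class models use the
#' arg-max with lowest-index tie-break.
#'
#' @param object A `pw_cnn`.
#' @param tiles A `pw_tileset` or tile array.
#' @param type `"label"` (default) or `"prob"`.
#' @param threshold Decision threshold in `[0, 1]` for binary models.
#' @param allow_untrained Permit prediction from an untrained model.
#' @param ... Unused.
#' @return Integer labels in `0:(n_classes-1)`, or a probability matrix.
#' @export
predict.pw_cnn <- function(object, tiles, type = c("label", "prob"),
                           threshold = 0.5, allow_untrained = FALSE, ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained) && !allow_untrained)
    stop_invalid("model is untrained; pass allow_untrained = TRUE to predict anyway")
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop_invalid("threshold must lie in [0, 1]")
  p <- forward_cnn(object, tiles)
  if (type == "prob") return(p)
  decide_labels(p, threshold)
}

# decision rule shared by predict and cross_validate
decide_labels <- function(p, threshold = 0.5) {
  if (ncol(p) == 2L) as.integer(p[, 2L] >= threshold)
  else max.col(p, ties.method = "first") - 1L
}
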