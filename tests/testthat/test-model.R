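test_that("architecture audit: shape chain, layer count, descriptor", {
  spec <- cnn_spec("deep", n_classes = 2L)
  a <- cnn_audit(spec)
  pools <- a[grepl("maxpool", a$stage), ]
  expect_equal(pools$out_size, c(64L, 32L, 16L))  # 128 -> 64 -> 32 -> 16
  expect_equal(tail(pools$depth, 1L), 128L)       # 16x16x128 enters the head
  expect_equal(attr(a, "n_conv"), 12L)
  expect_equal(attr(a, "n_pool"), 3L)
  expect_equal(attr(a, "n_fc"), 5L)
  expect_equal(attr(a, "n_layers"), 20L)

  expected <- data.frame(
    layer = c("Input", "Convolutional / ReLU", "MaxPooling",
              "Convolutional / ReLU", "MaxPooling",
              "Convolutional / ReLU", "MaxPooling",
              "Fully Connected / ReLU", "Fully Connected / SoftMax"),
    layer_size = c("128x128", "11x11", "2x2", "9x9", "2x2", "7x7", "2x2",
                   "128, 64, 32, 16", "2"),
    layer_depth = c(1L, 32L, 32L, 64L, 64L, 128L, 128L, 1L, 1L),
    n_layers = c(1L, 4L, 1L, 4L, 1L, 4L, 1L, 4L, 1L),
    properties = c("-", "Same Padding", "No Padding", "Same Padding",
                   "No Padding", "Same Padding", "No Padding", "-", "-"))
  expect_equal(describe_cnn(spec), expected)

  expect_error(cnn_spec(n_classes = 5L), "allow_other_classes")
  expect_warning(cnn_spec(n_classes = 5L, allow_other_classes = TRUE),
                 "outside")
  expect_error(cnn_spec(input_size = 100L), "divisible")
  expect_error(cnn_block(1L, kernel = 4L), "odd")
})

test_that("full network forward pass realizes the audited shapes", {
  spec <- cnn_spec("deep", n_classes = 3L)
  model <- build_cnn(spec, seed = 2)
  tile <- matrix(withr::with_seed(1, runif(128 * 128)), 128)
  ft <- parkwave:::nn_feature_forward(
    model, parkwave:::as_input_batch(tile, 128L))
  expect_equal(dim(ft$A), c(16L, 16L, 128L, 1L))
  p <- forward_cnn(model, array(tile, c(128, 128, 1)))
  expect_equal(dim(p), c(1L, 3L))
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("initialization is seed-deterministic", {
  spec <- tiny_spec()
  m1 <- build_cnn(spec, seed = 7)
  m2 <- build_cnn(spec, seed = 7)
  m3 <- build_cnn(spec, seed = 8)
  expect_identical(m1$ops[[1L]]$w, m2$ops[[1L]]$w)
  expect_identical(m1$dense[[1L]]$W, m2$dense[[1L]]$W)
  expect_false(identical(m1$ops[[1L]]$w, m3$ops[[1L]]$w))
})

test_that("SoftMax outputs are normalized, stateless, uniform at zero logits", {
  model <- build_cnn(tiny_spec(), seed = 1)
  tiles <- array(withr::with_seed(2, runif(16 * 16 * 4)), c(16, 16, 4))
  tiles[, , 3L] <- tiles[, , 1L]  # duplicated input
  p <- forward_cnn(model, tiles)
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_equal(p[3L, ], p[1L, ])

  zeroed <- model
  last <- length(zeroed$dense)
  zeroed$dense[[last]]$W[] <- 0
  zeroed$dense[[last]]$b[] <- 0
  pz <- forward_cnn(zeroed, tiles)
  expect_equal(pz, matrix(0.5, 4, 2), tolerance = 1e-12)

  expect_error(forward_cnn(model, array(0, c(8, 8, 2))), "16x16")
})

test_that("analytic gradients match finite differences on a tiny network", {
  spec <- tiny_spec()
  model <- build_cnn(spec, seed = 11)
  n <- 6L
  x <- parkwave:::as_input_batch(
    array(withr::with_seed(12, runif(16 * 16 * n)), c(16, 16, n)), 16L)
  y <- rep(0:1, 3L)

  loss_fn <- function(m) {
    fw <- parkwave:::nn_forward(m, x)
    pt <- fw$probs[cbind(seq_len(n), y + 1L)]
    -mean(log(pt))
  }
  fw <- parkwave:::nn_forward(model, x, keep = TRUE)
  dlogits <- fw$probs
  dlogits[cbind(seq_len(n), y + 1L)] <- dlogits[cbind(seq_len(n), y + 1L)] - 1
  gr <- parkwave:::nn_backward(model, fw, dlogits / n)

  eps <- 1e-6
  check <- function(get, set, analytic, k_probe) {
    for (k in k_probe) {
      mp <- set(model, k, get(model, k) + eps)
      mm <- set(model, k, get(model, k) - eps)
      num <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
      expect_lt(abs(analytic[k] - num), 1e-6 + 1e-4 * abs(num))
    }
  }
  probes <- withr::with_seed(13, sample(length(model$ops[[1L]]$w), 4L))
  check(function(m, k) m$ops[[1L]]$w[k],
        function(m, k, v) { m$ops[[1L]]$w[k] <- v; m },
        gr$conv[[1L]]$dw, probes)
  probes <- withr::with_seed(14, sample(length(model$dense[[1L]]$W), 4L))
  check(function(m, k) m$dense[[1L]]$W[k],
        function(m, k, v) { m$dense[[1L]]$W[k] <- v; m },
        gr$dense_W[[1L]], probes)
  check(function(m, k) m$dense[[2L]]$b[k],
        function(m, k, v) { m$dense[[2L]]$b[k] <- v; m },
        gr$dense_b[[2L]], 1:2)
})

test_that("training separates a linearly separable toy problem", {
  spec <- cnn_spec("small")
  n <- 200L
  tiles <- array(0, c(128, 128, 2L * n))
  for (i in seq_len(n)) tiles[, , n + i] <- 1
  y <- rep(0:1, each = n)
  model <- build_cnn(spec, seed = 1)
  cfg <- train_config(batch_size = 50L, learning_rate = 0.05,
                      epochs = 40L, seed = 1)
  model <- train_cnn(model, tiles, y, config = cfg)
  expect_equal(nrow(model$history), 40L)  # history length == epochs
  expect_gte(tail(model$history$accuracy, 1L), 0.99)
  expect_true(all(is.finite(model$history$loss)))
  pred <- predict(model, tiles)
  expect_gte(mean(pred == y), 0.99)
})

test_that("one small-step epoch does not increase the loss over the untrained model", {
  ts <- make_band_tileset(n_subjects_per_class = 2L, tiles_per_subject = 8L,
                          size = 16L, seed = 21)
  y <- match(ts$info$class_label, c(0L, 1L)) - 1L
  model0 <- build_cnn(tiny_spec(), seed = 3)
  x <- parkwave:::as_input_batch(ts$tiles, 16L)
  base_loss <- {
    fw <- parkwave:::nn_forward(model0, x)
    -mean(log(fw$probs[cbind(seq_along(y), y + 1L)]))
  }
  m1 <- train_cnn(model0, ts$tiles, y,
                  train_config(batch_size = 8L, learning_rate = 1e-4,
                               epochs = 1L, seed = 3))
  expect_lte(m1$history$loss[1L], base_loss + 1e-6)
})

test_that("training is reproducible and validates its inputs", {
  ts <- make_band_tileset(n_subjects_per_class = 2L, tiles_per_subject = 4L,
                          size = 16L, seed = 22)
  y <- match(ts$info$class_label, c(0L, 1L)) - 1L
  cfg <- train_config(batch_size = 4L, learning_rate = 0.01, epochs = 2L,
                      seed = 5)
  m1 <- train_cnn(build_cnn(tiny_spec(), seed = 9), ts$tiles, y, cfg)
  m2 <- train_cnn(build_cnn(tiny_spec(), seed = 9), ts$tiles, y, cfg)
  expect_identical(m1$ops[[1L]]$w, m2$ops[[1L]]$w)
  expect_identical(m1$dense[[2L]]$W, m2$dense[[2L]]$W)

  expect_error(train_cnn(build_cnn(tiny_spec(), seed = 1), ts$tiles,
                         rep(0L, length(y)), cfg), "single class")
  expect_error(train_cnn(build_cnn(tiny_spec(), seed = 1), ts$tiles,
                         rep(c(0L, 3L), length.out = length(y)), cfg),
               "labels")
})

test_that("decision rules: threshold with >= ties, lowest-index argmax", {
  expect_equal(parkwave:::decide_labels(matrix(c(0.2, 0.8), 1), 0.5), 1L)
  expect_equal(parkwave:::decide_labels(matrix(c(0.5, 0.5), 1), 0.5), 1L)
  expect_equal(parkwave:::decide_labels(matrix(c(0.8, 0.2), 1), 0.5), 0L)
  expect_equal(parkwave:::decide_labels(matrix(c(0.4, 0.4, 0.2), 1)), 0L)
  expect_equal(parkwave:::decide_labels(matrix(c(0.1, 0.4, 0.5), 1)), 2L)

  model <- build_cnn(tiny_spec(), seed = 1)
  tiles <- array(0.5, c(16, 16, 1))
  expect_error(predict(model, tiles), "untrained")
  expect_silent(predict(model, tiles, allow_untrained = TRUE))
  expect_error(predict(model, tiles, threshold = 1.5,
                       allow_untrained = TRUE), "threshold")
})
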