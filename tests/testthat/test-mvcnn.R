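test_that("fine-to-coarse label mapping is total and surjective", {
  expect_equal(as.character(coarse_map("L.Sto")), "Left")
  expect_equal(as.character(coarse_map("R.Pr")), "Prone")
  expect_equal(as.character(coarse_map("S")), "Supine")
  all_mapped <- coarse_map(posture_levels())
  expect_false(any(is.na(all_mapped)))
  expect_equal(as.vector(table(all_mapped)), c(1, 3, 3, 2))  # class sizes
  expect_error(coarse_map("upside-down"), "unknown posture")
})

test_that("model specs validate and stub backbones refuse to build", {
  expect_error(model_spec(n_classes = 5), "4 or 9")
  expect_error(model_spec(backbone = "lenet"), "unknown backbone")
  expect_error(build_model(model_spec(backbone = "resnet50")),
               "registry stub")
  expect_error(train_config(betas = c(0.999, 0.9)))
  m <- build_model(model_spec(n_views = 3, n_classes = 4, input_size = 16))
  expect_s3_class(m, "mvcnn_model")
})

test_that("view pooling is permutation-invariant and duplicate-stable", {
  spec1 <- model_spec(n_views = 1, n_classes = 4, input_size = 16)
  spec3 <- model_spec(n_views = 3, n_classes = 4, input_size = 16)
  m1 <- build_model(spec1, seed = 7)
  m3 <- build_model(spec3, seed = 7)      # same weights: init ignores n_views
  set.seed(1)
  v <- array(rnorm(16 * 16), c(1, 1, 16, 16))
  x3 <- array(0, c(1, 3, 16, 16))
  for (k in 1:3) x3[1, k, , ] <- v[1, 1, , ]

  # max over identical duplicated views equals the single-view logits
  l1 <- bedradar:::mvcnn_forward(m1, v)$logits
  l3 <- bedradar:::mvcnn_forward(m3, x3)$logits
  expect_equal(l3, l1, tolerance = 1e-12)

  # permuting distinct views leaves max-pooled logits unchanged
  set.seed(2)
  xd <- array(rnorm(2 * 3 * 16 * 16), c(2, 3, 16, 16))
  xp <- xd[, c(3, 1, 2), , , drop = FALSE]
  expect_equal(bedradar:::mvcnn_forward(m3, xd)$logits,
               bedradar:::mvcnn_forward(m3, xp)$logits, tolerance = 1e-12)

  # pooled feature dimensionality is independent of n_views
  expect_identical(dim(m1$params$W_head1), dim(m3$params$W_head1))
})

test_that("softmax probabilities normalise per sample", {
  m <- build_model(model_spec(n_views = 2, n_classes = 4, input_size = 16),
                   seed = 3)
  m$classes <- coarse_levels()
  set.seed(5)
  x <- array(rnorm(4 * 2 * 16 * 16), c(4, 2, 16, 16))
  p <- predict(m, x, type = "prob")
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences", {
  for (bb in c("tiny_cnn", "tiny_resnet", "tiny_densenet")) {
    m <- build_model(model_spec(backbone = bb, n_views = 2, n_classes = 4,
                                input_size = 16), seed = 11)
    set.seed(13)
    x <- array(rnorm(3 * 2 * 16 * 16, 0, 0.5), c(3, 2, 16, 16))
    y <- c(1L, 3L, 4L)
    loss_at <- function(params) {
      mm <- m; mm$params <- params
      fw <- bedradar:::mvcnn_forward(mm, x, training = TRUE)
      bedradar:::softmax_xent(fw$logits, y)$loss
    }
    fw <- bedradar:::mvcnn_forward(m, x, training = TRUE)
    sx <- bedradar:::softmax_xent(fw$logits, y)
    grads <- bedradar:::mvcnn_backward(m, sx$dlogits, fw$cache)
    eps <- 1e-5
    set.seed(17)
    for (nm in c("W_conv1", "W_conv3", "W_head1", "b_conv2")) {
      idx <- sample(length(m$params[[nm]]), 3)
      for (i in idx) {
        pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training is deterministic and inert at zero learning rate", {
  fx <- corner_blob_fixture(n_per_class = 4, seed = 31)
  spec <- model_spec(n_views = 2, n_classes = 4, input_size = 16)

  m0 <- build_model(spec, seed = 1)
  frozen <- train_mvcnn(m0, fx$x, fx$y,
                        train_config(learning_rate = 0, epochs = 1,
                                     batch_size = 8, seed = 9))
  expect_equal(frozen$params, m0$params, tolerance = 1e-12)

  cfg <- train_config(epochs = 3, batch_size = 8, seed = 9)
  h1 <- train_mvcnn(build_model(spec, seed = 1), fx$x, fx$y, cfg)$history
  h2 <- train_mvcnn(build_model(spec, seed = 1), fx$x, fx$y, cfg)$history
  expect_identical(h1, h2)
})

test_that("the network learns an easily separable synthetic set", {
  fx <- corner_blob_fixture(n_per_class = 10, seed = 41)
  m <- build_model(model_spec(n_views = 2, n_classes = 4, input_size = 16),
                   seed = 2)
  m <- train_mvcnn(m, fx$x, fx$y,
                   train_config(epochs = 10, batch_size = 8, seed = 2))
  h <- tidy(m)
  expect_gte(h$accuracy[nrow(h)], 0.9)
  expect_lt(h$loss[nrow(h)], h$loss[1])
  g <- glance(m)
  expect_identical(g$epochs, 10L)
  expect_equal(g$final_accuracy, h$accuracy[10])
})

test_that("evaluation accuracy and confusion matrix are consistent", {
  fx <- corner_blob_fixture(n_per_class = 5, seed = 51)
  spec <- model_spec(n_views = 2, n_classes = 4, input_size = 16)

  # a constant-predictor: zero weights, bias fixed on the first class
  m <- build_model(spec, seed = 1)
  m$params <- lapply(m$params, function(p) p * 0)
  m$params$b_head1 <- c(10, 0, 0, 0)
  m$classes <- coarse_levels()
  ev <- evaluate_model(m, fx$x, fx$y)
  expect_equal(ev$accuracy, 0.25)       # balanced 4-class test set

  # conservation and diagonal identity
  expect_equal(sum(ev$confusion), length(fx$y))
  expect_equal(as.vector(rowSums(ev$confusion)),
               as.vector(table(fx$y)))
  expect_equal(sum(diag(ev$confusion)) / sum(ev$confusion), ev$accuracy)

  # labels outside the taxonomy are refused
  expect_error(evaluate_model(m, fx$x, rep("Diagonal", 20)),
               "outside the model's taxonomy")

  td <- tidy(ev)
  expect_equal(sum(td$n), length(fx$y))
  expect_equal(glance(ev)$accuracy, ev$accuracy)
})

test_that("coarse accuracy of fine predictions never drops below fine accuracy", {
  # 9-class blobs: reuse corner fixture geometry per coarse group
  withr::with_seed(61, {
    n <- 36
    x <- array(rnorm(n * 2 * 16 * 16, 0, 0.3), c(n, 2, 16, 16))
    yf <- factor(rep(posture_levels(), length.out = n),
                 levels = posture_levels())
    for (k in seq_len(n)) {
      ci <- as.integer(yf[k])
      r0 <- 2 + (ci - 1) %% 3 * 5; c0 <- 2 + (ci - 1) %/% 3 * 5
      x[k, , r0 + (0:2), c0 + (0:2)] <- x[k, , r0 + (0:2), c0 + (0:2)] + 1
    }
    m <- build_model(model_spec(n_views = 2, n_classes = 9,
                                input_size = 16), seed = 3)
    m <- suppressWarnings(
      train_mvcnn(m, x, yf, train_config(epochs = 4, batch_size = 9,
                                         seed = 3)))
    pred_fine <- predict(m, x)
    acc_fine <- mean(pred_fine == yf)
    acc_coarse <- mean(coarse_map(pred_fine) == coarse_map(yf))
    expect_gte(acc_coarse, acc_fine)
  })
})
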