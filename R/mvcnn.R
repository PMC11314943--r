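#' Backbone registry
#'
#' Compact convolutional backbones implemented natively (run on one CPU at
#' desk scale): `tiny_cnn` (three 3x3 conv blocks, ~6k parameters),
#' `tiny_resnet` (identity skip over the last block) and `tiny_densenet`
#' (dense concatenation of the last two blocks). The large ImageNet-class
#' extractors appear as registry stubs for interface completeness; building
#' them raises an informative error.
#'
#' @return Tibble with columns `backbone`, `implemented`, `top_channels`
#'   (channel count entering the 4x4 adaptive average pool).
#' @export
backbone_registry <- function() {
  tibble::tibble(
    backbone = c("tiny_cnn", "tiny_resnet", "tiny_densenet",
                 "resnet50", "densenet121", "efficientnet_b0",
                 "phresnet50", "attention56", "swin_transformer"),
    implemented = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE),
    top_channels = c(32L, 16L, 32L, NA, NA, NA, NA, NA, NA)
  )
}

#' Multiview model specification
#'
#' @param backbone One of `backbone_registry()$backbone`.
#' @param n_views Number of radar views the model consumes.
#' @param n_classes 4 (coarse) or 9 (fine).
#' @param pooling Cross-view pooling: `"max"` (default, element-wise
#'   maximum over views) or `"mean"`.
#' @param input_size Side length the square input maps are resized to.
#' @param head Integer vector of hidden fully-connected widths between the
#'   pooled features and the class logits (empty = a single linear layer).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(backbone = "tiny_cnn", n_views = 8L,
                       n_classes = 4L, pooling = c("max", "mean"),
                       input_size = 32L, head = integer(0)) {
  pooling <- match.arg(pooling)
  reg <- backbone_registry()
  if (!backbone %in% reg$backbone) {
    stop("unknown backbone: ", backbone, call. = FALSE)
  }
  if (!n_classes %in% c(4L, 9L)) {
    stop("`n_classes` must be 4 or 9", call. = FALSE)
  }
  stopifnot(n_views >= 1, input_size >= 16, input_size %% 8 == 0)
  structure(
    list(backbone = backbone, n_views = as.integer(n_views),
         n_classes = as.integer(n_classes), pooling = pooling,
         input_size = as.integer(input_size), head = as.integer(head)),
    class = "model_spec"
  )
}

#' Training configuration
#'
#' Defaults follow the published recipe: cross-entropy loss, AdamW with
#' learning rate 0.001 and betas (0.9, 0.999).
#'
#' @param learning_rate AdamW learning rate (> 0 required for learning; 0
#'   is allowed and leaves weights untouched, useful for smoke tests).
#' @param betas Two AdamW moment-decay coefficients, 0 < b1 < b2 < 1.
#' @param weight_decay Decoupled weight decay.
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param seed RNG seed covering init shuffling and batching.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, betas = c(0.9, 0.999),
                         weight_decay = 0.01, epochs = 30L,
                         batch_size = 16L, seed = 1L) {
  stopifnot(learning_rate >= 0, length(betas) == 2,
            betas[1] > 0, betas[1] < betas[2], betas[2] < 1,
            epochs >= 1, batch_size >= 1)
  structure(
    list(learning_rate = learning_rate, betas = betas,
         weight_decay = weight_decay, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "train_config"
  )
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Build a multiview convolutional classifier
#'
#' Instantiates the shared-weight backbone, the cross-view pooling and the
#' fully connected head described by a `model_spec`. One backbone processes
#' every view with the same weights; features are pooled element-wise
#' across the view axis before classification, so the pooled feature
#' dimension is independent of the number of views.
#'
#' @param spec A `model_spec`.
#' @param seed Seed for the weight initialisation.
#' @return An object of class `mvcnn_model`.
#' @export
build_model <- function(spec, seed = 42L) {
  stopifnot(inherits(spec, "model_spec"))
  reg <- backbone_registry()
  row <- reg[reg$backbone == spec$backbone, ]
  if (!row$implemented) {
    stop("backbone '", spec$backbone, "' is a registry stub; ",
         "implemented backbones: ",
         paste(reg$backbone[reg$implemented], collapse = ", "),
         call. = FALSE)
  }
  params <- withr_seed(seed, init_backbone(spec$backbone))
  feat <- as.integer((spec$input_size / 8)^2 * row$top_channels)
  widths <- c(feat, spec$head, spec$n_classes)
  head_params <- withr_seed(seed + 1L, {
    hp <- list()
    for (i in seq_len(length(widths) - 1L)) {
      hp[[paste0("W_head", i)]] <- he_init(c(widths[i], widths[i + 1]),
                                           widths[i])
      hp[[paste0("b_head", i)]] <- numeric(widths[i + 1])
    }
    hp
  })
  structure(
    list(spec = spec, params = c(params, head_params),
         n_head_layers = length(widths) - 1L,
         fitted = FALSE, history = NULL,
         classes = NULL),
    class = "mvcnn_model"
  )
}

init_backbone <- function(backbone) {
  switch(backbone,
    tiny_cnn = list(
      W_conv1 = he_init(c(9 * 1, 8), 9), b_conv1 = numeric(8),
      W_conv2 = he_init(c(9 * 8, 16), 72), b_conv2 = numeric(16),
      W_conv3 = he_init(c(9 * 16, 32), 144), b_conv3 = numeric(32)
    ),
    tiny_resnet = list(
      W_conv1 = he_init(c(9 * 1, 8), 9), b_conv1 = numeric(8),
      W_conv2 = he_init(c(9 * 8, 16), 72), b_conv2 = numeric(16),
      W_conv3 = he_init(c(9 * 16, 16), 144), b_conv3 = numeric(16)
    ),
    tiny_densenet = list(
      W_conv1 = he_init(c(9 * 1, 8), 9), b_conv1 = numeric(8),
      W_conv2 = he_init(c(9 * 8, 16), 72), b_conv2 = numeric(16),
      W_conv3 = he_init(c(9 * 16, 16), 144), b_conv3 = numeric(16)
    )
  )
}

# Backbone forward: x [NV, H, W, 1] -> features [NV, F] + cache.
backbone_forward <- function(params, x, backbone) {
  c1 <- conv3_forward(x, params$W_conv1, params$b_conv1)
  r1 <- relu_forward(c1$out)
  p1 <- maxpool2_forward(r1$out)
  c2 <- conv3_forward(p1$out, params$W_conv2, params$b_conv2)
  r2 <- relu_forward(c2$out)
  p2 <- maxpool2_forward(r2$out)
  c3 <- conv3_forward(p2$out, params$W_conv3, params$b_conv3)
  r3 <- relu_forward(c3$out)
  top <- switch(backbone,
    tiny_cnn = r3$out,
    tiny_resnet = r3$out + p2$out,                  # identity skip
    tiny_densenet = abind4(p2$out, r3$out)          # dense concat
  )
  ap <- avgpool2_forward(top)
  fl <- flatten_forward(ap$out)
  list(out = fl$out,
       cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                    c3 = c3, r3 = r3, ap = ap, fl = fl,
                    backbone = backbone, p2dim = dim(p2$out)))
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

backbone_backward <- function(dfeat, cache, params) {
  dap <- flatten_backward(dfeat, cache$fl$cache)
  dtop <- avgpool2_backward(dap, cache$ap$cache)
  bb <- cache$backbone
  dskip <- NULL
  if (bb == "tiny_cnn") {
    dr3 <- dtop
  } else if (bb == "tiny_resnet") {
    dr3 <- dtop
    dskip <- dtop
  } else {  # tiny_densenet: split the channel concat
    nc <- cache$p2dim[4]
    dskip <- dtop[, , , seq_len(nc), drop = FALSE]
    dr3 <- dtop[, , , nc + seq_len(dim(dtop)[4] - nc), drop = FALSE]
  }
  dc3 <- relu_backward(dr3, cache$r3$cache)
  b3 <- conv3_backward(dc3, cache$c3$cache)
  dp2 <- b3$dx
  if (!is.null(dskip)) dp2 <- dp2 + dskip
  dr2 <- maxpool2_backward(dp2, cache$p2$cache)
  dc2 <- relu_backward(dr2, cache$r2$cache)
  b2 <- conv3_backward(dc2, cache$c2$cache)
  dr1 <- maxpool2_backward(b2$dx, cache$p1$cache)
  dc1 <- relu_backward(dr1, cache$r1$cache)
  b1 <- conv3_backward(dc1, cache$c1$cache)
  list(W_conv1 = b1$dW, b_conv1 = b1$db,
       W_conv2 = b2$dW, b_conv2 = b2$db,
       W_conv3 = b3$dW, b_conv3 = b3$db)
}

# Full forward: x [N, V, H, W] -> logits [N, K] (+ caches when training).
mvcnn_forward <- function(model, x, training = FALSE) {
  dm <- dim(x); N <- dm[1]; V <- dm[2]
  xb <- aperm(x, c(2, 1, 3, 4))              # view index fastest
  dim(xb) <- c(V * N, dm[3], dm[4], 1L)
  bf <- backbone_forward(model$params, xb, model$spec$backbone)
  feat <- bf$out                              # [V*N, F]
  Fdim <- ncol(feat)
  fv <- array(feat, c(V, N, Fdim))
  if (model$spec$pooling == "max") {
    pooled <- fv[1, , , drop = TRUE]
    if (N == 1) pooled <- matrix(pooled, 1, Fdim)
    argv <- matrix(1L, N, Fdim)
    if (V > 1) {
      for (v in 2:V) {
        cur <- matrix(fv[v, , ], N, Fdim)
        upd <- cur > pooled
        pooled[upd] <- cur[upd]
        argv[upd] <- v
      }
    }
    pool_cache <- argv
  } else {
    pooled <- matrix(0, N, Fdim)
    for (v in seq_len(V)) pooled <- pooled + matrix(fv[v, , ], N, Fdim)
    pooled <- pooled / V
    pool_cache <- NULL
  }
  h <- pooled
  head_caches <- list()
  for (i in seq_len(model$n_head_layers)) {
    lf <- linear_forward(h, model$params[[paste0("W_head", i)]],
                         model$params[[paste0("b_head", i)]])
    if (i < model$n_head_layers) {
      rf <- relu_forward(lf$out)
      head_caches[[i]] <- list(lin = lf$cache, relu = rf$cache)
      h <- rf$out
    } else {
      head_caches[[i]] <- list(lin = lf$cache, relu = NULL)
      h <- lf$out
    }
  }
  out <- list(logits = h)
  if (training) {
    out$cache <- list(bf = bf, pool = pool_cache, V = V, N = N,
                      Fdim = Fdim, head = head_caches)
  }
  out
}

mvcnn_backward <- function(model, dlogits, cache) {
  grads <- list()
  dh <- dlogits
  for (i in rev(seq_len(model$n_head_layers))) {
    hc <- cache$head[[i]]
    if (!is.null(hc$relu)) dh <- relu_backward(dh, hc$relu)
    lb <- linear_backward(dh, hc$lin)
    grads[[paste0("W_head", i)]] <- lb$dW
    grads[[paste0("b_head", i)]] <- lb$db
    dh <- lb$dx
  }
  # dh is now the gradient at the pooled features [N, F]
  V <- cache$V; N <- cache$N; Fdim <- cache$Fdim
  dfv <- array(0, c(V, N, Fdim))
  if (model$spec$pooling == "max") {
    argv <- cache$pool
    for (v in seq_len(V)) {
      sel <- argv == v
      dv <- matrix(0, N, Fdim)
      dv[sel] <- dh[sel]
      dfv[v, , ] <- dv
    }
  } else {
    for (v in seq_len(V)) dfv[v, , ] <- dh / V
  }
  dfeat <- matrix(dfv, V * N, Fdim)
  bgrads <- backbone_backward(dfeat, cache$bf$cache, model$params)
  c(grads, bgrads)
}

#' Train a multiview classifier
#'
#' Mini-batch AdamW training with softmax cross-entropy. Deterministic
#' given `config$seed` (shuffling and any dropout-free stochastic parts all
#' draw from the seeded stream).
#'
#' @param model An `mvcnn_model` from [build_model()].
#' @param x Numeric array `[n_samples, n_views, H, W]` of view stacks.
#' @param y Factor (or character) of class labels; its levels define the
#'   logit order.
#' @param config A `train_config`.
#' @return The fitted model, with `$history` (tibble: epoch, loss,
#'   accuracy) and `$classes`.
#' @export
train_mvcnn <- function(model, x, y, config = train_config()) {
  stopifnot(inherits(model, "mvcnn_model"), inherits(config, "train_config"))
  if (!is.array(x) || length(dim(x)) != 4) {
    stop("`x` must be a 4D array [samples, views, H, W]", call. = FALSE)
  }
  y <- as.factor(y)
  if (dim(x)[1] == 0) stop("empty training set", call. = FALSE)
  if (nlevels(y) != model$spec$n_classes) {
    stop("label levels (", nlevels(y), ") do not match model n_classes (",
         model$spec$n_classes, ")", call. = FALSE)
  }
  if (any(table(y) == 0)) {
    warning("class(es) absent from the training set: ",
            paste(levels(y)[table(y) == 0], collapse = ", "))
  }
  if (length(unique(y)) < 2) {
    stop("training data must contain >= 2 classes", call. = FALSE)
  }
  yi <- as.integer(y)
  N <- dim(x)[1]
  params <- model$params
  state <- adamw_init(params)
  hist <- vector("list", config$epochs)
  withr_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(N)
      total_loss <- 0; n_correct <- 0
      for (start in seq(1, N, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, N)]
        xb <- x[idx, , , , drop = FALSE]
        model$params <- params
        fw <- mvcnn_forward(model, xb, training = TRUE)
        sx <- softmax_xent(fw$logits, yi[idx])
        total_loss <- total_loss + sx$loss * length(idx)
        n_correct <- n_correct +
          sum(max.col(sx$probs, ties.method = "first") == yi[idx])
        grads <- mvcnn_backward(model, sx$dlogits, fw$cache)
        upd <- adamw_step(params, grads, state,
                          lr = config$learning_rate,
                          beta1 = config$betas[1], beta2 = config$betas[2],
                          weight_decay = config$weight_decay)
        params <- upd$params
        state <- upd$state
      }
      hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                      loss = total_loss / N,
                                      accuracy = n_correct / N)
    }
  })
  model$params <- params
  model$fitted <- TRUE
  model$classes <- levels(y)
  model$history <- dplyr::bind_rows(hist)
  model$train_config <- config
  model
}

#' Predict from a fitted multiview model
#'
#' @param object An `mvcnn_model`.
#' @param x Array `[n_samples, n_views, H, W]`.
#' @param type `"class"` (factor of labels) or `"prob"` (matrix of softmax
#'   probabilities).
#' @param batch_size Samples per forward pass.
#' @param ... Unused.
#' @return Factor of predicted labels or a probability matrix.
#' @export
predict.mvcnn_model <- function(object, x, type = c("class", "prob"),
                                batch_size = 64L, ...) {
  type <- match.arg(type)
  N <- dim(x)[1]
  probs <- matrix(NA_real_, N, object$spec$n_classes)
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    lg <- mvcnn_forward(object, x[idx, , , , drop = FALSE])$logits
    m <- apply(lg, 1, max)
    z <- exp(lg - m)
    probs[idx, ] <- z / rowSums(z)
  }
  if (type == "prob") {
    colnames(probs) <- object$classes
    return(probs)
  }
  cls <- object$classes %||% as.character(seq_len(object$spec$n_classes))
  factor(cls[max.col(probs, ties.method = "first")], levels = cls)
}

#' Evaluate a classifier on a labelled test set
#'
#' Accuracy is the ratio of correct predictions to the number of test
#' cases; the confusion matrix has true classes in rows and predicted
#' classes in columns, so row sums equal the per-class test counts.
#'
#' @param model A fitted `mvcnn_model`.
#' @param x Array `[n_samples, n_views, H, W]`.
#' @param y True labels.
#' @return An object of class `mvcnn_eval`: `accuracy`, `confusion`,
#'   `n`.
#' @export
evaluate_model <- function(model, x, y) {
  if (dim(x)[1] == 0) stop("empty test set", call. = FALSE)
  cls <- model$classes %||% as.character(seq_len(model$spec$n_classes))
  y <- as.character(y)
  bad <- setdiff(unique(y), cls)
  if (length(bad)) {
    stop("test label(s) outside the model's taxonomy: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  y <- factor(y, levels = cls)
  pred <- predict(model, x)
  confusion <- table(truth = y, prediction = pred)
  structure(
    list(accuracy = mean(pred == y), confusion = confusion,
         n = length(y)),
    class = "mvcnn_eval"
  )
}

#' @export
print.mvcnn_eval <- function(x, ...) {
  cat(sprintf("<mvcnn_eval> accuracy %.3f on %d samples\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' @export
print.mvcnn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<mvcnn_model %s> %d views -> %d classes, %s pooling, %d parameters%s\n",
              x$spec$backbone, x$spec$n_views, x$spec$n_classes,
              x$spec$pooling, np,
              if (x$fitted) " (fitted)" else " (untrained)"))
  invisible(x)
}

#' Tidy the training history of a fitted model
#'
#' @param x A fitted `mvcnn_model`.
#' @param ... Unused.
#' @return Tibble with columns epoch, loss, accuracy.
#' @export
tidy.mvcnn_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), loss = numeric(),
                                accuracy = numeric())
}

#' One-row summary of a fitted model
#'
#' @param x A fitted `mvcnn_model`.
#' @param ... Unused.
#' @return One-row tibble: backbone, n_views, n_classes, n_parameters,
#'   epochs, final_loss, final_accuracy.
#' @export
glance.mvcnn_model <- function(x, ...) {
  h <- tidy(x)
  tibble::tibble(
    backbone = x$spec$backbone,
    n_views = x$spec$n_views,
    n_classes = x$spec$n_classes,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    epochs = nrow(h),
    final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
    final_accuracy = if (nrow(h)) h$accuracy[nrow(h)] else NA_real_
  )
}

#' Tidy an evaluation result
#'
#' @param x An `mvcnn_eval`.
#' @param ... Unused.
#' @return Tibble of the confusion matrix in long form (truth, prediction,
#'   n).
#' @export
tidy.mvcnn_eval <- function(x, ...) {
  df <- as.data.frame(x$confusion)
  tibble::tibble(truth = df$truth, prediction = df$prediction,
                 n = df$Freq)
}

#' @rdname tidy.mvcnn_eval
#' @export
glance.mvcnn_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = x$n)
}

#' Plot the training history
#'
#' @param object A fitted `mvcnn_model`.
#' @param ... Unused.
#' @return A ggplot object with loss and training-accuracy curves.
#' @export
autoplot.mvcnn_model <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("loss", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = paste("Training history,", object$spec$backbone))
}

#' Assemble the model-input array for a set of samples
#'
#' Builds each sample's view stack (clutter suppression, profile
#' extraction, echo-map generation, per-view min-max) and resizes every
#' view to the model input size, returning the 4D array consumed by
#' [train_mvcnn()].
#'
#' @param samples List of `sample_record`.
#' @param placement Named list of `radar_spec`.
#' @param grid A `grid_spec`.
#' @param mask Ensemble mask (see [build_view_stack()]).
#' @param input_size Output side length in pixels.
#' @param ... Passed to [build_view_stack()].
#' @return List: `x` (array `[N, V, input_size, input_size]`), `radar_ids`.
#' @export
stack_views_array <- function(samples, placement, grid, mask = NULL,
                              input_size = 32L, ...) {
  geom_cache <- precompute_geometry(placement, grid)
  first <- build_view_stack(samples[[1]], placement, grid, mask = mask,
                            geom_cache = geom_cache, ...)
  V <- length(first$views)
  N <- length(samples)
  x <- array(0, c(N, V, input_size, input_size))
  fill <- function(k, st) {
    for (v in seq_len(V)) {
      x[k, v, , ] <<- resize_bilinear(st$views[[v]]$values, input_size)
    }
  }
  fill(1, first)
  if (N > 1) {
    for (k in 2:N) {
      st <- build_view_stack(samples[[k]], placement, grid, mask = mask,
                             geom_cache = geom_cache, ...)
      fill(k, st)
    }
  }
  list(x = x, radar_ids = first$radar_ids)
}
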