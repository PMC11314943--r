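# Minimal vectorised neural-network layers used by the multiview network.
# Tensors are 4D arrays [N, H, W, C] (batch, rows, cols, channels); dense
# activations are matrices [N, F]. Convolutions use the im2col strategy:
# unfold 3x3 neighbourhoods into a tall matrix so the convolution is a
# single matrix product, with the exact adjoint (col2im scatter-add) used
# in the backward pass.

# -- im2col / col2im for 3x3 'same' convolutions -----------------------------

im2col3 <- function(x) {
  dm <- dim(x); N <- dm[1]; H <- dm[2]; W <- dm[3]; C <- dm[4]
  xp <- array(0, c(N, H + 2L, W + 2L, C))
  xp[, 2:(H + 1L), 2:(W + 1L), ] <- x
  cols <- matrix(0, N * H * W, 9L * C)
  k <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      patch <- xp[, di + seq_len(H), dj + seq_len(W), , drop = FALSE]
      cols[, k * C + seq_len(C)] <- matrix(patch, N * H * W, C)
      k <- k + 1L
    }
  }
  cols
}

col2im3 <- function(dcols, N, H, W, C) {
  dxp <- array(0, c(N, H + 2L, W + 2L, C))
  k <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      patch <- array(dcols[, k * C + seq_len(C)], c(N, H, W, C))
      dxp[, di + seq_len(H), dj + seq_len(W), ] <-
        dxp[, di + seq_len(H), dj + seq_len(W), , drop = FALSE] + patch
      k <- k + 1L
    }
  }
  dxp[, 2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

# -- layers ------------------------------------------------------------------

conv3_forward <- function(x, W, b) {
  dm <- dim(x)
  cols <- im2col3(x)
  out <- sweep(cols %*% W, 2, b, `+`)
  list(out = array(out, c(dm[1], dm[2], dm[3], length(b))),
       cache = list(cols = cols, dims = dm, W = W))
}

conv3_backward <- function(dout, cache) {
  dm <- cache$dims
  dmat <- matrix(dout, dm[1] * dm[2] * dm[3], dim(dout)[4])
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, cache$W)
  dx <- col2im3(dcols, dm[1], dm[2], dm[3], dm[4])
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(dout, mask) dout * mask

maxpool2_forward <- function(x) {
  dm <- dim(x); H <- dm[2]; W <- dm[3]
  i1 <- seq(1L, H - 1L, by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, W - 1L, by = 2L); j2 <- j1 + 1L
  a <- x[, i1, j1, , drop = FALSE]; b <- x[, i2, j1, , drop = FALSE]
  d <- x[, i1, j2, , drop = FALSE]; e <- x[, i2, j2, , drop = FALSE]
  out <- pmax(a, b, d, e)
  list(out = out,
       cache = list(masks = list(a == out, b == out & a < out,
                                 d == out & a < out & b < out,
                                 e == out & a < out & b < out & d < out),
                    dims = dm, i1 = i1, i2 = i2, j1 = j1, j2 = j2))
}

maxpool2_backward <- function(dout, cache) {
  dx <- array(0, cache$dims)
  dx[, cache$i1, cache$j1, ] <- dout * cache$masks[[1]]
  dx[, cache$i2, cache$j1, ] <- dout * cache$masks[[2]]
  dx[, cache$i1, cache$j2, ] <- dout * cache$masks[[3]]
  dx[, cache$i2, cache$j2, ] <- dout * cache$masks[[4]]
  dx
}

gap_forward <- function(x) {
  dm <- dim(x)
  # mean over H and W -> [N, C]
  out <- apply(x, c(1, 4), mean)
  list(out = matrix(out, dm[1], dm[4]), cache = dm)
}

gap_backward <- function(dout, dm) {
  scale <- 1 / (dm[2] * dm[3])
  # broadcast [N, C] gradient over the spatial positions
  aperm(array(dout * scale, c(dm[1], dm[4], dm[2], dm[3])), c(1, 3, 4, 2))
}

# 2x2 average pooling (used as the adaptive pool before the flatten).
avgpool2_forward <- function(x) {
  dm <- dim(x); H <- dm[2]; W <- dm[3]
  i1 <- seq(1L, H - 1L, by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, W - 1L, by = 2L); j2 <- j1 + 1L
  out <- (x[, i1, j1, , drop = FALSE] + x[, i2, j1, , drop = FALSE] +
          x[, i1, j2, , drop = FALSE] + x[, i2, j2, , drop = FALSE]) / 4
  list(out = out, cache = list(dims = dm, i1 = i1, i2 = i2, j1 = j1,
                               j2 = j2))
}

avgpool2_backward <- function(dout, cache) {
  dx <- array(0, cache$dims)
  g <- dout / 4
  dx[, cache$i1, cache$j1, ] <- g
  dx[, cache$i2, cache$j1, ] <- g
  dx[, cache$i1, cache$j2, ] <- g
  dx[, cache$i2, cache$j2, ] <- g
  dx
}

flatten_forward <- function(x) {
  dm <- dim(x)
  list(out = matrix(x, dm[1], prod(dm[-1])), cache = dm)
}

flatten_backward <- function(dout, dm) array(dout, dm)

linear_forward <- function(x, W, b) {
  list(out = sweep(x %*% W, 2, b, `+`), cache = list(x = x, W = W))
}

linear_backward <- function(dout, cache) {
  list(dx = tcrossprod(dout, cache$W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

# Softmax cross-entropy: logits [N, K], y integer class 1..K.
softmax_xent <- function(logits, y) {
  m <- apply(logits, 1, max)
  z <- exp(logits - m)
  p <- z / rowSums(z)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

# -- AdamW -------------------------------------------------------------------

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Decoupled weight decay: applied to weight matrices/arrays, not biases.
adamw_step <- function(params, grads, state, lr, beta1, beta2,
                       eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- mhat / (sqrt(vhat) + eps)
    if (!grepl("^b", nm)) upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}
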