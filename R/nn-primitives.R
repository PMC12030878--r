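# Low-level neural-network primitives on (H, W, C, N) arrays.
# Convolutions are im2col + BLAS matrix products; every op has a matching
# backward pass. Nothing here is specific to the camera: it is the minimal
# layer set the spectrum-translation U-Net needs (conv2d, batch norm, ReLU,
# dense), with Adam as the optimizer.

zero_pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

crop_pad_hw <- function(xp, pad, h, w) {
  if (pad == 0L) return(xp)
  xp[pad + seq_len(h), pad + seq_len(w), , , drop = FALSE]
}

# Patch-extraction index cache: im2col/col2im are pure index gathers and
# scatter-adds; the (layer-shape-dependent) linear index array is built once
# and reused across every training step.
.idx_cache <- new.env(parent = emptyenv())

im2col_index <- function(dims_pad, k, out_h, out_w) {
  key <- paste(c(dims_pad, k, out_h, out_w), collapse = "_")
  idx <- .idx_cache[[key]]
  if (!is.null(idx)) return(idx)
  Hp <- dims_pad[1]; Wp <- dims_pad[2]; C <- dims_pad[3]; N <- dims_pad[4]
  # target layout: rows (C, k2), cols (P, N); element (c, di, dj, p_i, p_j, n)
  # reads xp[p_i + di, p_j + dj, c, n]
  di <- rep(seq_len(k), times = k)                # within-row offset
  dj <- rep(seq_len(k), each = k)
  rows_i <- outer(di, seq_len(out_h), "+") - 1L   # (k2, out_h), 0-based
  rows_j <- outer(dj, seq_len(out_w), "+") - 1L
  # linear index into (Hp, Wp, C, N)
  base <- array(0L, c(C, k * k, out_h * out_w))
  for (c in seq_len(C)) {
    off_c <- (c - 1L) * Hp * Wp
    ii <- array(rows_i, c(k * k, out_h, out_w))
    jj <- aperm(array(rows_j, c(k * k, out_w, out_h)), c(1L, 3L, 2L))
    base[c, , ] <- matrix((ii - 1L) + (jj - 1L) * Hp + off_c + 1L,
                          k * k, out_h * out_w)
  }
  dim(base) <- c(C * k * k, out_h * out_w)
  per_sample <- Hp * Wp * C
  idx <- base[, rep(seq_len(ncol(base)), N)] +
    rep((seq_len(N) - 1L) * per_sample, each = nrow(base) * ncol(base))
  dim(idx) <- c(C * k * k, out_h * out_w * N)
  .idx_cache[[key]] <- idx
  idx
}

# (H,W,C,N), kernel k -> matrix (C*k^2, P*N), P = out_h*out_w
im2col <- function(xp, k, out_h, out_w) {
  idx <- im2col_index(dim(xp), k, out_h, out_w)
  X <- xp[idx]
  dim(X) <- dim(idx)
  X
}

# static scatter-add plan per layer shape: sort order + segment bounds
col2im_plan <- function(dims_pad, k, out_h, out_w) {
  key <- paste(c("p", dims_pad, k, out_h, out_w), collapse = "_")
  plan <- .idx_cache[[key]]
  if (!is.null(plan)) return(plan)
  idx <- as.vector(im2col_index(dims_pad, k, out_h, out_w))
  ord <- order(idx)
  sorted <- idx[ord]
  ends <- c(which(diff(sorted) != 0L), length(sorted))
  plan <- list(ord = ord, ends = ends, targets = sorted[ends])
  .idx_cache[[key]] <- plan
  plan
}

col2im <- function(dX, k, out_h, out_w, dims_pad) {
  plan <- col2im_plan(dims_pad, k, out_h, out_w)
  cs <- cumsum(dX[plan$ord])
  sums <- cs[plan$ends] - c(0, cs[plan$ends[-length(plan$ends)]])
  dxp <- array(0, dims_pad)
  dxp[plan$targets] <- sums
  dxp
}

conv2d_forward <- function(x, W, b, pad) {
  d <- dim(x)
  k <- as.integer(round(sqrt(ncol(W) / d[3])))
  out_h <- d[1] - k + 1L + 2L * pad
  out_w <- d[2] - k + 1L + 2L * pad
  if (out_h < 1 || out_w < 1) stop("convolution output size is empty")
  xp <- zero_pad_hw(x, pad)
  X <- im2col(xp, k, out_h, out_w)
  Y <- W %*% X + b                     # (C_out, P*N)
  C_out <- nrow(W); N <- d[4]
  dim(Y) <- c(C_out, out_h * out_w, N)
  y <- aperm(Y, c(2L, 1L, 3L))
  dim(y) <- c(out_h, out_w, C_out, N)
  list(y = y, cache = list(X = X, dims = d, dims_pad = dim(xp), k = k,
                           pad = pad, out_h = out_h, out_w = out_w))
}

conv2d_backward <- function(dy, W, cache) {
  d <- dim(dy)                         # (out_h, out_w, C_out, N)
  dY <- aperm(dy, c(3L, 1L, 2L, 4L))
  dim(dY) <- c(d[3], d[1] * d[2] * d[4])
  dW <- tcrossprod(dY, cache$X)
  db <- rowSums(dY)
  dX <- crossprod(W, dY)
  dxp <- col2im(dX, cache$k, cache$out_h, cache$out_w, cache$dims_pad)
  dx <- crop_pad_hw(dxp, cache$pad, cache$dims[1], cache$dims[2])
  list(dx = dx, dW = dW, db = db)
}

bn_forward <- function(x, gamma, beta, running, training,
                       eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  M <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(M) <- c(d[1] * d[2] * d[4], d[3])
  if (training) {
    mu <- colMeans(M)
    va <- colMeans(M^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * va
  } else {
    mu <- running$mean
    va <- running$var
  }
  sd_inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(M, 2L, mu, "-"), 2L, sd_inv, "*")
  Y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  dim(Y) <- c(d[1], d[2], d[4], d[3])
  y <- aperm(Y, c(1L, 2L, 4L, 3L))
  list(y = y, running = running,
       cache = list(xhat = xhat, sd_inv = sd_inv, dims = d,
                    training = training))
}

bn_backward <- function(dy, gamma, cache) {
  d <- cache$dims
  D <- aperm(dy, c(1L, 2L, 4L, 3L))
  dim(D) <- c(d[1] * d[2] * d[4], d[3])
  dgamma <- colSums(D * cache$xhat)
  dbeta <- colSums(D)
  Dg <- sweep(D, 2L, gamma, "*")
  if (cache$training) {
    m <- nrow(D)
    dXhat_mean <- colMeans(Dg)
    dXhatXhat_mean <- colMeans(Dg * cache$xhat)
    dM <- sweep(
      Dg - matrix(dXhat_mean, m, length(dXhat_mean), byrow = TRUE) -
        cache$xhat *
        matrix(dXhatXhat_mean, m, length(dXhatXhat_mean), byrow = TRUE),
      2L, cache$sd_inv, "*")
  } else {
    dM <- sweep(Dg, 2L, cache$sd_inv, "*")
  }
  dim(dM) <- c(d[1], d[2], d[4], d[3])
  dx <- aperm(dM, c(1L, 2L, 4L, 3L))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

relu_backward <- function(dy, mask) dy * mask

dense_forward <- function(x, W, b) {
  d <- dim(x)
  M <- x
  dim(M) <- c(prod(d[1:3]), d[4])
  Y <- W %*% M + b
  y <- Y
  dim(y) <- c(d[1], d[2], d[3], d[4])
  list(y = y, cache = list(M = M, dims = d))
}

dense_backward <- function(dy, W, cache) {
  d <- cache$dims
  D <- dy
  dim(D) <- c(prod(d[1:3]), d[4])
  list(dx = {
    dx <- crossprod(W, D)
    dim(dx) <- d
    dx
  }, dW = tcrossprod(D, cache$M), db = rowSums(D))
}

# channelwise bottleneck: one (P x P) map shared by all channels
chdense_forward <- function(x, W, b) {
  d <- dim(x)
  M <- x
  dim(M) <- c(d[1] * d[2], d[3] * d[4])
  Y <- W %*% M + b
  dim(Y) <- d
  list(y = Y, cache = list(M = M, dims = d))
}

chdense_backward <- function(dy, W, cache) {
  d <- cache$dims
  D <- dy
  dim(D) <- c(d[1] * d[2], d[3] * d[4])
  list(dx = {
    dx <- crossprod(W, D)
    dim(dx) <- d
    dx
  }, dW = tcrossprod(D, cache$M), db = rowSums(D))
}

uniform_init <- function(nr, nc, fan_in) {
  bound <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -bound, bound), nr, nc)
}

adam_state <- function(param) {
  lapply(param, function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(param, grad, state, step, lr, beta1, beta2,
                        eps = 1e-8) {
  for (nm in names(param)) {
    g <- grad[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^step)
    vhat <- st$v / (1 - beta2^step)
    param[[nm]] <- param[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(param = param, state = state)
}
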