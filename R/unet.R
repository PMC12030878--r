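#' U-Net architecture specification
#'
#' Describes the pair's shared architecture: four compression steps with
#' shrinking filters (9/7/5/3) and paddings (2/2/1/0) that reduce the
#' 17x17 spectrum to 7x7 without pooling while growing the feature count
#' (32/64/128/256 at full scale); a linear bottleneck; four decompression
#' steps (filter 3, paddings 2/2/2/3) whose inputs are the channel
#' concatenation of the previous output and the same-size compression
#' output; batch-normalization-then-ReLU before each convolution (the
#' first block omits the ReLU on the raw signed input); and a final
#' 1-feature 1x1 projection. The spatial arithmetic `out = in - k + 1 +
#' 2p` is validated at construction and must restore 17x17 at the output.
#'
#' @param features Feature counts of the four compression steps.
#' @param kernels Filter sizes of the compression steps (decompression
#'   always uses 3).
#' @param enc_pads,dec_pads Paddings of the compression/decompression
#'   steps.
#' @param input_size Side of the (square) input map, default 17.
#' @param bottleneck `"dense"` (flatten, fully connected, reshape) or
#'   `"channelwise"` (one 49x49 map shared across channels).
#' @return A `unet_spec` with the validated size trace.
#' @examples
#' unet_spec()$sizes  # 13 11 9 7 | 7 | 9 11 13 17
#' @export
unet_spec <- function(features = c(32L, 64L, 128L, 256L),
                      kernels = c(9L, 7L, 5L, 3L),
                      enc_pads = c(2L, 2L, 1L, 0L),
                      dec_pads = c(2L, 2L, 2L, 3L),
                      input_size = 17L,
                      bottleneck = c("dense", "channelwise")) {
  bottleneck <- match.arg(bottleneck)
  stopifnot(length(features) == 4, length(kernels) == 4,
            length(enc_pads) == 4, length(dec_pads) == 4)
  enc_sizes <- integer(4)
  s <- as.integer(input_size)
  for (i in 1:4) {
    s <- s - kernels[i] + 1L + 2L * enc_pads[i]
    if (s < 1L) {
      stop(sprintf("compression step %d collapses the map (size %d)", i, s))
    }
    enc_sizes[i] <- s
  }
  dec_sizes <- integer(4)
  for (i in 1:4) {
    s <- s - 3L + 1L + 2L * dec_pads[i]
    dec_sizes[i] <- s
  }
  if (dec_sizes[4] != input_size) {
    stop(sprintf("decompression step 9 emits %dx%d, expected %dx%d",
                 dec_sizes[4], dec_sizes[4], input_size, input_size))
  }
  # skip connections concatenate same-size maps: d6 in pairs with enc4,
  # d7 with enc3, d8 with enc2, d9 with enc1
  skip_in <- c(enc_sizes[4], dec_sizes[1:3])
  skip_enc <- c(enc_sizes[4], enc_sizes[3:1])
  bad <- which(skip_in != skip_enc)
  if (length(bad)) {
    stop(sprintf("skip connection at decompression step %d pairs %dx%d %s",
                 5L + bad[1], skip_in[bad[1]], skip_in[bad[1]],
                 sprintf("with %dx%d", skip_enc[bad[1]], skip_enc[bad[1]])))
  }
  structure(list(
    features = as.integer(features), kernels = as.integer(kernels),
    enc_pads = as.integer(enc_pads), dec_pads = as.integer(dec_pads),
    input_size = as.integer(input_size), bottleneck = bottleneck,
    enc_sizes = enc_sizes, dec_sizes = dec_sizes,
    sizes = c(enc_sizes, enc_sizes[4], dec_sizes)
  ), class = "unet_spec")
}

#' @export
print.unet_spec <- function(x, ...) {
  cat("<unet_spec>\n")
  cat("  compression:  ", paste(sprintf("%dx%d/%d", x$enc_sizes,
                                        x$enc_sizes, x$features),
                                collapse = " "), "\n")
  cat("  bottleneck:   ", sprintf("%s on %dx%dx%d", x$bottleneck,
                                  x$enc_sizes[4], x$enc_sizes[4],
                                  x$features[4]), "\n")
  cat("  decompression:", paste(sprintf("%dx%d", x$dec_sizes, x$dec_sizes),
                                collapse = " "), "\n")
  invisible(x)
}

new_conv_block <- function(c_in, c_out, k, pad, relu = TRUE, bn = TRUE) {
  fan_in <- c_in * k * k
  list(type = "conv_block", relu = relu, bn = bn, pad = as.integer(pad),
       param = c(
         if (bn) list(gamma = rep(1, c_in), beta = rep(0, c_in)),
         list(W = uniform_init(c_out, c_in * k * k, fan_in),
              b = stats::runif(c_out, -1 / sqrt(fan_in), 1 / sqrt(fan_in)))
       ),
       running = if (bn) list(mean = rep(0, c_in), var = rep(1, c_in)))
}

new_bottleneck <- function(spec) {
  P <- spec$enc_sizes[4]^2
  C <- spec$features[4]
  if (spec$bottleneck == "dense") {
    n <- P * C
    list(type = "dense_block", channelwise = FALSE, bn = TRUE, relu = TRUE,
         param = list(gamma = rep(1, C), beta = rep(0, C),
                      W = uniform_init(n, n, n),
                      b = stats::runif(n, -1 / sqrt(n), 1 / sqrt(n))),
         running = list(mean = rep(0, C), var = rep(1, C)))
  } else {
    list(type = "dense_block", channelwise = TRUE, bn = TRUE, relu = TRUE,
         param = list(gamma = rep(1, C), beta = rep(0, C),
                      W = uniform_init(P, P, P),
                      b = stats::runif(P, -1 / sqrt(P), 1 / sqrt(P))),
         running = list(mean = rep(0, C), var = rep(1, C)))
  }
}

#' Build one U-Net from a specification
#'
#' Initializes all weights from the seeded default scheme (uniform on
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`); two builds with the same seed
#' produce identical networks.
#'
#' @param spec A [unet_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A `unet` object.
#' @export
build_unet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  f <- spec$features
  withr_rng(seed, function() {
    layers <- list(
      enc1 = new_conv_block(1L, f[1], spec$kernels[1], spec$enc_pads[1],
                            relu = FALSE),
      enc2 = new_conv_block(f[1], f[2], spec$kernels[2], spec$enc_pads[2]),
      enc3 = new_conv_block(f[2], f[3], spec$kernels[3], spec$enc_pads[3]),
      enc4 = new_conv_block(f[3], f[4], spec$kernels[4], spec$enc_pads[4]),
      bottleneck = new_bottleneck(spec),
      dec6 = new_conv_block(2L * f[4], f[3], 3L, spec$dec_pads[1]),
      dec7 = new_conv_block(2L * f[3], f[2], 3L, spec$dec_pads[2]),
      dec8 = new_conv_block(2L * f[2], f[1], 3L, spec$dec_pads[3]),
      dec9 = new_conv_block(2L * f[1], f[1], 3L, spec$dec_pads[4]),
      head = new_conv_block(f[1], 1L, 1L, 0L, relu = FALSE, bn = FALSE)
    )
    structure(list(spec = spec, layers = layers, seed = seed),
              class = "unet")
  })
}

#' @export
print.unet <- function(x, ...) {
  np <- sum(vapply(x$layers,
                   function(l) sum(lengths(l$param)), numeric(1)))
  cat(sprintf("<unet> %s bottleneck, %s parameters\n", x$spec$bottleneck,
              format(np, big.mark = ",")))
  print(x$spec)
  invisible(x)
}

block_forward <- function(net, name, x, training) {
  layer <- net$layers[[name]]
  cache <- list()
  if (isTRUE(layer$bn)) {
    bn <- bn_forward(x, layer$param$gamma, layer$param$beta,
                     layer$running, training)
    x <- bn$y
    cache$bn <- bn$cache
    net$layers[[name]]$running <- bn$running
  }
  if (isTRUE(layer$relu)) {
    r <- relu_forward(x)
    x <- r$y
    cache$relu <- r$cache
  }
  if (layer$type == "conv_block") {
    cv <- conv2d_forward(x, layer$param$W, layer$param$b, layer$pad)
  } else if (isTRUE(layer$channelwise)) {
    cv <- chdense_forward(x, layer$param$W, layer$param$b)
  } else {
    cv <- dense_forward(x, layer$param$W, layer$param$b)
  }
  cache$main <- cv$cache
  list(y = cv$y, cache = cache, net = net)
}

block_backward <- function(net, name, cache, dy) {
  layer <- net$layers[[name]]
  if (layer$type == "conv_block") {
    bk <- conv2d_backward(dy, layer$param$W, cache$main)
  } else if (isTRUE(layer$channelwise)) {
    bk <- chdense_backward(dy, layer$param$W, cache$main)
  } else {
    bk <- dense_backward(dy, layer$param$W, cache$main)
  }
  grad <- list(W = bk$dW, b = bk$db)
  dx <- bk$dx
  if (!is.null(cache$relu)) dx <- relu_backward(dx, cache$relu)
  if (!is.null(cache$bn)) {
    bb <- bn_backward(dx, layer$param$gamma, cache$bn)
    dx <- bb$dx
    grad$gamma <- bb$dgamma
    grad$beta <- bb$dbeta
  }
  list(dx = dx, grad = grad)
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Forward pass of one U-Net
#'
#' @param net A [build_unet()] network.
#' @param x Input array `(H, W, 1, N)` or a single `H x W` matrix.
#' @param training Use batch statistics (and cache for backprop) when
#'   `TRUE`; running statistics when `FALSE`.
#' @return List with `out` (same shape as `x`), `cache` (when training),
#'   and the updated `net` (running BN statistics).
#' @export
unet_forward <- function(net, x, training = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  stopifnot(length(dim(x)) == 4)
  caches <- list()
  acts <- list()
  h <- x
  for (nm in c("enc1", "enc2", "enc3", "enc4")) {
    st <- block_forward(net, nm, h, training)
    net <- st$net; caches[[nm]] <- st$cache; h <- st$y
    acts[[nm]] <- h
  }
  st <- block_forward(net, "bottleneck", h, training)
  net <- st$net; caches$bottleneck <- st$cache; h <- st$y
  skips <- c("enc4", "enc3", "enc2", "enc1")
  decs <- c("dec6", "dec7", "dec8", "dec9")
  for (i in 1:4) {
    hin <- concat_c(h, acts[[skips[i]]])
    caches[[paste0(decs[i], "_split")]] <- dim(h)[3]
    st <- block_forward(net, decs[i], hin, training)
    net <- st$net; caches[[decs[i]]] <- st$cache; h <- st$y
  }
  st <- block_forward(net, "head", h, training)
  net <- st$net; caches$head <- st$cache
  list(out = st$y, cache = if (training) caches, net = net)
}

#' Backward pass of one U-Net
#' @param net Network used in the forward pass.
#' @param cache Cache returned by [unet_forward()] with `training = TRUE`.
#' @param dout Gradient of the loss w.r.t. the output array.
#' @return List of per-layer gradients.
#' @keywords internal
unet_backward <- function(net, cache, dout) {
  grads <- list()
  bk <- block_backward(net, "head", cache$head, dout)
  grads$head <- bk$grad
  dh <- bk$dx
  skips <- c("enc1", "enc2", "enc3", "enc4")
  dskip <- list(enc1 = 0, enc2 = 0, enc3 = 0, enc4 = 0)
  for (i in 4:1) {
    nm <- c("dec6", "dec7", "dec8", "dec9")[i]
    bk <- block_backward(net, nm, cache[[nm]], dh)
    grads[[nm]] <- bk$grad
    nsplit <- cache[[paste0(nm, "_split")]]
    dh <- bk$dx[, , seq_len(nsplit), , drop = FALSE]
    sk <- skips[5L - i]
    dskip[[sk]] <- bk$dx[, , nsplit + seq_len(dim(bk$dx)[3] - nsplit), ,
                         drop = FALSE]
  }
  bk <- block_backward(net, "bottleneck", cache$bottleneck, dh)
  grads$bottleneck <- bk$grad
  dh <- bk$dx + dskip$enc4
  for (nm in c("enc4", "enc3", "enc2", "enc1")) {
    bk <- block_backward(net, nm, cache[[nm]], dh)
    grads[[nm]] <- bk$grad
    dh <- bk$dx
    if (nm != "enc1") dh <- dh + dskip[[skips[match(nm, skips) - 1L]]]
  }
  grads
}

#' Weighted mean absolute percentage error
#'
#' Sum of absolute prediction errors over all entries divided by the sum
#' of absolute reference values; scale-invariant
#' (`wmape(a*p, a*r) = wmape(p, r)` for `a != 0`) and equal to 1 for an
#' all-zero prediction.
#' @param predicted,reference Numeric arrays of identical shape.
#' @return Scalar loss.
#' @export
wmape_loss <- function(predicted, reference) {
  if (!all(dim(predicted) %||% length(predicted) ==
           dim(reference) %||% length(reference))) {
    stop("predicted and reference must have identical shape")
  }
  denom <- sum(abs(reference))
  if (denom == 0) stop("reference is identically zero: WMAPE undefined")
  sum(abs(predicted - reference)) / denom
}

`%||%` <- function(a, b) if (is.null(a)) b else a

wmape_grad <- function(predicted, reference) {
  sign(predicted - reference) / sum(abs(reference))
}
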