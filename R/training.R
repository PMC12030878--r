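#' Build the pair of identical U-Nets
#'
#' One network optimizes the real part of the spectrum, the second the
#' imaginary part; they share the architecture and differ only in their
#' initialization seeds.
#' @param spec A [unet_spec()].
#' @param seed Base seed (real net uses `seed`, imaginary net `seed + 1`).
#' @return A `unet_pair`.
#' @export
unet_pair <- function(spec = unet_spec(), seed = 1L) {
  structure(list(re = build_unet(spec, seed),
                 im = build_unet(spec, seed + 1L),
                 spec = spec, seed = seed, trained = FALSE),
            class = "unet_pair")
}

#' @export
print.unet_pair <- function(x, ...) {
  cat("<unet_pair>", if (x$trained) "(trained)" else "(untrained)", "\n")
  print(x$spec)
  invisible(x)
}

stack_batch <- function(mats) {
  h <- nrow(mats[[1]])
  array(unlist(mats), c(h, ncol(mats[[1]]), 1L, length(mats)))
}

train_one_net <- function(net, inputs, targets, mask, epochs, batch_size,
                          lr, beta1, beta2, seed,
                          val_inputs = NULL, val_targets = NULL) {
  n <- length(inputs)
  state <- lapply(net$layers, function(l) adam_state(l$param))
  step <- 0L
  mask_n <- function(N) array(rep(mask, N), c(dim(mask), 1L, N))
  train_curve <- val_curve <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- withr_rng(seed * 1000L + ep, function() sample.int(n))
    starts <- seq(1L, n, by = batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1L, n)]
      x <- stack_batch(inputs[idx])
      r <- stack_batch(targets[idx])
      mk <- mask_n(length(idx))
      fw <- unet_forward(net, x, training = TRUE)
      net <- fw$net
      pred <- fw$out * mk
      losses[bi] <- wmape_loss(pred, r)
      if (!is.finite(losses[bi])) {
        stop(sprintf("non-finite loss at epoch %d batch %d", ep, bi))
      }
      dout <- mk * wmape_grad(pred, r)
      grads <- unet_backward(net, fw$cache, dout)
      step <- step + 1L
      for (nm in names(net$layers)) {
        upd <- adam_update(net$layers[[nm]]$param, grads[[nm]],
                           state[[nm]], step, lr, beta1, beta2)
        net$layers[[nm]]$param <- upd$param
        state[[nm]] <- upd$state
      }
    }
    train_curve[ep] <- mean(losses)
    if (!is.null(val_inputs)) {
      val_curve[ep] <- eval_loss(net, val_inputs, val_targets, mask,
                                 batch_size)
    }
  }
  list(net = net, train_curve = train_curve,
       val_curve = if (!is.null(val_inputs)) val_curve)
}

eval_loss <- function(net, inputs, targets, mask, batch_size = 16L) {
  n <- length(inputs)
  tot_err <- tot_ref <- 0
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    x <- stack_batch(inputs[idx])
    r <- stack_batch(targets[idx])
    mk <- array(rep(mask, length(idx)), c(dim(mask), 1L, length(idx)))
    pred <- unet_forward(net, x, training = FALSE)$out * mk
    tot_err <- tot_err + sum(abs(pred - r))
    tot_ref <- tot_ref + sum(abs(r))
  }
  tot_err / tot_ref
}

#' Train the U-Net pair on a normalized dataset
#'
#' The real-part network trains on `(Re j_norm -> Re C_norm)` and the
#' imaginary-part network on the imaginary parts, with the half-visible
#' mask applied to both the network input and output before the WMAPE
#' loss (Adam, batches of three, 30 epochs at the reference settings).
#' Per-epoch mean losses are recorded for the training set and, when
#' given, the validation set. Deterministic for fixed seeds.
#'
#' @param pair A [unet_pair()].
#' @param dataset List of samples, each with 17x17 complex `jnorm` and
#'   `Cnorm` matrices (or `current_spectrum` objects) and logical `mask`.
#' @param epochs,batch_size,lr,beta1,beta2 Training hyperparameters
#'   (defaults: 30, 3, 1e-3, 0.9, 0.999).
#' @param seed Shuffling seed.
#' @param validation Optional validation sample list for per-epoch loss.
#' @return The trained `unet_pair` with a `history` data.frame (epoch,
#'   train/validation loss for the real and imaginary nets).
#' @export
train_unet_pair <- function(pair, dataset, epochs = 30L, batch_size = 3L,
                            lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                            seed = 1L, validation = NULL) {
  stopifnot(inherits(pair, "unet_pair"))
  if (length(dataset) == 0) stop("empty training dataset")
  pull <- function(ds, part) lapply(ds, function(s) {
    v <- sample_values(s$jnorm)
    if (part == "re") Re(v) else Im(v)
  })
  pull_ref <- function(ds, part) lapply(ds, function(s) {
    v <- sample_values(s$Cnorm)
    if (part == "re") Re(v) else Im(v)
  })
  mask <- sample_mask(dataset[[1]])
  res_re <- train_one_net(pair$re, pull(dataset, "re"),
                          pull_ref(dataset, "re"), mask, epochs,
                          batch_size, lr, beta1, beta2, seed,
                          if (!is.null(validation)) pull(validation, "re"),
                          if (!is.null(validation))
                            pull_ref(validation, "re"))
  res_im <- train_one_net(pair$im, pull(dataset, "im"),
                          pull_ref(dataset, "im"), mask, epochs,
                          batch_size, lr, beta1, beta2, seed + 1L,
                          if (!is.null(validation)) pull(validation, "im"),
                          if (!is.null(validation))
                            pull_ref(validation, "im"))
  pair$re <- res_re$net
  pair$im <- res_im$net
  pair$trained <- TRUE
  pair$history <- data.frame(
    epoch = seq_len(epochs),
    train_re = res_re$train_curve, train_im = res_im$train_curve,
    val_re = res_re$val_curve %||% NA_real_,
    val_im = res_im$val_curve %||% NA_real_
  )
  pair
}

sample_values <- function(x) {
  if (inherits(x, "current_spectrum")) x$values else x
}

sample_mask <- function(s) {
  if (!is.null(s$mask)) return(s$mask)
  if (inherits(s$jnorm, "current_spectrum")) return(s$jnorm$mask)
  stop("sample carries no half-visible mask")
}

#' Run the trained pair on a normalized input spectrum
#'
#' The real and imaginary channels are produced by the respective
#' networks (evaluation mode, running batch-norm statistics) and
#' recombined into a complex spectrum; the half-visible mask is
#' re-applied to the output. Inputs with active pixels outside the mask
#' are rejected: the pair is defined on filtered spectra only.
#'
#' @param pair A trained [unet_pair()].
#' @param j_norm 17x17 complex matrix or `current_spectrum` (normalized,
#'   filtered, cropped input).
#' @param mask Logical 17x17 half-visible mask (taken from `j_norm` when
#'   it is a `current_spectrum`).
#' @return A 17x17 `current_spectrum` with the network output.
#' @export
infer <- function(pair, j_norm, mask = NULL) {
  stopifnot(inherits(pair, "unet_pair"))
  v <- sample_values(j_norm)
  if (is.null(mask)) {
    if (inherits(j_norm, "current_spectrum")) mask <- j_norm$mask
    else stop("supply the half-visible mask for plain-matrix input")
  }
  if (any(v[!mask] != 0)) {
    stop("input has active pixels outside the half-visible mask; ",
         "filter and crop it first")
  }
  run <- function(net, part) {
    x <- array(part, c(dim(part), 1L, 1L))
    unet_forward(net, x, training = FALSE)$out[, , 1L, 1L]
  }
  out <- complex(real = run(pair$re, Re(v)), imaginary = run(pair$im, Im(v)))
  out <- matrix(out, nrow(v), ncol(v))
  out[!mask] <- 0
  grid <- if (inherits(j_norm, "current_spectrum")) j_norm$grid else NULL
  off <- if (inherits(j_norm, "current_spectrum")) j_norm$crop_offset
  new_current_spectrum(out, mask, grid, crop_offset = off)
}
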