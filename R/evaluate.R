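#' Gaussian window for structural similarity
#' @keywords internal
ssim_window <- function(size = 11L, sigma = 1.5) {
  ax <- seq_len(size) - (size + 1) / 2
  g <- exp(-ax^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# weighted local mean by valid 2D convolution with window w
conv_valid <- function(x, w) {
  k <- nrow(w)
  oh <- nrow(x) - k + 1L
  ow <- ncol(x) - k + 1L
  out <- matrix(0, oh, ow)
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      out <- out + w[di + 1L, dj + 1L] *
        x[di + seq_len(oh), dj + seq_len(ow)]
    }
  }
  out
}

#' Mean structural similarity index
#'
#' SSIM with the standard convention: Gaussian window of size 11 and
#' sigma 1.5, stability constants `k1 = 0.01`, `k2 = 0.03`, valid
#' (unpadded) windows, and the data range taken as max - min over the
#' two images jointly. The second argument is the reference.
#'
#' @param a,b Real matrices of identical shape (at least the window
#'   size in each dimension).
#' @param window_size,sigma,k1,k2 Convention parameters.
#' @param data_range Optional fixed dynamic range.
#' @return Scalar in [-1, 1].
#' @export
ssim <- function(a, b, window_size = 11L, sigma = 1.5,
                 k1 = 0.01, k2 = 0.03, data_range = NULL) {
  if (!all(dim(a) == dim(b))) stop("images must share the same shape")
  if (any(dim(a) < window_size)) {
    stop("images smaller than the SSIM window")
  }
  if (diff(range(b)) == 0) stop("constant reference: SSIM undefined")
  if (is.null(data_range)) data_range <- diff(range(c(a, b)))
  C1 <- (k1 * data_range)^2
  C2 <- (k2 * data_range)^2
  w <- ssim_window(window_size, sigma)
  mu_a <- conv_valid(a, w)
  mu_b <- conv_valid(b, w)
  va <- conv_valid(a * a, w) - mu_a^2
  vb <- conv_valid(b * b, w) - mu_b^2
  cab <- conv_valid(a * b, w) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10*log10(range^2 / mse)` with the range taken as max - min of the
#' reference `b`. Identical inputs give `Inf` with a warning.
#' @param a Image under test.
#' @param b Reference image.
#' @param data_range Optional fixed dynamic range.
#' @return Scalar in dB.
#' @export
psnr <- function(a, b, data_range = NULL) {
  if (!all(dim(a) == dim(b))) stop("images must share the same shape")
  mse <- mean((a - b)^2)
  if (is.null(data_range)) data_range <- diff(range(b))
  if (mse == 0) {
    warning("identical images: PSNR is infinite")
    return(Inf)
  }
  10 * log10(data_range^2 / mse)
}

#' Evaluate the U-Net pair over a dataset
#'
#' Per-batch SSIM and PSNR on the real and imaginary parts of the 17x17
#' spectra, comparing both the network input (`j_norm` vs `C_norm`) and
#' the network output (`C_net` vs `C_norm`) against the reference.
#' Metrics are averaged within each full batch (size 3 by default, the
#' training batch size: a 359-sample validation set gives 119 full
#' batches); the trailing remainder batch is excluded from the curves
#' but included in the dataset-level means.
#'
#' @param pair A trained [unet_pair()].
#' @param dataset Sample list (as for [train_unet_pair()]).
#' @param batch_size Batch size for the curves (default 3).
#' @return A `metric_report`: `batches` data.frame (one row per full
#'   batch, columns `ssim_in/out` and `psnr_in/out` for `re`/`im`),
#'   `means` (over all samples), `n_full_batches`, `n_remainder`.
#' @export
evaluate_dataset <- function(pair, dataset, batch_size = 3L) {
  if (length(dataset) == 0) stop("empty dataset")
  per_sample <- lapply(dataset, function(s) {
    jn <- sample_values(s$jnorm)
    cn <- sample_values(s$Cnorm)
    out <- infer(pair, s$jnorm,
                 mask = if (inherits(s$jnorm, "current_spectrum")) NULL
                 else sample_mask(s))
    ov <- out$values
    c(ssim_in_re = ssim(Re(jn), Re(cn)), ssim_in_im = ssim(Im(jn), Im(cn)),
      ssim_out_re = ssim(Re(ov), Re(cn)), ssim_out_im = ssim(Im(ov), Im(cn)),
      psnr_in_re = psnr(Re(jn), Re(cn)), psnr_in_im = psnr(Im(jn), Im(cn)),
      psnr_out_re = psnr(Re(ov), Re(cn)), psnr_out_im = psnr(Im(ov), Im(cn)))
  })
  M <- do.call(rbind, per_sample)
  n <- nrow(M)
  n_full <- n %/% batch_size
  batches <- NULL
  if (n_full > 0) {
    grp <- rep(seq_len(n_full), each = batch_size)
    batches <- as.data.frame(
      apply(M[seq_along(grp), , drop = FALSE], 2L,
            function(col) tapply(col, grp, mean)))
    batches <- cbind(batch = seq_len(n_full), batches)
    rownames(batches) <- NULL
  }
  structure(list(
    batches = batches,
    means = colMeans(M),
    n_full_batches = n_full,
    n_remainder = n - n_full * batch_size,
    batch_size = batch_size
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d full batches of %d (+%d remainder)\n",
              x$n_full_batches, x$batch_size, x$n_remainder))
  m <- x$means
  cat(sprintf("  SSIM  in  re/im: %.3f / %.3f   out re/im: %.3f / %.3f\n",
              m["ssim_in_re"], m["ssim_in_im"], m["ssim_out_re"],
              m["ssim_out_im"]))
  cat(sprintf("  PSNR  in  re/im: %.1f / %.1f   out re/im: %.1f / %.1f dB\n",
              m["psnr_in_re"], m["psnr_in_im"], m["psnr_out_re"],
              m["psnr_out_im"]))
  invisible(x)
}
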