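#' Swap quadrants so the origin moves between corner and center
#'
#' For even grid sizes the forward and inverse shifts coincide, so one
#' helper serves both directions.
#' @param x Matrix.
#' @return Shifted matrix.
#' @keywords internal
fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  stopifnot(n1 %% 2 == 0, n2 %% 2 == 0)
  x[c((n1 / 2 + 1):n1, 1:(n1 / 2)), c((n2 / 2 + 1):n2, 1:(n2 / 2))]
}

#' Centered 2D Fourier transform (Riemann-sum convention)
#'
#' `F(kx,kz) = spacing^2 * sum f(x,z) exp(-1i*(kx*x + kz*z))` with both the
#' spatial and spectral origins stored at index n/2 (0-based). Together
#' with [inverse_cfft2()] this is an exact transform pair.
#' @param x Complex matrix with DC-centered layout.
#' @param spacing Spatial sample pitch in m.
#' @return Complex matrix, DC-centered spectrum.
#' @export
cfft2 <- function(x, spacing) {
  fftshift2(stats::fft(fftshift2(x))) * spacing^2
}

#' Inverse of [cfft2()]
#' @param X Complex DC-centered spectrum.
#' @param spacing Spatial sample pitch in m.
#' @return Complex matrix in the spatial domain.
#' @export
inverse_cfft2 <- function(X, spacing) {
  n <- nrow(X) * ncol(X)
  fftshift2(stats::fft(fftshift2(X), inverse = TRUE)) / (n * spacing^2)
}

#' Spectrum of a retina field
#'
#' Centered discrete Fourier transform of the 64x64 scattered-field map,
#' normalized as a Riemann sum of the continuous transform (factor
#' `spacing^2` per sample), with the `exp(-1i k x)` kernel sign matching
#' the Weyl expansion of the Green's function.
#' @param field A `retina_field` or plain complex matrix.
#' @param geom A [camera_geometry()].
#' @return Complex DC-centered spectrum matrix.
#' @export
field_spectrum <- function(field, geom) {
  m <- as_field_matrix(field)
  if (nrow(m) != geom$n || ncol(m) != geom$n) {
    stop("field must be ", geom$n, "x", geom$n)
  }
  cfft2(m, geom$spacing)
}

#' Invert the Fourier diffraction relation on the visible domain
#'
#' The scattered-field spectrum on the retina obeys
#' `E_hat = (-1i / (2*gamma)) * j_hat * exp(-1i*gamma*d)`, so the
#' current spectrum is recovered as
#' `j_hat = 2i*gamma * E_hat * exp(+1i*gamma*d)`, defined only on the
#' visible disk where gamma is real; outside it is set to zero, and at the
#' rim the `2*gamma` factor vanishes smoothly (no division occurs).
#'
#' @param E_hat Spectrum from [field_spectrum()].
#' @param geom A [camera_geometry()].
#' @param sg Optional precomputed [spectral_grid()].
#' @return A `current_spectrum`: list with complex `values` (zero outside
#'   the visible mask), the logical `mask` applied, and the grid.
#' @export
diffraction_map <- function(E_hat, geom, sg = spectral_grid(geom)) {
  stopifnot(nrow(E_hat) == sg$n, ncol(E_hat) == sg$n)
  g <- Re(sg$gamma)
  j <- 2i * g * E_hat * exp(1i * g * geom$d)
  j[!sg$visible] <- 0
  new_current_spectrum(j, sg$visible, sg)
}

new_current_spectrum <- function(values, mask, sg, crop_offset = NULL) {
  structure(list(values = values, mask = mask, grid = sg,
                 crop_offset = crop_offset),
            class = "current_spectrum")
}

#' @export
print.current_spectrum <- function(x, ...) {
  cat(sprintf("<current_spectrum> %dx%d, %d active pixels%s\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              if (!is.null(x$crop_offset)) " (cropped)" else ""))
  invisible(x)
}

#' Visible / half-visible spectral filter
#'
#' Zeroes the spectrum outside the disk of radius `fraction * k_water`
#' with inclusive boundary. Only the full visible range (`fraction = 1`)
#' and its half (`fraction = 0.5`) are defined; on the 64x64 grid with
#' step `k_water/16` the half-visible support holds exactly 197 pixels
#' inside a 17x17 bounding box.
#'
#' @param spectrum A `current_spectrum` or plain complex matrix on the
#'   spectral grid.
#' @param fraction Either `1.0` or `0.5`.
#' @param geom A [camera_geometry()] (needed when `spectrum` is a matrix).
#' @return A `current_spectrum` with the filter applied and its mask.
#' @export
visible_filter <- function(spectrum, fraction, geom = NULL) {
  if (!isTRUE(all.equal(fraction, 1.0)) &&
      !isTRUE(all.equal(fraction, 0.5))) {
    stop("fraction must be 1.0 (visible) or 0.5 (half-visible)")
  }
  if (inherits(spectrum, "current_spectrum")) {
    sg <- spectrum$grid
    v <- spectrum$values
  } else {
    stopifnot(!is.null(geom))
    sg <- spectral_grid(geom, n = nrow(spectrum))
    v <- spectrum
  }
  mask <- sg$k_perp2 <= (fraction * sg$k_water)^2
  v[!mask] <- 0
  new_current_spectrum(v, mask, sg)
}

#' Crop the half-visible spectrum to its 17x17 bounding box
#'
#' Symmetric window of pixel offsets -8..+8 around DC; inverting with
#' [embed_box()] restores the full grid exactly. Errors if any active
#' pixel lies outside the window (which would indicate a wrong mask).
#' @param filtered A half-visible-filtered `current_spectrum`.
#' @param half_width Half-width of the window in pixels (default 8).
#' @return A cropped `current_spectrum` (17x17) carrying `crop_offset`.
#' @export
crop_box <- function(filtered, half_width = 8L) {
  stopifnot(inherits(filtered, "current_spectrum"))
  n <- nrow(filtered$values)
  dc <- n / 2 + 1L                      # 1-based index of DC
  idx <- (dc - half_width):(dc + half_width)
  outside <- filtered$mask
  outside[idx, idx] <- FALSE
  if (any(outside & filtered$values != 0)) {
    stop("active pixels outside the crop window: apply the half-visible ",
         "filter first")
  }
  new_current_spectrum(filtered$values[idx, idx],
                       filtered$mask[idx, idx], filtered$grid,
                       crop_offset = idx[1L] - 1L)
}

#' Re-embed a cropped spectrum into the full grid
#' @param cropped A `current_spectrum` from [crop_box()].
#' @return A full-grid `current_spectrum`.
#' @export
embed_box <- function(cropped) {
  stopifnot(inherits(cropped, "current_spectrum"),
            !is.null(cropped$crop_offset))
  n <- cropped$grid$n
  m <- nrow(cropped$values)
  idx <- cropped$crop_offset + seq_len(m)
  values <- matrix(0 + 0i, n, n)
  mask <- matrix(FALSE, n, n)
  values[idx, idx] <- cropped$values
  mask[idx, idx] <- cropped$mask
  new_current_spectrum(values, mask, cropped$grid)
}

#' Backproject a filtered current spectrum to the image plane
#'
#' Inverse centered transform of the (filtered) current spectrum: the
#' qualitative induced-current image of the camera.
#' @param j_hat A `current_spectrum` (full grid; cropped inputs are
#'   re-embedded automatically).
#' @param geom A [camera_geometry()].
#' @return Complex n x n image `j_z(x, z)`.
#' @export
backproject <- function(j_hat, geom) {
  if (inherits(j_hat, "current_spectrum")) {
    if (!is.null(j_hat$crop_offset)) j_hat <- embed_box(j_hat)
    j_hat <- j_hat$values
  }
  inverse_cfft2(j_hat, geom$spacing)
}

#' Normalized spectral density in dB
#'
#' `10*log10(|j_hat|^2 / max |j_hat|^2)`: the induced-current power
#' spectrum relative to its maximum, which is exactly 0 dB; pixels with
#' zero magnitude map to `floor_db`.
#' @param j_hat A `current_spectrum` or complex matrix.
#' @param floor_db Value assigned to zero-magnitude pixels (default -Inf).
#' @return Real matrix in dB.
#' @export
nsd <- function(j_hat, floor_db = -Inf) {
  v <- if (inherits(j_hat, "current_spectrum")) j_hat$values else j_hat
  m2 <- Mod(v)^2
  mx <- max(m2)
  if (mx == 0) stop("all-zero spectrum has no normalized spectral density")
  out <- 10 * log10(m2 / mx)
  out[m2 == 0] <- floor_db
  out
}

#' Differential induced-current image
#'
#' Magnitude of the complex difference between two backprojected current
#' images (e.g. with and without a tumor); non-negative everywhere.
#' @param j_with,j_without Complex matrices on the same grid.
#' @return Real non-negative matrix.
#' @export
differential_image <- function(j_with, j_without) {
  if (!all(dim(j_with) == dim(j_without))) {
    stop("images must share the same grid")
  }
  Mod(j_with - j_without)
}
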