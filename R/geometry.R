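#' Physical constants used throughout the camera model
#'
#' Vacuum permittivity (F/m) and the speed of light (m/s) as used by the
#' camera equations; `c = 3e8` is the convention under which the water
#' wavenumber at 2.45 GHz rounds to 438 1/m.
#' @keywords internal
.mw_const <- list(
  eps0 = 8.8541878128e-12,
  c0   = 3e8
)

#' Planar camera geometry
#'
#' Describes the monochromatic planar microwave camera: operating frequency,
#' water coupling medium, the 64x64 retina of field samples spaced a quarter
#' of the water wavelength apart, and the backpropagation distance `d`
#' between the retina and the observation plane through the phantom.
#'
#' The propagation wavenumber `k_water` uses the real-part convention
#' `k0 * sqrt(eps_water)` (about 438 1/m at 2.45 GHz); the complex water
#' permittivity `eps_water - 1i * sigma_water / (omega * eps0)` is kept
#' alongside for contrast computations, and optionally for the propagation
#' exponent when `lossy_propagation = TRUE`.
#'
#' @param frequency Operating frequency in Hz.
#' @param eps_water Real relative permittivity of the coupling medium.
#' @param sigma_water Conductivity of the coupling medium in S/m.
#' @param n Number of retina samples per transverse axis.
#' @param d Retina-to-observation-plane distance in m.
#' @param lossy_propagation If `TRUE`, the forward solver propagates with the
#'   complex water wavenumber (physical attenuation); if `FALSE` (default)
#'   propagation uses the real `k_water`, which makes the Born forward model
#'   algebraically consistent with the spectral inversion.
#' @return An object of class `camera_geometry`.
#' @examples
#' geom <- camera_geometry()
#' round(geom$k_water) # 438
#' @export
camera_geometry <- function(frequency = 2.45e9, eps_water = 73,
                            sigma_water = 1, n = 64L, d = 0.10,
                            lossy_propagation = FALSE) {
  stopifnot(frequency > 0, eps_water > 1, sigma_water >= 0, n >= 2, d > 0)
  omega <- 2 * pi * frequency
  k0 <- omega / .mw_const$c0
  eps_w_imag <- sigma_water / (omega * .mw_const$eps0)
  eps_water_complex <- complex(real = eps_water, imaginary = -eps_w_imag)
  k_water <- k0 * sqrt(eps_water)
  k_water_complex <- k0 * sqrt(eps_water_complex)
  lambda_water <- 2 * pi / k_water
  spacing <- lambda_water / 4
  structure(list(
    frequency = frequency,
    omega = omega,
    k0 = k0,
    eps_water = eps_water,
    sigma_water = sigma_water,
    eps_water_imag = eps_w_imag,
    eps_water_complex = eps_water_complex,
    k_water = k_water,
    k_water_complex = k_water_complex,
    lambda_water = lambda_water,
    spacing = spacing,
    n = as.integer(n),
    d = d,
    delta_k = 2 * pi / (n * spacing),
    lossy_propagation = isTRUE(lossy_propagation)
  ), class = "camera_geometry")
}

#' @export
print.camera_geometry <- function(x, ...) {
  cat("<camera_geometry>\n")
  cat(sprintf("  f = %.4g GHz, water eps_r = %g, sigma = %g S/m\n",
              x$frequency / 1e9, x$eps_water, x$sigma_water))
  cat(sprintf("  k_water = %.2f 1/m, lambda/4 spacing = %.3f mm\n",
              x$k_water, x$spacing * 1e3))
  cat(sprintf("  retina %dx%d, d = %g m, lossy propagation: %s\n",
              x$n, x$n, x$d, x$lossy_propagation))
  invisible(x)
}

#' Centered coordinates of a grid axis
#'
#' 0-based index `i` maps to `(i - n/2) * step`; the origin sits at index
#' `n/2` (1-based `n/2 + 1`), matching the DC-centered FFT layout.
#' @param n Number of samples (even).
#' @param step Sample spacing.
#' @return Numeric vector of length `n`.
#' @export
centered_axis <- function(n, step) {
  (seq_len(n) - 1 - n / 2) * step
}

#' Spectral grid and longitudinal wavenumber map
#'
#' Builds the DC-centered `(kx, kz)` grid of the retina spectrum with step
#' `delta_k = k_water / 16` (for the default 64-sample retina) and the
#' longitudinal wavenumber `gamma = sqrt(k_water^2 - kx^2 - kz^2)`.
#' `gamma` is real exactly on the visible disk `kx^2 + kz^2 <= k_water^2`;
#' outside, the branch `gamma = -1i * sqrt(kx^2 + kz^2 - k_water^2)` is
#' taken so that `exp(-1i * gamma * y)` decays for growing `y`.
#'
#' @param geom A [camera_geometry()].
#' @param n Grid size (defaults to the retina size).
#' @param delta_k Spectral step (defaults to `2*pi/(n*spacing)`).
#' @return An object of class `spectral_grid` with matrices `kx`, `kz`,
#'   `gamma` (complex), `k_perp2`, and logical masks `visible`
#'   (full visible disk) and `half_visible` (radius `k_water/2`).
#' @export
spectral_grid <- function(geom, n = geom$n,
                          delta_k = 2 * pi / (n * geom$spacing)) {
  ax <- centered_axis(n, delta_k)
  kx <- matrix(ax, n, n)               # varies along rows (x index)
  kz <- matrix(ax, n, n, byrow = TRUE) # varies along columns (z index)
  kw <- geom$k_water
  k_perp2 <- kx^2 + kz^2
  visible <- k_perp2 <= kw^2
  half_visible <- k_perp2 <= (kw / 2)^2
  gamma <- matrix(complex(real = 0, imaginary = 0), n, n)
  gamma[visible] <- complex(real = sqrt(kw^2 - k_perp2[visible]))
  gamma[!visible] <- complex(imaginary = -sqrt(k_perp2[!visible] - kw^2))
  structure(list(
    n = n, delta_k = delta_k, kx = kx, kz = kz, k_perp2 = k_perp2,
    gamma = gamma, visible = visible, half_visible = half_visible,
    k_water = kw
  ), class = "spectral_grid")
}

#' Longitudinal wavenumber for an arbitrary (possibly complex) medium k
#'
#' Branch: principal square root, sign-flipped when needed so that
#' `Im(gamma) <= 0`, i.e. `exp(-1i * gamma * y)` never grows with `y`.
#' @param k Medium wavenumber (real or complex scalar).
#' @param k_perp2 Matrix of `kx^2 + kz^2`.
#' @return Complex matrix of `gamma` values.
#' @keywords internal
gamma_branch <- function(k, k_perp2) {
  g <- sqrt((k * k - k_perp2) + 0i)
  flip <- Im(g) > 0
  g[flip] <- -g[flip]
  g
}
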