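#' Construct a retina field object
#' @keywords internal
new_retina_field <- function(values, geom, provenance = "born",
                             snr_db = Inf) {
  structure(list(values = values, geom = geom, provenance = provenance,
                 snr_db = snr_db),
            class = "retina_field")
}

#' @export
print.retina_field <- function(x, ...) {
  cat(sprintf("<retina_field> %dx%d (%s)%s\n", nrow(x$values),
              ncol(x$values), x$provenance,
              if (is.finite(x$snr_db)) sprintf(", SNR %g dB", x$snr_db)
              else ""))
  invisible(x)
}

as_field_matrix <- function(field) {
  if (inherits(field, "retina_field")) field$values else field
}

#' Incident plane wave
#'
#' Unit-amplitude monochromatic plane wave polarized along z and
#' propagating along +y in the coupling medium, with phase convention
#' `exp(-1i * k_water * y)` (consistent with the Green's-function kernel
#' sign). By default the propagation exponent uses the real-part water
#' wavenumber, so `|E_i| = 1` everywhere; with `lossy_propagation` the
#' complex wavenumber attenuates the wave.
#'
#' @param geom A [camera_geometry()].
#' @param y Numeric vector of y coordinates in m.
#' @return Complex vector of incident-field values.
#' @export
incident_field <- function(geom, y) {
  k <- if (geom$lossy_propagation) geom$k_water_complex else geom$k_water
  exp(-1i * k * y)
}

#' Born-approximation forward solver (3D angular spectrum)
#'
#' First-Born scattered field on the camera retina: the induced current is
#' `j_z = (k^2 - k_water^2) * E_i` per voxel (with the complex water
#' permittivity in the contrast term, so water voxels radiate nothing),
#' and each transverse slab is propagated to the retina plane at
#' `y = d` by the angular-spectrum kernel `(-1i/(2*gamma)) *
#' exp(-1i*gamma*|d - y'|)`, summed over slabs with midpoint weights.
#' Evanescent components decay exponentially through the complex gamma
#' branch. The transform runs on an internally zero-padded grid
#' (`pad_factor` times the retina) to refine the spectral quadrature;
#' `pad_factor = 1` makes the solver algebraically exact against the
#' spectral inversion chain.
#'
#' @param phantom A [build_phantom()] result (same transverse spacing as
#'   the retina, transverse extent not exceeding it).
#' @param geom A [camera_geometry()].
#' @param pad_factor Integer >= 1 zero-padding factor (default 1).
#' @return A `retina_field`.
#' @export
born_forward <- function(phantom, geom, pad_factor = 1L) {
  g <- phantom$grid
  if (g$n > geom$n) {
    stop("phantom transverse grid (", g$n, ") is wider than the retina (",
         geom$n, ")")
  }
  if (abs(g$spacing - geom$spacing) > 1e-12) {
    stop("phantom voxel pitch must equal the retina spacing")
  }
  if (max(g$y) >= geom$d) {
    stop("phantom extends beyond the retina plane y = d")
  }
  np <- as.integer(pad_factor) * geom$n
  sgp <- spectral_grid(geom, n = np)
  kprop <- if (geom$lossy_propagation) geom$k_water_complex else geom$k_water
  gam <- gamma_branch(kprop, sgp$k_perp2)
  base_kernel <- (-1i / (2 * gam)) * exp(-1i * gam * geom$d)
  base_kernel[gam == 0] <- 0  # measure-zero rim of the visible disk

  kw2 <- geom$k0^2 * geom$eps_water_complex
  Ei <- incident_field(geom, g$y)
  acc <- matrix(0 + 0i, np, np)
  off <- (np - g$n) / 2
  idx <- off + seq_len(g$n)
  pad <- matrix(0 + 0i, np, np)
  for (jy in seq_len(g$n_y)) {
    chi <- geom$k0^2 * phantom$eps[, jy, ] - kw2
    if (all(chi == 0)) next
    pad[idx, idx] <- chi * Ei[jy]
    acc <- acc + cfft2(pad, g$spacing) *
      (base_kernel * exp(1i * gam * g$y[jy]))
    pad[idx, idx] <- 0
  }
  acc <- acc * g$spacing          # slab thickness (midpoint rule)
  Epad <- inverse_cfft2(acc, g$spacing)
  ridx <- (np - geom$n) / 2 + seq_len(geom$n)
  new_retina_field(Epad[ridx, ridx], geom, provenance = "born")
}

#' Add complex white Gaussian noise at a prescribed SNR
#'
#' Independent circular complex Gaussian noise on every retina sample,
#' with total noise power equal to the mean signal power divided by
#' `10^(snr_db/10)`. Deterministic given `seed`; `snr_db = Inf` returns
#' the field unchanged.
#'
#' @param field A `retina_field` (or complex matrix).
#' @param snr_db Signal-to-noise ratio in dB.
#' @param seed Integer seed.
#' @return A `retina_field` tagged with the SNR.
#' @export
add_awgn <- function(field, snr_db, seed = 1L) {
  stopifnot(!is.na(snr_db))
  m <- as_field_matrix(field)
  geom <- if (inherits(field, "retina_field")) field$geom else NULL
  if (is.infinite(snr_db)) {
    return(new_retina_field(m, geom,
                            provenance = attr(field, "provenance"),
                            snr_db = Inf))
  }
  p_sig <- mean(Mod(m)^2)
  p_noise <- p_sig / 10^(snr_db / 10)
  n <- length(m)
  noise <- withr_rng(seed, function() {
    complex(real = stats::rnorm(n, sd = sqrt(p_noise / 2)),
            imaginary = stats::rnorm(n, sd = sqrt(p_noise / 2)))
  })
  new_retina_field(m + matrix(noise, nrow(m), ncol(m)), geom,
                   provenance = if (inherits(field, "retina_field"))
                     field$provenance else "unknown",
                   snr_db = snr_db)
}
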