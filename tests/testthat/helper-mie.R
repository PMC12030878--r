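# Cylindrical-harmonics (Mie series) oracle for a homogeneous lossless
# cylinder in water, z-polarized plane wave exp(-i*k*y), exp(+i*omega*t)
# convention (outgoing waves are Hankel functions of the second kind).
# Independent of the volume-integral solver: closed-form coefficients from
# the boundary conditions, evaluated with base Bessel functions.

mie_hankel2 <- function(nu, x) {
  complex(real = besselJ(x, nu), imaginary = -besselY(x, nu))
}

mie_dJ <- function(nu, x) {
  if (nu == 0) -besselJ(x, 1)
  else (besselJ(x, nu - 1) - besselJ(x, nu + 1)) / 2
}

mie_dH2 <- function(nu, x) {
  if (nu == 0) -mie_hankel2(1, x)
  else (mie_hankel2(nu - 1, x) - mie_hankel2(nu + 1, x)) / 2
}

# angular weight collapsing the +/-n modes of exp(-i k rho sin(phi)) =
# sum_n J_n(k rho) exp(-i n phi), using J_{-n} = (-1)^n J_n
mie_mode_weight <- function(n, phi) {
  if (n == 0) array(1, dim(phi) %||% length(phi))
  else if (n %% 2 == 0) 2 * cos(n * phi)
  else -2i * sin(n * phi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# total field of the cylinder (radius a, interior wavenumber k1) on points
# given by radius R and azimuth phi, background wavenumber k0
mie_cylinder_field <- function(R, phi, a, k0, k1, n_modes = 24L) {
  inside <- R <= a
  E <- exp(-1i * k0 * R * sin(phi))
  E[inside] <- 0
  for (n in 0:n_modes) {
    J0 <- besselJ(k0 * a, n); J0p <- mie_dJ(n, k0 * a)
    J1c <- besselJ(k1 * a, n); J1p <- mie_dJ(n, k1 * a)
    H <- mie_hankel2(n, k0 * a); Hp <- mie_dH2(n, k0 * a)
    D <- -k1 * J1p * H + k0 * J1c * Hp
    b <- (J0 * k1 * J1p - J1c * k0 * J0p) / D   # scattered coefficient
    cc <- -2i / (pi * a * D)                    # interior (from Wronskian)
    w <- mie_mode_weight(n, phi)
    E[!inside] <- E[!inside] + b * mie_hankel2(n, k0 * R[!inside]) *
      w[!inside]
    E[inside] <- E[inside] + cc * besselJ(k1 * R[inside], n) * w[inside]
  }
  E
}
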