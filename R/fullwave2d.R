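#' Hankel functions of the second kind (real argument)
#' @keywords internal
hankel2 <- function(nu, x) {
  complex(real = besselJ(x, nu), imaginary = -besselY(x, nu))
}

#' Build the discretized 2D Green's kernel (Richmond circular cells)
#'
#' Each square pixel is replaced by the equal-area disk of radius
#' `a = spacing/sqrt(pi)`. Integrating the 2D Green's function
#' `g = (-1i/4) * H0_2(k*rho)` over a cell and multiplying by `k^2` gives
#' the off-diagonal coupling `(-1i*pi*a*k/2) * J1(k*a) * H0_2(k*rho)` and
#' the self term `(-1i*pi*a*k/2) * H1_2(k*a) - 1`.
#' @keywords internal
vie2d_kernel <- function(nx, ny, spacing, k) {
  a <- spacing / sqrt(pi)
  px <- 2L * nx; py <- 2L * ny
  dx <- ((seq_len(px) - 1 + nx) %% px) - nx
  dy <- ((seq_len(py) - 1 + ny) %% py) - ny
  rho <- spacing * sqrt(outer(dx^2, dy^2, "+"))
  K <- matrix(0 + 0i, px, py)
  nz <- rho > 0
  K[nz] <- (-1i * pi * a * k / 2) * besselJ(k * a, 1) * hankel2(0, k * rho[nz])
  K[!nz] <- (-1i * pi * a * k / 2) * hankel2(1, k * a) - 1
  stats::fft(K)
}

vie2d_conv <- function(Kh, u) {
  nx <- nrow(u); ny <- ncol(u)
  up <- matrix(0 + 0i, 2L * nx, 2L * ny)
  up[seq_len(nx), seq_len(ny)] <- u
  v <- stats::fft(stats::fft(up) * Kh, inverse = TRUE) / (4 * nx * ny)
  v[seq_len(nx), seq_len(ny)]
}

#' BiCGSTAB for a complex linear operator
#' @keywords internal
bicgstab <- function(amul, b, tol = 1e-8, max_iter = 500L) {
  x <- b * 0
  r <- b - amul(x)
  rhat <- r
  rho <- alpha <- omega <- 1 + 0i
  v <- p <- r * 0
  nb <- sqrt(sum(Mod(b)^2))
  dotc <- function(a, c) sum(Conj(a) * c)
  for (it in seq_len(max_iter)) {
    rho1 <- dotc(rhat, r)
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * v)
    v <- amul(p)
    alpha <- rho / dotc(rhat, v)
    s <- r - alpha * v
    t <- amul(s)
    omega <- dotc(t, s) / dotc(t, t)
    x <- x + alpha * p + omega * s
    r <- s - omega * t
    res <- sqrt(sum(Mod(r)^2)) / nb
    if (res <= tol) {
      return(list(x = x, iterations = it, residual = res,
                  converged = TRUE))
    }
  }
  list(x = x, iterations = max_iter, residual = res, converged = FALSE)
}

#' Solve the 2D scalar volume integral equation
#'
#' Total z-polarized field in a 2D (x, y) contrast slice immersed in
#' water, from the volume integral equation
#' `E_t = E_i + k_water^2 * Integral(chi * E_t * g)`, solved by BiCGSTAB
#' with the convolution applied by FFT. The Green kernel uses the
#' real-part water wavenumber; the contrast `chi = (k^2 - k_water^2) /
#' k_water^2` may be complex (lossy tissues).
#'
#' @param eps Complex relative-permittivity matrix on the (x, y) grid.
#' @param spacing Pixel pitch in m (should not exceed a tenth of the
#'   water wavelength).
#' @param geom A [camera_geometry()].
#' @param tol Relative residual tolerance.
#' @param max_iter Iteration cap; non-convergence is an error carrying
#'   the residual.
#' @param born If `TRUE`, return the first-Born solution
#'   (`E_t = E_i`, scattered field from a single kernel application)
#'   instead of iterating.
#' @return List with complex matrices `E_t`, `E_i`, `E_s`, the contrast
#'   `chi`, grid axes `x`, `y`, `spacing`, and solver diagnostics.
#' @export
solve_vie2d <- function(eps, spacing, geom, tol = 1e-8, max_iter = 500L,
                        born = FALSE) {
  if (spacing > geom$lambda_water / 10 + 1e-12) {
    stop("pixel size must be at most lambda_water/10")
  }
  nx <- nrow(eps); ny <- ncol(eps)
  kw <- geom$k_water
  chi <- (geom$k0^2 * eps - geom$k0^2 * geom$eps_water_complex) / kw^2
  x <- centered_axis(nx, spacing)
  y <- centered_axis(ny, spacing)
  Ei <- matrix(exp(-1i * kw * y), nx, ny, byrow = TRUE)
  Kh <- vie2d_kernel(nx, ny, spacing, kw)
  if (born || all(chi == 0)) {
    Et <- Ei
    info <- list(iterations = 0L, residual = 0)
  } else {
    amul <- function(u) {
      u <- matrix(u, nx, ny)
      as.vector(u - vie2d_conv(Kh, chi * u))
    }
    sol <- bicgstab(amul, as.vector(Ei), tol = tol, max_iter = max_iter)
    if (!sol$converged) {
      stop(sprintf("VIE solver did not converge in %d iterations ",
                   sol$iterations),
           sprintf("(relative residual %.3g)", sol$residual))
    }
    Et <- matrix(sol$x, nx, ny)
    info <- sol[c("iterations", "residual")]
  }
  Es <- if (all(chi == 0)) Ei * 0 else vie2d_conv(Kh, chi * Et)
  c(list(E_t = Et, E_i = Ei, E_s = Es, chi = chi, x = x, y = y,
         spacing = spacing), info)
}

cfft1 <- function(v, spacing) {
  n <- length(v)
  s <- c((n / 2 + 1):n, 1:(n / 2))
  (stats::fft(v[s]))[s] * spacing
}

icfft1 <- function(V, spacing) {
  n <- length(V)
  s <- c((n / 2 + 1):n, 1:(n / 2))
  (stats::fft(V[s], inverse = TRUE))[s] / (n * spacing)
}

#' Full-wave 2D forward solver for the camera retina
#'
#' Multiple-scattering surrogate data generator: solves the 2D volume
#' integral equation on the observation-plane slice (cylindrical
#' geometry, fields invariant along z), forms the induced current
#' `j_z = (k^2 - k_water^2) * E_t`, and propagates it column by column to
#' the retina plane with the 1D angular-spectrum kernel
#' `(-1i/(2*gamma)) * exp(-1i*gamma*(d - y'))`. The slice grid must be a
#' `refine`-fold refinement of the retina pitch so its x samples contain
#' the retina positions.
#'
#' @param eps Complex permittivity slice, `64*refine` x ny.
#' @param geom A [camera_geometry()].
#' @param refine Integer: retina spacing / slice pixel size (>= 3 keeps
#'   the pixel under a tenth of the wavelength).
#' @param ... Passed to [solve_vie2d()] (`tol`, `max_iter`, `born`).
#' @return A `retina_field` (identical rows along z) with the solver
#'   output attached as attribute `solution`.
#' @export
fullwave2d_forward <- function(eps, geom, refine = 4L, ...) {
  refine <- as.integer(refine)
  spacing <- geom$spacing / refine
  nx <- nrow(eps); ny <- ncol(eps)
  if (nx != geom$n * refine) {
    stop("slice must have ", geom$n * refine, " x samples (refine = ",
         refine, ")")
  }
  sol <- solve_vie2d(eps, spacing, geom, ...)
  if (max(sol$y) >= geom$d) stop("slice extends beyond the retina plane")
  kw <- geom$k_water
  j <- kw^2 * sol$chi * sol$E_t
  kx <- centered_axis(nx, 2 * pi / (nx * spacing))
  gam <- gamma_branch(kw, kx^2)
  prop0 <- (-1i / (2 * gam))
  prop0[gam == 0] <- 0  # rim of the visible range
  Ehat <- rep(0 + 0i, nx)
  for (jy in seq_len(ny)) {
    col <- j[, jy]
    if (all(col == 0)) next
    Ehat <- Ehat + spacing * cfft1(col, spacing) *
      (prop0 * exp(-1i * gam * (geom$d - sol$y[jy])))
  }
  Eline <- icfft1(Ehat, spacing)
  ridx <- seq(1L, nx, by = refine)
  # slice x grid: (i - nx/2)*spacing; retina x: (i - n/2)*spacing*refine
  stopifnot(length(ridx) == geom$n)
  vals <- matrix(Eline[ridx], geom$n, geom$n)  # constant along z
  rf <- new_retina_field(vals, geom, provenance = "fullwave2d")
  attr(rf, "solution") <- sol
  rf
}
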