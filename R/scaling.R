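#' Min-max scale the real and imaginary parts of a complex image
#'
#' Componentwise affine map of the real and imaginary parts onto [0, 1].
#' The imaginary part of both the contrast and the induced currents is
#' small against the real part; scaling each part separately gives them
#' equivalent dynamics before the network sees them. The per-part minima
#' and maxima are recorded so the operation stays traceable/invertible.
#'
#' @param image Complex matrix with nonconstant real and imaginary parts.
#' @return Complex matrix in `[0,1] + 1i*[0,1]` with attribute `scaling`
#'   (list `re_min`, `re_max`, `im_min`, `im_max`).
#' @export
minmax_complex <- function(image) {
  re <- Re(image); im <- Im(image)
  rng_re <- range(re); rng_im <- range(im)
  if (diff(rng_re) == 0 || diff(rng_im) == 0) {
    stop("min-max scaling undefined for a constant real or imaginary part")
  }
  out <- complex(
    real = (re - rng_re[1]) / diff(rng_re),
    imaginary = (im - rng_im[1]) / diff(rng_im)
  )
  out <- matrix(out, nrow(image), ncol(image))
  attr(out, "scaling") <- list(re_min = rng_re[1], re_max = rng_re[2],
                               im_min = rng_im[1], im_max = rng_im[2])
  out
}

#' Normalized, filtered, cropped spectrum of a min-max scaled image
#'
#' Transforms the scaled image to the spectral domain, applies the
#' half-visible filter and the 17x17 crop, and divides by the maximum
#' modulus over the active mask so `max |spectrum| = 1`. Division by a
#' positive real number modifies only magnitudes, never phases, and keeps
#' every real and imaginary value inside [-1, 1].
#'
#' @param scaled_image Complex n x n image (typically from
#'   [minmax_complex()]).
#' @param geom A [camera_geometry()].
#' @return A 17x17 `current_spectrum` with attribute `max_mod` (the
#'   recorded normalization constant) and any `scaling` attribute of the
#'   input carried along.
#' @export
spectrum_normalize <- function(scaled_image, geom) {
  spec <- field_spectrum(scaled_image, geom)
  filt <- visible_filter(spec, 0.5, geom)
  cropped <- crop_box(filt)
  mm <- max(Mod(cropped$values[cropped$mask]))
  if (mm == 0) stop("all-zero spectrum cannot be normalized")
  cropped$values <- cropped$values / mm
  attr(cropped, "max_mod") <- mm
  attr(cropped, "scaling") <- attr(scaled_image, "scaling")
  cropped
}

#' Water-reference calibration of a reconstructed contrast image
#'
#' Computes `M_re` and `M_im`, the means of the real and imaginary parts
#' over the pixels outside the phantom contour (known to be water), and
#' calibrates `eps_cal = (Re(C_net)/M_re) * eps_water` and
#' `sigma_cal = (Im(C_net)/M_im) * sigma_water`, so a pixel whose value
#' equals the water mean maps exactly to the water properties
#' (eps 73, sigma 1 S/m). The calibration is invariant to a global
#' rescaling of `C_net` because the mean rescales with it.
#'
#' @param C_net_image Complex n x n image reconstructed from the network
#'   output spectrum.
#' @param contour_mask Logical matrix, `TRUE` inside the phantom.
#' @param geom A [camera_geometry()].
#' @return A `calibrated_maps` list with `eps_cal`, `sigma_cal`, `M_re`,
#'   `M_im` and the mask.
#' @export
water_calibrate <- function(C_net_image, contour_mask, geom) {
  outside <- !contour_mask
  if (!any(outside)) stop("contour mask leaves no water pixels")
  M_re <- mean(Re(C_net_image)[outside])
  M_im <- mean(Im(C_net_image)[outside])
  if (M_re == 0 || M_im == 0) {
    stop("zero water mean: calibration undefined")
  }
  structure(list(
    eps_cal = (Re(C_net_image) / M_re) * geom$eps_water,
    sigma_cal = (Im(C_net_image) / M_im) * geom$sigma_water,
    M_re = M_re, M_im = M_im, contour_mask = contour_mask,
    geom = geom
  ), class = "calibrated_maps")
}

#' Rescale calibrated maps onto positive physical ranges
#'
#' Second min-max pass enforcing positive reconstructed extrema: the
#' permittivity map is mapped onto `[min|eps_cal|, max|eps_cal|]`
#' preserving orientation, and the conductivity map onto the same
#' modulus range of `sigma_cal` with the reversed structure
#' `max|.| + (min|.| - max|.|) * (x - min x)/(max x - min x)` (so its
#' largest calibrated value maps to `min|sigma_cal|`).
#'
#' @param maps A `calibrated_maps` from [water_calibrate()].
#' @return The same object with `eps_net` and `sigma_net` added.
#' @export
rescale_properties <- function(maps) {
  stopifnot(inherits(maps, "calibrated_maps"))
  eps <- maps$eps_cal; sig <- maps$sigma_cal
  if (diff(range(eps)) == 0 || diff(range(sig)) == 0) {
    stop("constant calibrated map cannot be rescaled")
  }
  am_eps <- range(abs(eps)); am_sig <- range(abs(sig))
  maps$eps_net <- am_eps[1] + diff(am_eps) *
    (eps - min(eps)) / diff(range(eps))
  maps$sigma_net <- am_sig[2] + (am_sig[1] - am_sig[2]) *
    (sig - min(sig)) / diff(range(sig))
  maps
}

#' Enforce the known coupling-medium values outside the contour
#'
#' The phantom contour is prior information during evaluation: every
#' pixel outside it is water, so the reconstructed maps are set exactly
#' to `eps_water` and `sigma_water` there. Idempotent; inside pixels are
#' untouched.
#'
#' @param maps A `calibrated_maps` with `eps_net`/`sigma_net` (run
#'   [rescale_properties()] first).
#' @param contour_mask Optional logical matrix overriding the stored one.
#' @return The updated `calibrated_maps`.
#' @export
apply_contour_prior <- function(maps, contour_mask = maps$contour_mask) {
  stopifnot(inherits(maps, "calibrated_maps"),
            !is.null(maps$eps_net), !is.null(maps$sigma_net))
  outside <- !contour_mask
  maps$eps_net[outside] <- maps$geom$eps_water
  maps$sigma_net[outside] <- maps$geom$sigma_water
  maps
}

#' Full denormalization chain: network spectrum to physical maps
#'
#' Re-embeds a 17x17 output spectrum into the 64x64 grid, inverse
#' transforms it to a contrast image, and runs water calibration, the
#' positive rescaling and the contour prior.
#'
#' @param C_net_spectrum A 17x17 `current_spectrum` (network output).
#' @param contour_mask Logical n x n phantom-support mask.
#' @param geom A [camera_geometry()].
#' @return A `calibrated_maps` with `eps_net`, `sigma_net`.
#' @export
reconstruct_maps <- function(C_net_spectrum, contour_mask, geom) {
  img <- backproject(C_net_spectrum, geom)
  maps <- water_calibrate(img, contour_mask, geom)
  maps <- rescale_properties(maps)
  apply_contour_prior(maps)
}
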