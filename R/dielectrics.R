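#' Tissue dielectric properties at the camera frequency
#'
#' Nominal relative permittivity and conductivity of the four phantom
#' tissues (fat, glandular, skin, tumor) and of the water coupling medium
#' at 2.45 GHz, as used for every simulation. Values follow the standard
#' tissue-property compilations for this band.
#'
#' @param frequency Frequency in Hz (stored for the loss-term conversion
#'   `eps'' = sigma / (omega * eps0)`).
#' @return A `tissue_dielectrics` object: data.frame with columns `tissue`,
#'   `eps_r`, `sigma`, `eps_imag`, plus `frequency` attribute.
#' @examples
#' tissue_dielectrics()
#' @export
tissue_dielectrics <- function(frequency = 2.45e9) {
  tab <- data.frame(
    tissue = c("fat", "glandular", "skin", "tumor", "water"),
    eps_r  = c(5, 44, 42, 53, 73),
    sigma  = c(0.1, 1.5, 1.6, 1.8, 1.0),
    stringsAsFactors = FALSE
  )
  omega <- 2 * pi * frequency
  tab$eps_imag <- tab$sigma / (omega * .mw_const$eps0)
  attr(tab, "frequency") <- frequency
  class(tab) <- c("tissue_dielectrics", "data.frame")
  tab
}

#' Apply bounded uniform jitter to tissue properties
#'
#' Multiplies each tissue's permittivity and conductivity by an independent
#' `Uniform(1 - amount, 1 + amount)` draw (default +/-5%), one draw per
#' tissue per quantity. Water is never jittered: it is the known coupling
#' medium used later for calibration.
#'
#' @param nominal A [tissue_dielectrics()] table.
#' @param seed Integer seed; the same seed always reproduces the same draw.
#' @param amount Relative half-width of the jitter interval (default 0.05).
#' @return A jittered `tissue_dielectrics` table.
#' @export
jitter_dielectrics <- function(nominal, seed, amount = 0.05) {
  stopifnot(inherits(nominal, "tissue_dielectrics"), amount >= 0)
  out <- nominal
  idx <- which(out$tissue != "water")
  if (amount > 0) {
    factors <- withr_rng(seed, function() {
      matrix(stats::runif(2L * length(idx), 1 - amount, 1 + amount),
             ncol = 2L)
    })
    out$eps_r[idx] <- out$eps_r[idx] * factors[, 1L]
    out$sigma[idx] <- out$sigma[idx] * factors[, 2L]
  }
  omega <- 2 * pi * attr(out, "frequency")
  out$eps_imag <- out$sigma / (omega * .mw_const$eps0)
  out
}

#' Run code with a temporarily seeded RNG, restoring global state
#' @keywords internal
withr_rng <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Complex relative permittivity of one tissue
#'
#' `eps_r - 1i * sigma/(omega*eps0)` under the exp(+i omega t) convention.
#' @param dielectrics A `tissue_dielectrics` table.
#' @param tissue Tissue name.
#' @return Complex scalar.
#' @export
complex_permittivity <- function(dielectrics, tissue) {
  row <- match(tissue, dielectrics$tissue)
  if (is.na(row)) stop("unknown tissue: ", tissue)
  complex(real = dielectrics$eps_r[row],
          imaginary = -dielectrics$eps_imag[row])
}
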