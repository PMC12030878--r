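#' Parametric surrogate cavity library
#'
#' Analytic solids standing in for the printable breast cavities: three
#' fat/skin shells (superellipsoids, inner fat boundary plus a 2.5 mm skin
#' thickness), five glandular inclusions (ellipsoids, common off-center
#' placement so rotations and mirrors produce distinct views), and five
#' tumor shapes labelled A-E with maximum dimensions between 0.5 cm and
#' 2 cm. Sizes are chosen once so that glandular cavity 5 does not fit
#' inside the smallest fat cavity (its vertical semi-axis exceeds the
#' shell) while every other fat x gland pair nests with at least 2 mm of
#' clearance, and so that every tumor fits the adipose annulus of every
#' legal pair.
#'
#' All lengths are in meters.
#'
#' @return A list with elements `fat` (3 shells), `gland` (5 inclusions),
#'   `tumor` (5 shapes, named A-E), `gland_offset`, `margin`,
#'   `glandular_tumor_offset`, and the held-out `test` phantom geometry.
#' @export
cavity_library <- function() {
  fat <- list(
    list(inner = c(0.048, 0.040, 0.048), skin = 0.0025, p = 2.5),
    list(inner = c(0.058, 0.050, 0.058), skin = 0.0025, p = 2.5),
    list(inner = c(0.068, 0.058, 0.068), skin = 0.0025, p = 2.5)
  )
  gland_semi <- list(
    c(0.012, 0.010, 0.014),
    c(0.016, 0.014, 0.018),
    c(0.020, 0.018, 0.022),
    c(0.024, 0.020, 0.026),
    c(0.030, 0.044, 0.030)  # tall: excluded from fat shell 1
  )
  tumor <- list(
    A = c(0.0025, 0.0025, 0.0025),  # 0.5 cm
    B = c(0.0040, 0.0040, 0.0040),  # 0.8 cm
    C = c(0.0060, 0.0045, 0.0050),  # 1.2 cm
    D = c(0.0075, 0.0075, 0.0075),  # 1.5 cm
    E = c(0.0080, 0.0070, 0.0100)   # 2.0 cm
  )
  list(
    fat = fat,
    gland = lapply(gland_semi, function(s) list(semi = s, p = 2)),
    gland_offset = c(0.006, 0.003, 0.004),
    tumor = tumor,
    glandular_tumor_offset = c(-0.004, 0.002, 0.003),
    margin = 0.002,
    test = list(
      fat = list(inner = c(0.052, 0.044, 0.050), skin = 0.0025, p = 2.2),
      gland = list(
        list(semi = c(0.018, 0.015, 0.020), center = c(0.004, 0.002, 0.000)),
        list(semi = c(0.014, 0.012, 0.016), center = c(-0.010, -0.004, 0.008))
      ),
      tumor = list(semi = c(0.006, 0.006, 0.006))
    )
  )
}

#' Superellipsoid membership test
#'
#' `sum(|(r - center)/semi|^p) <= 1`; `p = 2` is an ordinary ellipsoid.
#' @param pts n x 3 matrix of points (m).
#' @param center Length-3 center.
#' @param semi Length-3 semi-axes.
#' @param p Superellipsoid exponent.
#' @return Logical vector.
#' @export
inside_solid <- function(pts, center, semi, p = 2) {
  u <- abs(sweep(pts, 2L, center, "-"))
  u <- sweep(u, 2L, semi, "/")
  (u[, 1L]^p + u[, 2L]^p + u[, 3L]^p) <= 1
}

#' Does a glandular cavity nest inside a fat shell?
#'
#' Conservative per-axis criterion: offset + gland semi-axis + margin must
#' stay strictly below the inner fat semi-axis on every axis. Exactly one
#' pair fails (fat 1, gland 5), which is what makes 3*5 - 1 = 14 tumor-free
#' models.
#' @param fat_id Fat shell index 1..3.
#' @param gland_id Glandular cavity index 1..5.
#' @param lib Cavity library (defaults to [cavity_library()]).
#' @return Logical scalar.
#' @export
gland_fits <- function(fat_id, gland_id, lib = cavity_library()) {
  f <- lib$fat[[fat_id]]$inner
  g <- lib$gland[[gland_id]]$semi
  all(abs(lib$gland_offset) + g + lib$margin < f)
}

#' Center of the adipose tumor for a given fat/gland pair
#'
#' Placed on the +x axis in the observation plane (y = 0), midway between
#' the glandular cavity's +x extent and the inner fat boundary.
#' @keywords internal
adipose_tumor_center <- function(fat_id, gland_id, lib = cavity_library()) {
  gx <- lib$gland_offset[1L] + lib$gland[[gland_id]]$semi[1L]
  fx <- lib$fat[[fat_id]]$inner[1L]
  c((gx + fx) / 2, 0, 0)
}
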