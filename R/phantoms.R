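#' Enumerate the phantom database configurations
#'
#' Deterministic, sorted enumeration of the combinatorial database:
#' 3 fat shells x 5 glandular cavities minus the single non-nesting pair
#' gives 14 tumor-free models; the four tumor cases (1 none, 2 adipose,
#' 3 glandular, 4 both) give 56; mirroring and 16 rotations give 1792.
#' Each tumor shape A-E is associated with exactly one glandular cavity
#' (shape = LETTERS[gland_id]), so a shape never repeats across cavities.
#'
#' @param include_tumors Include tumor cases 2-4 (default `TRUE`).
#' @param include_mirrors Include the mirrored view of each phantom.
#' @param n_rotations Number of evenly spaced views over a full turn
#'   (rotation index k maps to angle `2*pi*k/n_rotations`).
#' @return A data.frame with one row per configuration: `phantom_id`,
#'   `fat_id`, `gland_id`, `tumor_case`, `tumor_shape`, `mirror`,
#'   `rotation`, `n_rotations`, `jitter_seed`, `model`.
#' @examples
#' nrow(enumerate_configs(FALSE, FALSE, 1))  # 14
#' nrow(enumerate_configs(TRUE, FALSE, 1))   # 56
#' nrow(enumerate_configs(TRUE, TRUE, 16))   # 1792
#' @export
enumerate_configs <- function(include_tumors = TRUE,
                              include_mirrors = TRUE,
                              n_rotations = 16L) {
  stopifnot(n_rotations >= 1)
  lib <- cavity_library()
  tumor_cases <- if (include_tumors) 1:4 else 1L
  mirrors <- if (include_mirrors) c(FALSE, TRUE) else FALSE
  grid <- expand.grid(
    rotation = 0:(n_rotations - 1L),
    mirror = mirrors,
    tumor_case = tumor_cases,
    gland_id = 1:5,
    fat_id = 1:3,
    KEEP.OUT.ATTRS = FALSE
  )
  keep <- mapply(gland_fits, grid$fat_id, grid$gland_id,
                 MoreArgs = list(lib = lib))
  grid <- grid[keep, , drop = FALSE]
  grid <- grid[order(grid$fat_id, grid$gland_id, grid$tumor_case,
                     grid$mirror, grid$rotation), , drop = FALSE]
  rownames(grid) <- NULL
  grid$tumor_shape <- ifelse(grid$tumor_case == 1L, NA_character_,
                             LETTERS[grid$gland_id])
  grid$n_rotations <- as.integer(n_rotations)
  # one jitter draw per physical phantom (fat, gland, tumor case): all of
  # its mirrored/rotated views share the same tissue values
  grid$jitter_seed <- grid$fat_id * 100L + grid$gland_id * 10L +
    grid$tumor_case
  grid$model <- "train"
  grid$phantom_id <- sprintf("f%dg%dt%d%s_r%02d", grid$fat_id,
                             grid$gland_id, grid$tumor_case,
                             ifelse(grid$mirror, "m", ""), grid$rotation)
  grid[, c("phantom_id", "fat_id", "gland_id", "tumor_case", "tumor_shape",
           "mirror", "rotation", "n_rotations", "jitter_seed", "model")]
}

#' Held-out test phantom configurations
#'
#' The dedicated test phantom (surrogate of the physical reference model,
#' with geometry never used in the training combinatorics and a tumor in
#' the fatty region on the observation plane) enumerated over 16 rotations
#' and their mirror images: 32 configurations.
#'
#' @param n_rotations Number of rotations (default 16).
#' @return A data.frame with the same columns as [enumerate_configs()].
#' @export
test_configs <- function(n_rotations = 16L) {
  grid <- expand.grid(rotation = 0:(n_rotations - 1L),
                      mirror = c(FALSE, TRUE), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$mirror, grid$rotation), , drop = FALSE]
  rownames(grid) <- NULL
  data.frame(
    phantom_id = sprintf("test%s_r%02d", ifelse(grid$mirror, "m", ""),
                         grid$rotation),
    fat_id = 0L, gland_id = 0L, tumor_case = 2L, tumor_shape = "T",
    mirror = grid$mirror, rotation = grid$rotation,
    n_rotations = as.integer(n_rotations),
    jitter_seed = 999L, model = "test",
    stringsAsFactors = FALSE
  )
}

#' Voxel grid specification
#'
#' Axis-aligned grid centered on the camera axis: `n` x `n` transverse
#' voxels at the retina spacing and `n_y` slabs along the propagation
#' axis. 0-based voxel index i maps to coordinate `(i - n/2) * spacing`.
#'
#' @param geom A [camera_geometry()].
#' @param n Transverse samples per axis (defaults to the retina size).
#' @param n_y Number of y slabs.
#' @param spacing Voxel pitch in m (defaults to the retina spacing).
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(geom, n = geom$n, n_y = 36L, spacing = geom$spacing) {
  structure(list(n = as.integer(n), n_y = as.integer(n_y),
                 spacing = spacing,
                 x = centered_axis(n, spacing),
                 y = centered_axis(n_y, spacing),
                 z = centered_axis(n, spacing)),
            class = "grid_spec")
}

.tissue_codes <- c(water = 0L, skin = 1L, fat = 2L, glandular = 3L,
                   tumor = 4L)

#' Build a voxel phantom from a configuration
#'
#' Paints the tissue labels on the voxel grid with precedence
#' tumor > gland > fat > skin > water, after applying the view transform:
#' the solid is mirrored (x -> -x) and then rotated about the vertical
#' z axis by `2*pi*rotation/n_rotations`. Because the wave propagates
#' along y, the mirrored phantom is not equivalent to any rotation of the
#' original. The complex relative permittivity per voxel is taken from the
#' (jittered) dielectric table.
#'
#' @param config One row of [enumerate_configs()] or [test_configs()].
#' @param dielectrics A `tissue_dielectrics` table (jitter it beforehand
#'   with the config's `jitter_seed` for database generation).
#' @param grid A [grid_spec()].
#' @return A `voxel_phantom`: list with `labels` and complex `eps` arrays
#'   of dim `c(n, n_y, n)` (x, y, z order), the grid, config and
#'   dielectrics.
#' @export
build_phantom <- function(config, dielectrics, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  config <- as.list(config[1, , drop = FALSE])
  lib <- cavity_library()
  if (config$model == "train" &&
      !gland_fits(config$fat_id, config$gland_id, lib)) {
    stop(sprintf(
      "glandular cavity %d does not nest inside fat shell %d",
      config$gland_id, config$fat_id))
  }

  # voxel centers, transformed into the untransformed solid's frame:
  # rotate by -theta about z, then mirror x -> -x
  pts <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z,
                               KEEP.OUT.ATTRS = FALSE))
  theta <- 2 * pi * config$rotation / config$n_rotations
  ct <- cos(theta); st <- sin(theta)
  xr <- ct * pts[, 1L] + st * pts[, 2L]
  yr <- -st * pts[, 1L] + ct * pts[, 2L]
  if (isTRUE(config$mirror)) xr <- -xr
  q <- cbind(xr, yr, pts[, 3L])

  solids <- phantom_solids(config, lib)
  labels <- rep(.tissue_codes[["water"]], nrow(q))
  for (s in solids) {   # painted in precedence order
    labels[inside_solid(q, s$center, s$semi, s$p)] <- .tissue_codes[[s$tissue]]
  }

  eps_by_code <- vapply(names(.tissue_codes), function(t)
    complex_permittivity(dielectrics, t), complex(1))
  eps <- eps_by_code[labels + 1L]

  dim_arr <- c(grid$n, grid$n_y, grid$n)
  structure(list(
    labels = array(labels, dim_arr),
    eps = array(eps, dim_arr),
    grid = grid, config = config, dielectrics = dielectrics
  ), class = "voxel_phantom")
}

#' Solid list (in painting order) for a configuration
#' @keywords internal
phantom_solids <- function(config, lib = cavity_library()) {
  solids <- list()
  if (config$model == "test") {
    tg <- lib$test
    outer <- tg$fat$inner + tg$fat$skin
    solids <- c(solids, list(
      list(tissue = "skin", center = c(0, 0, 0), semi = outer, p = tg$fat$p),
      list(tissue = "fat", center = c(0, 0, 0), semi = tg$fat$inner,
           p = tg$fat$p)))
    for (g in tg$gland) {
      solids <- c(solids, list(
        list(tissue = "glandular", center = g$center, semi = g$semi, p = 2)))
    }
    gx <- max(vapply(tg$gland, function(g) g$center[1L] + g$semi[1L],
                     numeric(1)))
    tc <- c((gx + tg$fat$inner[1L]) / 2, 0, 0)
    solids <- c(solids, list(
      list(tissue = "tumor", center = tc, semi = tg$tumor$semi, p = 2)))
    return(solids)
  }
  fat <- lib$fat[[config$fat_id]]
  gland <- lib$gland[[config$gland_id]]
  solids <- c(solids, list(
    list(tissue = "skin", center = c(0, 0, 0), semi = fat$inner + fat$skin,
         p = fat$p),
    list(tissue = "fat", center = c(0, 0, 0), semi = fat$inner, p = fat$p),
    list(tissue = "glandular", center = lib$gland_offset, semi = gland$semi,
         p = gland$p)))
  if (config$tumor_case %in% c(2L, 4L)) {  # adipose tumor
    solids <- c(solids, list(
      list(tissue = "tumor",
           center = adipose_tumor_center(config$fat_id, config$gland_id, lib),
           semi = lib$tumor[[config$tumor_shape]], p = 2)))
  }
  if (config$tumor_case %in% c(3L, 4L)) {  # glandular tumor
    solids <- c(solids, list(
      list(tissue = "tumor",
           center = lib$gland_offset + lib$glandular_tumor_offset,
           semi = lib$tumor[[config$tumor_shape]], p = 2)))
  }
  solids
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("<voxel_phantom>", x$config$phantom_id, "\n")
  cat(sprintf("  grid %d x %d x %d, spacing %.3f mm\n", dim(x$labels)[1],
              dim(x$labels)[2], dim(x$labels)[3], x$grid$spacing * 1e3))
  tab <- table(factor(x$labels, levels = .tissue_codes,
                      labels = names(.tissue_codes)))
  print(tab)
  invisible(x)
}

#' Complex dielectric contrast on an observation plane
#'
#' Extracts the slice y = `plane_y` of the phantom and forms the contrast
#' `C = (eps' - eps'_water) - 1i*(eps'' - eps''_water)`, which is exactly
#' `eps_complex - eps_water_complex` under the stored sign convention.
#' Water pixels have C = 0 by construction; the contour mask marks
#' non-water pixels.
#'
#' @param phantom A [build_phantom()] result.
#' @param geom A [camera_geometry()] (for the water reference).
#' @param plane_y Plane coordinate in m (must lie inside the grid).
#' @return A `contrast_map`: list with complex matrix `C` (n x n, x by z),
#'   logical `mask`, and the slice's tissue `labels`.
#' @export
contrast_slice <- function(phantom, geom, plane_y = 0) {
  y <- phantom$grid$y
  if (plane_y < min(y) - phantom$grid$spacing / 2 ||
      plane_y > max(y) + phantom$grid$spacing / 2) {
    stop("plane_y = ", plane_y, " lies outside the voxel grid")
  }
  j <- which.min(abs(y - plane_y))
  eps <- phantom$eps[, j, ]
  labels <- phantom$labels[, j, ]
  structure(list(
    C = eps - geom$eps_water_complex,
    mask = labels != .tissue_codes[["water"]],
    labels = labels,
    plane_y = y[j]
  ), class = "contrast_map")
}

#' Shuffle and split the training enumeration
#'
#' Deterministic seeded shuffle of the (test-phantom-free) training
#' configurations, then a floor(train_fraction * n) head/tail split.
#' For the full 1792-sample enumeration at the default fraction this
#' yields 1433 training and 359 validation samples; the held-out test
#' phantom contributes its own 32 views.
#'
#' @param configs Data.frame from [enumerate_configs()].
#' @param train_fraction Fraction in (0, 1) (default 0.8).
#' @param shuffle_seed Integer seed for the shuffle.
#' @return List with data.frames `train`, `validation`, `test`.
#' @export
split_dataset <- function(configs, train_fraction = 0.8, shuffle_seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  if (any(configs$model != "train")) {
    stop("the held-out test phantom must be excluded before splitting")
  }
  n <- nrow(configs)
  perm <- withr_rng(shuffle_seed, function() sample.int(n))
  shuffled <- configs[perm, , drop = FALSE]
  n_train <- floor(train_fraction * n)
  train <- shuffled[seq_len(n_train), , drop = FALSE]
  validation <- shuffled[setdiff(seq_len(n), seq_len(n_train)), ,
                         drop = FALSE]
  validation$model <- "validation"
  rownames(train) <- rownames(validation) <- NULL
  list(train = train, validation = validation,
       test = test_configs(n_rotations = max(configs$n_rotations)))
}
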