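test_that("database enumeration reproduces the combinatorial counts", {
  expect_equal(nrow(enumerate_configs(FALSE, FALSE, 1)), 14L)
  expect_equal(nrow(enumerate_configs(TRUE, FALSE, 1)), 56L)
  expect_equal(nrow(enumerate_configs(TRUE, TRUE, 16)), 1792L)
  # deterministic sorted enumeration
  expect_identical(enumerate_configs(TRUE, TRUE, 16),
                   enumerate_configs(TRUE, TRUE, 16))
})

test_that("only glandular cavity 5 fails to nest, and only in fat shell 1", {
  fits <- outer(1:3, 1:5, Vectorize(gland_fits))
  expect_false(fits[1, 5])
  expect_equal(sum(fits), 14L)
})

test_that("each tumor shape is associated with one glandular cavity", {
  cfgs <- enumerate_configs(TRUE, FALSE, 1)
  tab <- unique(cfgs[cfgs$tumor_case > 1, c("gland_id", "tumor_shape")])
  expect_equal(nrow(tab), length(unique(tab$gland_id)))
  expect_equal(anyDuplicated(tab$tumor_shape), 0L)
})

test_that("rotation index maps to angle 2*pi*k/16", {
  cfgs <- enumerate_configs(TRUE, TRUE, 16)
  expect_setequal(unique(cfgs$rotation), 0:15)
  expect_equal(unique(cfgs$n_rotations), 16L)
})

test_that("tumor cases paint the expected voxels", {
  di <- tissue_dielectrics()
  c1 <- fix_config(tumor_case = 1L, rotation = 0L, mirror = FALSE)
  p1 <- build_phantom(c1, di, fix_grid)
  expect_equal(sum(p1$labels == 4L), 0L)

  c4 <- fix_config(tumor_case = 4L, rotation = 0L, mirror = FALSE,
                   gland_id = 4L)
  p4 <- build_phantom(c4, di, fix_grid)
  expect_gt(sum(p4$labels == 4L), 0L)
  # two separated tumors: one inside the glandular region, one in fat
  tum <- which(p4$labels == 4L, arr.ind = TRUE)
  lib <- cavity_library()
  pts <- cbind(fix_grid$x[tum[, 1]], fix_grid$y[tum[, 2]],
               fix_grid$z[tum[, 3]])
  gl <- inside_solid(pts, lib$gland_offset, lib$gland[[4]]$semi, 2)
  expect_gt(sum(gl), 0)    # glandular tumor voxels
  expect_gt(sum(!gl), 0)   # adipose tumor voxels
})

test_that("mirroring twice restores the phantom exactly", {
  di <- tissue_dielectrics()
  cfg <- fix_config(tumor_case = 2L, rotation = 5L, mirror = FALSE)
  cfg_m <- cfg
  cfg_m$mirror <- TRUE
  p0 <- build_phantom(cfg, di, fix_grid)
  pm <- build_phantom(cfg_m, di, fix_grid)
  expect_false(identical(p0$labels, pm$labels))
  # mirroring the solid is an involution: toggling the flag back restores it
  cfg_mm <- cfg_m
  cfg_mm$mirror <- FALSE
  expect_identical(build_phantom(cfg_mm, di, fix_grid)$labels, p0$labels)
})

test_that("mirror differs from the 180-degree rotation", {
  di <- tissue_dielectrics()
  cfg <- fix_config(tumor_case = 2L, rotation = 0L, mirror = TRUE)
  cfg8 <- fix_config(tumor_case = 2L, rotation = 8L, mirror = FALSE)
  pm <- build_phantom(cfg, di, fix_grid)
  p8 <- build_phantom(cfg8, di, fix_grid)
  expect_false(identical(pm$labels, p8$labels))
})

test_that("build_phantom is deterministic and rejects non-nesting pairs", {
  di <- tissue_dielectrics()
  cfg <- fix_config()
  expect_identical(build_phantom(cfg, di, fix_grid)$eps,
                   build_phantom(cfg, di, fix_grid)$eps)
  bad <- cfg
  bad$fat_id <- 1L; bad$gland_id <- 5L
  expect_error(build_phantom(bad, di, fix_grid), "does not nest")
})

test_that("background voxels carry water and tissues are piecewise constant", {
  ph <- fix_phantom()
  expect_true(all(ph$eps[ph$labels == 0L] == fix_geom$eps_water_complex))
  for (code in sort(unique(as.vector(ph$labels)))) {
    expect_length(unique(ph$eps[ph$labels == code]), 1L)
  }
})

test_that("contrast slice obeys the contrast definition", {
  di <- tissue_dielectrics()   # nominal values
  cfg <- fix_config(tumor_case = 2L, rotation = 0L, mirror = FALSE)
  ph <- build_phantom(cfg, di, fix_grid)
  cm <- contrast_slice(ph, fix_geom, plane_y = 0)
  # water pixels: C exactly zero; mask marks non-water
  expect_true(all(cm$C[!cm$mask] == 0))
  expect_identical(cm$mask, cm$labels != 0L)
  # nominal tumor pixel: Re(C) = 53 - 73 = -20
  expect_equal(unique(Re(cm$C[cm$labels == 4L])), -20)
  # fat pixel imaginary part: independent hand evaluation of the
  # contrast definition, -(eps''_fat - eps''_water)
  omega <- 2 * pi * 2.45e9; eps0 <- 8.8541878128e-12
  im_expected <- -(0.1 / (omega * eps0) - 1.0 / (omega * eps0))
  expect_gt(im_expected, 0)
  expect_equal(unique(Im(cm$C[cm$labels == 2L])), im_expected)
  # real part of C is non-positive for every tissue (all eps' < 73)
  expect_true(all(Re(cm$C) <= 0))
  expect_error(contrast_slice(ph, fix_geom, plane_y = 1), "outside")
})

test_that("held-out test phantom has a tumor in fat on the central plane", {
  di <- tissue_dielectrics()
  tc <- test_configs()
  expect_equal(nrow(tc), 32L)
  ph <- build_phantom(tc[1, ], di, fix_grid)
  cm <- contrast_slice(ph, fix_geom, plane_y = 0)
  expect_gt(sum(cm$labels == 4L), 0L)
})
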