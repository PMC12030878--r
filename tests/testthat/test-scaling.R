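test_that("min-max scaling maps each part onto [0,1] exactly", {
  x <- matrix(complex(real = c(-2, 0, 2, 1), imaginary = c(1, 3, 2, 0)), 2, 2)
  s <- minmax_complex(x)
  expect_equal(sort(unique(Re(s))), c(0, 0.5, 0.75, 1))
  expect_equal(range(Re(s)), c(0, 1))
  expect_equal(range(Im(s)), c(0, 1))
  # idempotent on an image already spanning [0,1] in both parts
  expect_equal(minmax_complex(s), s, ignore_attr = TRUE)
  expect_error(minmax_complex(matrix(2 + 1i * 1:4, 2, 2)), "constant")
  # scaling record allows traceability
  sc <- attr(s, "scaling")
  expect_equal(sc$re_min, -2); expect_equal(sc$re_max, 2)
})

test_that("spectrum normalization bounds parts in [-1,1] with unit max modulus", {
  ph <- fix_phantom()
  cm <- contrast_slice(ph, fix_geom, 0)
  ns <- spectrum_normalize(minmax_complex(cm$C), fix_geom)
  expect_equal(dim(ns$values), c(17L, 17L))
  expect_equal(max(Mod(ns$values[ns$mask])), 1)
  expect_true(all(Re(ns$values) >= -1 & Re(ns$values) <= 1))
  expect_true(all(Im(ns$values) >= -1 & Im(ns$values) <= 1))
  expect_true(all(ns$values[!ns$mask] == 0))
  # renormalizing a normalized spectrum changes nothing but the record:
  # dividing by a positive real preserves every phase
  mm <- max(Mod(ns$values[ns$mask]))
  expect_equal(mm, 1)
  raw <- crop_box(visible_filter(field_spectrum(minmax_complex(cm$C),
                                                fix_geom), 0.5, fix_geom))
  keep <- ns$mask & Mod(ns$values) > 0
  expect_equal(Arg(ns$values[keep]), Arg(raw$values[keep]),
               tolerance = 1e-12)
})

test_that("water calibration has the stated fixed points and invariance", {
  set.seed(9)
  img <- matrix(complex(real = rnorm(64^2, 1), imaginary = rnorm(64^2, 2)),
                64, 64)
  mask <- matrix(FALSE, 64, 64)
  mask[20:40, 20:40] <- TRUE
  # constant water region: every outside pixel equals the water mean and
  # must map exactly to (73, 1)
  img[!mask] <- 0.4 + 0.7i
  cal <- water_calibrate(img, mask, fix_geom)
  expect_equal(cal$M_re, 0.4)
  expect_equal(cal$M_im, 0.7)
  expect_true(all(cal$eps_cal[!mask] == 73))
  expect_true(all(cal$sigma_cal[!mask] == 1))
  # scale invariance: doubling the image leaves the calibration unchanged
  cal3 <- water_calibrate(2 * img, mask, fix_geom)
  expect_equal(cal3$eps_cal, cal$eps_cal)
  expect_equal(cal3$sigma_cal, cal$sigma_cal)
  expect_error(water_calibrate(img, matrix(TRUE, 64, 64), fix_geom),
               "no water")
})

test_that("property rescaling matches a hand evaluation and stays positive", {
  # 3-pixel toy map, hand-evaluated
  maps <- structure(list(
    eps_cal = matrix(c(-10, 20, 50, 30), 2, 2),
    sigma_cal = matrix(c(-0.5, 0.25, 1.5, 1.0), 2, 2),
    M_re = 1, M_im = 1, contour_mask = matrix(TRUE, 2, 2),
    geom = fix_geom), class = "calibrated_maps")
  out <- rescale_properties(maps)
  # eps: spans [min|.|, max|.|] = [10, 50]; x=-10 -> 10, x=50 -> 50
  expect_equal(out$eps_net[1, 1], 10)
  expect_equal(out$eps_net[1, 2], 50)
  expect_equal(out$eps_net[2, 1], 10 + 40 * (20 - (-10)) / 60)
  # sigma: reversed structure max|.| + (min|.|-max|.|) * t
  t_vals <- (maps$sigma_cal - (-0.5)) / 2
  expect_equal(out$sigma_net, 1.5 + (0.25 - 1.5) * t_vals)
  expect_true(all(out$eps_net >= 0))
  expect_true(all(out$sigma_net >= 0))
  bad <- maps; bad$eps_cal <- matrix(1, 2, 2)
  expect_error(rescale_properties(bad), "constant")
})

test_that("contour prior enforces water outside and is idempotent", {
  set.seed(10)
  maps <- structure(list(
    eps_cal = matrix(rnorm(16, 40), 4, 4),
    sigma_cal = matrix(abs(rnorm(16, 1)), 4, 4),
    contour_mask = matrix(c(rep(FALSE, 8), rep(TRUE, 8)), 4, 4),
    geom = fix_geom), class = "calibrated_maps")
  maps <- rescale_properties(maps)
  inside_before <- maps$eps_net[maps$contour_mask]
  out <- apply_contour_prior(maps)
  expect_true(all(out$eps_net[!out$contour_mask] == 73))
  expect_true(all(out$sigma_net[!out$contour_mask] == 1))
  expect_identical(out$eps_net[out$contour_mask], inside_before)
  expect_identical(apply_contour_prior(out), out)
  # all-water mask gives constant maps
  aw <- maps; aw$contour_mask <- matrix(FALSE, 4, 4)
  awo <- apply_contour_prior(aw)
  expect_true(all(awo$eps_net == 73) && all(awo$sigma_net == 1))
})

test_that("a perfect network recovers water exactly outside the contour", {
  # round trip: normalize the reference contrast, pretend the network is
  # perfect (C_net = C_norm), denormalize with the contour prior
  ph <- fix_phantom()
  cm <- contrast_slice(ph, fix_geom, 0)
  Cnorm <- spectrum_normalize(minmax_complex(cm$C), fix_geom)
  maps <- reconstruct_maps(Cnorm, cm$mask, fix_geom)
  expect_true(all(maps$eps_net[!cm$mask] == 73))
  expect_true(all(maps$sigma_net[!cm$mask] == 1))
  expect_true(all(maps$eps_net >= 0) && all(maps$sigma_net >= 0))
  # inside values live within the physical display ranges up to
  # spectral-truncation ringing
  expect_lt(max(maps$eps_net), 110)
})
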