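test_that("centered transform pair has the stated conventions", {
  geom <- fix_geom
  n <- geom$n
  # constant field -> delta at DC (0-based index 32 = 1-based 33)
  const <- matrix(1 + 0i, n, n)
  S <- field_spectrum(const, geom)
  expect_equal(Mod(S[33, 33]), n^2 * geom$spacing^2)
  S[33, 33] <- 0
  expect_equal(max(Mod(S)), 0)
  # off-center delta -> flat magnitude, linear phase ramp
  delta <- matrix(0 + 0i, n, n)
  delta[36, 33] <- 1
  D <- field_spectrum(delta, geom)
  expect_equal(Mod(D), matrix(geom$spacing^2, n, n))
  sg <- fix_sg
  expect_equal(Arg(D[20, 33]),
               Arg(exp(-1i * sg$kx[20, 33] * centered_axis(n, geom$spacing)[36])),
               tolerance = 1e-9)
  # round trip is the identity to round-off
  set.seed(11)
  x <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  expect_lt(rel_err(inverse_cfft2(cfft2(x, geom$spacing), geom$spacing), x),
            1e-13)
  expect_error(field_spectrum(x[1:10, 1:10], geom), "64")
})

test_that("the diffraction relation inverts exactly on the visible mask", {
  sg <- fix_sg
  g <- Re(sg$gamma)
  set.seed(4)
  jhat <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  # forward relation E_hat = (-i/2gamma) jhat e^{-i gamma d}; guard rim
  Ehat <- matrix(0 + 0i, 64, 64)
  ok <- sg$visible & g > 0
  Ehat[ok] <- (-1i / (2 * g[ok])) * jhat[ok] * exp(-1i * g[ok] * fix_geom$d)
  rec <- diffraction_map(Ehat, fix_geom)
  expect_equal(rec$values[ok], jhat[ok], tolerance = 1e-12)
  expect_true(all(rec$values[!sg$visible] == 0))
  # zero spectrum maps to zero currents
  expect_equal(max(Mod(diffraction_map(matrix(0 + 0i, 64, 64),
                                       fix_geom)$values)), 0)
})

test_that("half-visible filter keeps 197 pixels in a 17x17 box", {
  ones <- matrix(1 + 0i, 64, 64)
  f <- visible_filter(ones, 0.5, fix_geom)
  expect_equal(sum(f$mask), 197L)
  expect_equal(sum(Mod(f$values)), 197)
  # support fits the 17x17 box around DC
  act <- which(f$mask, arr.ind = TRUE)
  expect_true(all(abs(act - 33) <= 8))
  # full-visible count under the same inclusive rule
  expect_equal(sum(visible_filter(ones, 1.0, fix_geom)$mask), 797L)
  # idempotence
  expect_identical(visible_filter(f, 0.5)$values, f$values)
  expect_error(visible_filter(ones, 0.7, fix_geom), "fraction")
})

test_that("crop and embed are exact inverses preserving the mask", {
  set.seed(5)
  x <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  f <- visible_filter(x, 0.5, fix_geom)
  cr <- crop_box(f)
  expect_equal(dim(cr$values), c(17L, 17L))
  expect_equal(sum(cr$mask), 197L)
  # DC pixel lands at the crop center (0-based (8,8))
  expect_equal(cr$values[9, 9], f$values[33, 33])
  emb <- embed_box(cr)
  expect_identical(emb$values, f$values)
  expect_identical(emb$mask, f$mask)
  # full-visible support does not fit and must be rejected
  expect_error(crop_box(visible_filter(x, 1.0, fix_geom)), "outside")
})

test_that("backprojection satisfies Parseval and zero maps to zero", {
  geom <- fix_geom
  expect_equal(max(Mod(backproject(matrix(0 + 0i, 64, 64), geom))), 0)
  set.seed(6)
  S <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  img <- backproject(S, geom)
  # Riemann-sum Parseval: sum|img|^2 * N * spacing^4 = sum|S|^2
  expect_equal(sum(Mod(img)^2) * 64^2 * geom$spacing^4,
               sum(Mod(S)^2), tolerance = 1e-10)
})

test_that("full Born chain equals the y-integrated current reference", {
  ph <- fix_phantom()
  fld <- born_forward(ph, fix_geom)
  chain <- backproject(
    visible_filter(diffraction_map(field_spectrum(fld, fix_geom), fix_geom),
                   0.5),
    fix_geom)
  Jref <- born_current_reference(ph, fix_geom)
  Jref[!fix_sg$half_visible] <- 0
  ref <- backproject(Jref, fix_geom)
  expect_lt(rel_err(chain, ref), 1e-9)
  # the backprojected current peaks inside the phantom footprint
  cm <- contrast_slice(ph, fix_geom, 0)
  peak <- which(Mod(chain) == max(Mod(chain)), arr.ind = TRUE)
  expect_true(cm$mask[peak[1], peak[2]])
})

test_that("NSD normalizes to 0 dB and is scale invariant", {
  set.seed(8)
  S <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  m <- nsd(S)
  expect_equal(max(m), 0)
  expect_equal(nsd(5i * S), m)
  # squared-magnitude reading: |j| = max/10 is -20 dB
  T2 <- matrix(0 + 0i, 4, 4)
  T2[1, 1] <- 10; T2[2, 2] <- 1
  expect_equal(nsd(T2)[2, 2], -20)
  expect_error(nsd(matrix(0 + 0i, 4, 4)), "all-zero")
})

test_that("differential image isolates the tumor contribution", {
  di <- tissue_dielectrics()
  cfg2 <- fix_config(tumor_case = 2L, rotation = 0L, mirror = FALSE)
  cfg1 <- fix_config(tumor_case = 1L, rotation = 0L, mirror = FALSE)
  run <- function(cfg) {
    ph <- build_phantom(cfg, di, fix_grid)
    backproject(visible_filter(diffraction_map(
      field_spectrum(born_forward(ph, fix_geom), fix_geom), fix_geom), 0.5),
      fix_geom)
  }
  j2 <- run(cfg2); j1 <- run(cfg1)
  d <- differential_image(j2, j1)
  expect_true(all(d >= 0))
  expect_equal(max(differential_image(j2, j2)), 0)
  # by Born linearity the difference equals the tumor-only chain
  ph2 <- build_phantom(cfg2, di, fix_grid)
  ph1 <- build_phantom(cfg1, di, fix_grid)
  pht <- ph2
  pht$eps <- fix_geom$eps_water_complex + (ph2$eps - ph1$eps)
  jt <- backproject(visible_filter(diffraction_map(
    field_spectrum(born_forward(pht, fix_geom), fix_geom), fix_geom), 0.5),
    fix_geom)
  # the phantoms differ only on the tumor voxels, so j2 - j1 equals the
  # chain of the difference contrast
  expect_lt(rel_err(j2 - j1, jt), 1e-9)
  expect_error(differential_image(j2, j1[1:10, 1:10]), "same grid")
})

test_that("half-visible filtering makes the current image noise-robust", {
  # SSIM between noisy (10 dB) and noiseless filtered current images on
  # the held-out test phantom stays high: the filter removes most noise
  di <- tissue_dielectrics()
  ph <- build_phantom(test_configs()[1, ], di, fix_grid)
  fld <- born_forward(ph, fix_geom)
  chain <- function(f) backproject(visible_filter(diffraction_map(
    field_spectrum(f, fix_geom), fix_geom), 0.5), fix_geom)
  j0 <- chain(fld)
  j10 <- chain(add_awgn(fld, 10, seed = 2))
  # the camera's qualitative image is the current magnitude map
  expect_gte(ssim(Mod(j10), Mod(j0)), 0.8)
  # the real part carries almost all of the Born current's energy and
  # stays close; the imaginary part is two orders of magnitude weaker and
  # is not asserted (noise-dominated at this SNR)
  expect_gte(ssim(Re(j10), Re(j0)), 0.7)
})
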