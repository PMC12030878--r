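# Shared fixtures, built once per test run.

fix_geom <- camera_geometry()
fix_grid <- grid_spec(fix_geom)
fix_sg <- spectral_grid(fix_geom)

# one representative tumor-bearing configuration
fix_config <- function(tumor_case = 4L, rotation = 3L, mirror = TRUE,
                       fat_id = 1L, gland_id = 2L) {
  cfgs <- enumerate_configs(TRUE, TRUE, 16)
  row <- cfgs[cfgs$fat_id == fat_id & cfgs$gland_id == gland_id &
                cfgs$tumor_case == tumor_case &
                cfgs$rotation == rotation & cfgs$mirror == mirror, ]
  row[1, , drop = FALSE]
}

fix_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- fix_config()
      di <- jitter_dielectrics(tissue_dielectrics(), cfg$jitter_seed)
      cache <<- build_phantom(cfg, di, fix_grid)
    }
    cache
  }
})

# a phantom that is all water except one tumor voxel
single_voxel_phantom <- function(geom = fix_geom, grid = fix_grid,
                                 ix = 30L, iy = 5L, iz = 35L) {
  cfg <- enumerate_configs(FALSE, FALSE, 1)[1, ]
  di <- tissue_dielectrics()
  ph <- build_phantom(cfg, di, grid)
  ph$eps[] <- geom$eps_water_complex
  ph$labels[] <- 0L
  ph$eps[ix, iy, iz] <- complex_permittivity(di, "tumor")
  ph$labels[ix, iy, iz] <- 4L
  attr(ph, "voxel") <- c(ix = ix, iy = iy, iz = iz)
  ph
}

# y-integrated Born current spectrum with the Ewald phase: the reference
# the diffraction inversion must reproduce (direct slab summation)
born_current_reference <- function(phantom, geom, sg = spectral_grid(geom)) {
  kw2 <- geom$k0^2 * geom$eps_water_complex
  Ei <- incident_field(geom, phantom$grid$y)
  J <- matrix(0 + 0i, sg$n, sg$n)
  g <- Re(sg$gamma)
  for (jy in seq_len(phantom$grid$n_y)) {
    chi <- geom$k0^2 * phantom$eps[, jy, ] - kw2
    if (all(chi == 0)) next
    J <- J + phantom$grid$spacing *
      cfft2(chi * Ei[jy], phantom$grid$spacing) *
      exp(1i * g * phantom$grid$y[jy])
  }
  J
}

rel_err <- function(a, b) {
  sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
}

# tiny normalized dataset from a few simulated configurations
small_dataset <- local({
  cache <- NULL
  function(n = 6L) {
    if (is.null(cache)) {
      cfgs <- enumerate_configs(TRUE, TRUE, 4)
      sel <- cfgs[seq(1L, nrow(cfgs), length.out = 12L), ]
      cache <<- generate_dataset(sel, fix_geom, fix_grid, seed = 99L)
    }
    cache[seq_len(n)]
  }
})

tiny_unet_spec <- function(bottleneck = "channelwise") {
  unet_spec(features = c(4L, 6L, 8L, 10L), bottleneck = bottleneck)
}
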