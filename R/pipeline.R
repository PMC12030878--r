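#' Simulate one database sample end to end
#'
#' Builds the (jittered) phantom for a configuration, simulates the
#' scattered field on the retina, optionally adds noise, runs the
#' spectral chain (spectrum, diffraction inversion, half-visible filter,
#' backprojection), and produces the normalized network input spectrum
#' `j_norm` together with the normalized reference contrast spectrum
#' `C_norm` of the observation-plane slice.
#'
#' @param config One row of [enumerate_configs()] / [test_configs()].
#' @param geom A [camera_geometry()].
#' @param grid A [grid_spec()].
#' @param nominal Nominal [tissue_dielectrics()] (jittered per config).
#' @param snr_db Retina-field SNR in dB (`Inf` for noiseless).
#' @param noise_seed Seed for the noise draw.
#' @param pad_factor Zero-padding factor of the Born solver.
#' @param keep_fields Keep the retina field and current image in the
#'   sample (default `TRUE`).
#' @return A sample list with `jnorm`, `Cnorm` (17x17
#'   `current_spectrum`s), `mask`, `contour`, contrast `C`, and metadata.
#' @export
simulate_sample <- function(config, geom, grid, nominal = tissue_dielectrics(geom$frequency),
                            snr_db = Inf, noise_seed = 1L,
                            pad_factor = 1L, keep_fields = TRUE) {
  dielec <- jitter_dielectrics(nominal, config$jitter_seed)
  phantom <- build_phantom(config, dielec, grid)
  field <- born_forward(phantom, geom, pad_factor = pad_factor)
  if (is.finite(snr_db)) field <- add_awgn(field, snr_db, noise_seed)
  spec <- field_spectrum(field, geom)
  j_hat <- visible_filter(diffraction_map(spec, geom), 0.5)
  j_img <- backproject(j_hat, geom)
  cmap <- contrast_slice(phantom, geom, plane_y = 0)
  jnorm <- spectrum_normalize(minmax_complex(j_img), geom)
  Cnorm <- spectrum_normalize(minmax_complex(cmap$C), geom)
  out <- list(
    id = config$phantom_id, config = as.list(config),
    jnorm = jnorm, Cnorm = Cnorm, mask = jnorm$mask,
    contour = cmap$mask, C = cmap$C,
    snr_db = snr_db, split = config$model
  )
  if (keep_fields) {
    out$field <- field
    out$j_img <- j_img
  }
  out
}

#' Generate a dataset of normalized sample pairs
#'
#' @param configs Data.frame of configurations.
#' @param geom,grid,nominal As in [simulate_sample()].
#' @param seed Base seed (sample i uses noise seed `seed + i`).
#' @param snr_db SNR applied to every retina field.
#' @param pad_factor Born solver padding.
#' @param keep_fields Keep per-sample fields (heavier archives).
#' @param progress Print a dot every 25 samples.
#' @return List of samples (class `mw_dataset`).
#' @export
generate_dataset <- function(configs, geom, grid,
                             nominal = tissue_dielectrics(geom$frequency),
                             seed = 1L, snr_db = Inf, pad_factor = 1L,
                             keep_fields = FALSE, progress = FALSE) {
  samples <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    samples[[i]] <- simulate_sample(configs[i, , drop = FALSE], geom, grid,
                                    nominal, snr_db = snr_db,
                                    noise_seed = seed + i,
                                    pad_factor = pad_factor,
                                    keep_fields = keep_fields)
    if (progress && i %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  structure(samples, class = c("mw_dataset", "list"))
}

#' Write / read a dataset archive
#'
#' One directory with a manifest and one serialized file per sample;
#' read(write(x)) reproduces the samples bit-identically.
#' @param dataset An `mw_dataset` (list of samples).
#' @param dir Archive directory (created if needed).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` the
#'   dataset.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(dataset, `[[`, character(1), "id")
  for (i in seq_along(dataset)) {
    saveRDS(dataset[[i]], file.path(dir, paste0(ids[i], ".rds")),
            version = 3, compress = FALSE)
  }
  utils::write.csv(data.frame(id = ids,
                              split = vapply(dataset, `[[`, character(1),
                                             "split")),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  samples <- lapply(manifest$id, function(id)
    readRDS(file.path(dir, paste0(id, ".rds"))))
  structure(samples, class = c("mw_dataset", "list"))
}

#' Run the full pipeline: generate, split, train, evaluate
#'
#' Reduced-scale, reproducible end-to-end run: enumerates (a subset of)
#' the database, simulates all samples, splits them, trains the U-Net
#' pair and reports metrics on the held-out samples. All stochastic
#' choices (jitter, shuffle, noise, weight init) derive from the seeds
#' in `config`.
#'
#' @param config List: `n_rotations`, `include_mirrors`,
#'   `include_tumors`, `max_samples` (optional cap after shuffling),
#'   `train_fraction`, `epochs`, `batch_size`, `lr`, `features`,
#'   `bottleneck`, `snr_db`, `seed`, `n_y`, `out_dir` (optional: write
#'   artifacts there).
#' @return List with `split` (config tables), `train`, `validation`,
#'   `test` datasets, trained `pair`, `history`, and the `report` of
#'   [evaluate_dataset()] on the test set.
#' @export
run_pipeline <- function(config = list()) {
  cf <- utils::modifyList(list(
    n_rotations = 4L, include_mirrors = TRUE, include_tumors = TRUE,
    max_samples = NULL, train_fraction = 0.8, epochs = 5L,
    batch_size = 3L, lr = 1e-3, features = c(8L, 16L, 32L, 64L),
    bottleneck = "channelwise", snr_db = Inf, seed = 1L, n_y = 36L,
    out_dir = NULL
  ), config)
  geom <- camera_geometry()
  grid <- grid_spec(geom, n_y = cf$n_y)
  configs <- enumerate_configs(cf$include_tumors, cf$include_mirrors,
                               cf$n_rotations)
  split <- split_dataset(configs, cf$train_fraction, shuffle_seed = cf$seed)
  if (!is.null(cf$max_samples)) {
    split$train <- utils::head(split$train, cf$max_samples)
    split$validation <- utils::head(split$validation,
                                    max(2L, cf$max_samples %/% 4L))
  }
  ds_train <- generate_dataset(split$train, geom, grid, seed = cf$seed,
                               snr_db = cf$snr_db)
  ds_val <- generate_dataset(split$validation, geom, grid,
                             seed = cf$seed + 10000L, snr_db = cf$snr_db)
  ds_test <- generate_dataset(split$test, geom, grid,
                              seed = cf$seed + 20000L, snr_db = cf$snr_db)
  spec <- unet_spec(features = cf$features, bottleneck = cf$bottleneck)
  pair <- unet_pair(spec, seed = cf$seed)
  pair <- train_unet_pair(pair, ds_train, epochs = cf$epochs,
                          batch_size = cf$batch_size, lr = cf$lr,
                          seed = cf$seed, validation = ds_val)
  report <- evaluate_dataset(pair, ds_test, batch_size = cf$batch_size)
  out <- list(config = cf, split = split, train = ds_train,
              validation = ds_val, test = ds_test, pair = pair,
              history = pair$history, report = report)
  if (!is.null(cf$out_dir)) {
    dir.create(cf$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(ds_train, file.path(cf$out_dir, "train"))
    write_dataset(ds_val, file.path(cf$out_dir, "validation"))
    write_dataset(ds_test, file.path(cf$out_dir, "test"))
    saveRDS(pair, file.path(cf$out_dir, "unet_pair.rds"))
    utils::write.csv(pair$history,
                     file.path(cf$out_dir, "training_log.csv"),
                     row.names = FALSE)
  }
  out
}

#' Plot reconstructed permittivity and conductivity maps
#'
#' Side-by-side images with the camera's display ranges: relative
#' permittivity on [1, 73] and conductivity on [0, 2] S/m.
#' @param maps A `calibrated_maps` with `eps_net`/`sigma_net`.
#' @param ... Passed to [graphics::image()].
#' @export
plot_property_maps <- function(maps, ...) {
  stopifnot(inherits(maps, "calibrated_maps"))
  op <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(maps$eps_net, zlim = c(1, 73), main = "eps_r",
                  col = grDevices::hcl.colors(64, "viridis"),
                  useRaster = TRUE, ...)
  graphics::image(pmin(pmax(maps$sigma_net, 0), 2), zlim = c(0, 2),
                  main = "sigma [S/m]",
                  col = grDevices::hcl.colors(64, "viridis"),
                  useRaster = TRUE, ...)
  invisible(maps)
}

#' Plot the normalized spectral density map
#' @param j_hat A `current_spectrum`.
#' @param floor_db dB floor for display (default -60).
#' @param ... Passed to [graphics::image()].
#' @export
plot_nsd <- function(j_hat, floor_db = -60, ...) {
  m <- nsd(j_hat, floor_db = floor_db)
  m[m < floor_db] <- floor_db
  graphics::image(m, zlim = c(floor_db, 0), main = "NSD [dB]",
                  col = grDevices::hcl.colors(64, "inferno"),
                  useRaster = TRUE, ...)
  invisible(m)
}
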