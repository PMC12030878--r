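test_that("full-scale architecture arithmetic reproduces the size table", {
  spec <- unet_spec()
  expect_equal(spec$features, c(32L, 64L, 128L, 256L))
  expect_equal(spec$enc_sizes, c(13L, 11L, 9L, 7L))
  expect_equal(spec$dec_sizes, c(9L, 11L, 13L, 17L))
  expect_equal(spec$sizes, c(13L, 11L, 9L, 7L, 7L, 9L, 11L, 13L, 17L))
})

test_that("invalid size arithmetic is rejected naming the step", {
  expect_error(unet_spec(kernels = c(23L, 7L, 5L, 3L)),
               "compression step 1")
  expect_error(unet_spec(kernels = c(17L, 7L, 5L, 3L)),
               "compression step 4")
  expect_error(unet_spec(dec_pads = c(2L, 2L, 2L, 2L)),
               "step 9")
})

test_that("builds are seeded and deterministic with finite outputs", {
  spec <- tiny_unet_spec()
  n1 <- build_unet(spec, seed = 3)
  n2 <- build_unet(spec, seed = 3)
  x <- matrix(0, 17, 17)
  y1 <- unet_forward(n1, x)$out
  expect_equal(dim(y1), c(17L, 17L, 1L, 1L))
  expect_true(all(is.finite(y1)))
  expect_identical(unet_forward(n2, x)$out, y1)
  n3 <- build_unet(spec, seed = 4)
  expect_false(identical(unet_forward(n3, x)$out, y1))
})

test_that("intermediate activations follow the size trace", {
  spec <- tiny_unet_spec()
  net <- build_unet(spec, 1)
  x <- array(rnorm(17 * 17 * 2), c(17, 17, 1, 2))
  fw <- unet_forward(net, x, training = TRUE)
  dims <- vapply(c("enc1", "enc2", "enc3", "enc4"), function(nm)
    fw$cache[[nm]]$main$out_h, integer(1))
  expect_equal(unname(dims), c(13L, 11L, 9L, 7L))
  expect_equal(dim(fw$out), c(17L, 17L, 1L, 2L))
})

test_that("backpropagation matches numerical gradients", {
  spec <- unet_spec(features = c(2L, 3L, 4L, 5L), bottleneck = "dense")
  net <- build_unet(spec, 7)
  set.seed(42)
  x <- array(rnorm(17 * 17 * 2), c(17, 17, 1, 2))
  r <- array(rnorm(17 * 17 * 2), c(17, 17, 1, 2))
  fw <- unet_forward(net, x, training = TRUE)
  grads <- mwcamera:::unet_backward(fw$net, fw$cache,
                                    mwcamera:::wmape_grad(fw$out, r))
  numgrad <- function(l, p, i) {
    e <- 1e-6
    up <- function(d) {
      n2 <- net
      n2$layers[[l]]$param[[p]][i] <- n2$layers[[l]]$param[[p]][i] + d
      wmape_loss(unet_forward(n2, x, training = TRUE)$out, r)
    }
    (up(e) - up(-e)) / (2 * e)
  }
  checks <- list(c("enc1", "W", 5), c("enc3", "gamma", 2),
                 c("bottleneck", "W", 101), c("dec6", "W", 11),
                 c("dec9", "beta", 1), c("head", "W", 2))
  for (ck in checks) {
    ana <- grads[[ck[1]]][[ck[2]]][as.integer(ck[3])]
    num <- numgrad(ck[1], ck[2], as.integer(ck[3]))
    expect_lt(abs(ana - num) / max(abs(ana), abs(num), 1e-8), 1e-4)
  }
})

test_that("WMAPE has the defining values and scale invariance", {
  r <- matrix(c(2, 0, 0, 0), 2, 2)
  expect_equal(wmape_loss(r, r), 0)
  expect_equal(wmape_loss(r * 0, r), 1)   # zero prediction -> unity
  p <- matrix(1, 2, 2)
  expect_equal(wmape_loss(p, r), 2)       # (1+1+1+1)/2
  set.seed(2)
  a <- matrix(rnorm(16), 4); b <- matrix(rnorm(16), 4)
  expect_equal(wmape_loss(-3.2 * a, -3.2 * b), wmape_loss(a, b))
  expect_error(wmape_loss(a, b * 0), "identically zero")
  expect_error(wmape_loss(a, b[1:2, 1:2]), "shape")
})

test_that("batch partitioning of 1433 items with batch 3 gives 478 batches", {
  expect_equal(length(seq(1L, 1433L, by = 3L)), 478L)
})

test_that("the network has the capacity to learn the identity task", {
  # 30-epoch training on an identity dataset (reference = input) drives
  # the WMAPE under 0.1: a pure capacity check of the architecture
  cfgs <- enumerate_configs(TRUE, TRUE, 4)
  sel <- cfgs[round(seq(1L, nrow(cfgs), length.out = 64L)), ]
  ds <- generate_dataset(sel, fix_geom, fix_grid, seed = 99L)
  inputs <- rep(lapply(ds, function(s) Re(s$jnorm$values)), 3L)
  mask <- ds[[1]]$mask
  net <- build_unet(unet_spec(features = c(8L, 16L, 32L, 64L),
                              bottleneck = "channelwise"), seed = 1L)
  res <- mwcamera:::train_one_net(net, inputs, inputs, mask, epochs = 30L,
                                  batch_size = 3L, lr = 1e-3, beta1 = 0.9,
                                  beta2 = 0.999, seed = 1L)
  expect_lt(res$train_curve[30], res$train_curve[1])
  final <- mwcamera:::eval_loss(res$net, inputs, inputs, mask)
  expect_lt(final, 0.1)
})

test_that("inference masks output, is deterministic and validates input", {
  ds <- small_dataset(2L)
  pair <- unet_pair(tiny_unet_spec(), seed = 2)
  out <- infer(pair, ds[[1]]$jnorm)
  expect_s3_class(out, "current_spectrum")
  expect_true(all(out$values[!out$mask] == 0))
  expect_identical(infer(pair, ds[[1]]$jnorm)$values, out$values)
  bad <- ds[[1]]$jnorm
  bad$values[1, 1] <- 1   # corner is outside the 197-pixel mask
  expect_error(infer(pair, bad), "outside the half-visible mask")
})

test_that("training is deterministic given the seeds", {
  ds <- small_dataset(6L)
  p1 <- train_unet_pair(unet_pair(tiny_unet_spec(), 5), ds, epochs = 2L,
                        seed = 9)
  p2 <- train_unet_pair(unet_pair(tiny_unet_spec(), 5), ds, epochs = 2L,
                        seed = 9)
  expect_identical(p1$history, p2$history)
  expect_identical(infer(p1, ds[[1]]$jnorm)$values,
                   infer(p2, ds[[1]]$jnorm)$values)
})
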