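ns <- asNamespace("msanomaly")

test_that("lr schedule follows the closed-form warmup + cosine curve", {
  cfg <- pretrain_config(epochs = 500L, warmup_epochs = 20L, peak_lr = 0.2)
  expect_equal(lr_schedule(20, cfg), 0.2)
  expect_equal(lr_schedule(10, cfg), 0.1)           # half-way up the ramp
  expect_lt(lr_schedule(499, cfg), 1e-4)            # ~0 at the final epoch
  # continuity at the warmup/cosine junction
  expect_lt(abs(lr_schedule(20, cfg) - cfg$peak_lr), 1e-9)
  expect_error(lr_schedule(-1, cfg), "out of range")
  expect_error(lr_schedule(500, cfg), "out of range")
  expect_error(pretrain_config(epochs = 10L, warmup_epochs = 10L), "smaller")
})

test_that("augment_pair transforms input and target jointly", {
  set.seed(1)
  v <- array(runif(6^3), c(6, 6, 6))
  r <- array(runif(6^3), c(6, 6, 6))
  # find a seed where nothing fires: all three uniform draws > 0.5
  fire_seed <- NULL
  for (s in 1:100) {
    set.seed(s)
    if (all(runif(3) > 0.5)) { fire_seed <- s; break }
  }
  set.seed(fire_seed)
  out <- augment_pair(v, r)
  expect_identical(out$volume, v)
  expect_identical(out$target, r)

  # force a flip only: probability 1 for the first draw, then none
  set.seed(2)
  out2 <- augment_pair(v, r, prob = 1, max_shift = 0L, noise_sd = 0)
  # whatever spatial transform fired was applied identically to both grids
  match_axis <- FALSE
  for (ax in 1:3) {
    if (identical(out2$volume, ns$flip_array(v, ax))) {
      match_axis <- identical(out2$target, ns$flip_array(r, ax))
    }
  }
  expect_true(match_axis)

  # when only the noise augmentation fires, the target is bit-identical
  noise_seed <- NULL
  for (s in 1:200) {
    set.seed(s)
    d <- runif(3)
    if (d[1] > 0.5 && d[2] > 0.5 && d[3] < 0.5) { noise_seed <- s; break }
  }
  set.seed(noise_seed)
  out3 <- augment_pair(v, r, noise_sd = 0.05)
  expect_identical(out3$target, ns$clip01(r))
  expect_false(identical(out3$volume, v))
  expect_true(all(out3$volume >= 0 & out3$volume <= 1))
})

test_that("pair validation catches misalignment and invalid BCE targets", {
  nets <- build_unet(tiny_unet_cfg(), seed = 1L)
  v <- ms_volume(array(0.5, c(16, 16, 16)), patient_id = "A")
  r_ok <- structure(list(data = array(0.1, c(16, 16, 16)),
                         source_volume_id = "A"), class = "residual_volume")
  r_bad_id <- r_ok; r_bad_id$source_volume_id <- "B"
  cfg <- pretrain_config(epochs = 2L, warmup_epochs = 1L, peak_lr = 1e-3,
                         optimizer = "adam_family")
  expect_error(pretrain_reconstructor(nets$encoder, nets$decoder,
                                      list(list(volume = v, residual = r_bad_id)), cfg),
               "misaligned")
  r_bad_range <- r_ok; r_bad_range$data[1] <- 1.5
  expect_error(pretrain_reconstructor(nets$encoder, nets$decoder,
                                      list(list(volume = v, residual = r_bad_range)), cfg),
               "outside")
})

test_that("BCE of an exactly matched binary prediction is numerically zero", {
  tgt <- array(as.numeric(runif(4^3) > 0.5), c(4, 4, 4, 1, 1))
  l <- ns$op_loss_bce(ns$ag_node(tgt), tgt)
  expect_lt(l$value, 1e-6)
})

test_that("short self-supervised pretraining reduces the reconstruction loss", {
  p <- tiny_phantom(seed = 2L)
  vols <- lapply(1:20, function(i) {
    pp <- p; pp$seed <- 300L + i
    pp$lesion_type <- c("polyp_like", "cyst_like")[i %% 2 + 1]
    s <- if (i %% 2 == 0) generate_anomalous_volume(pp) else generate_normal_volume(pp)
    v <- s$volume; v$patient_id <- sprintf("U%02d", i); v
  })
  normals <- vols[vapply(vols, function(v) identical(v$label, "normal"), TRUE)]
  cae <- train_cae(build_cae(tiny_cae_cfg(), seed = 1L), normals, epochs = 5L,
                   batch_size = 4L)
  resids <- generate_residual_dataset(cae, vols, median_kernel = 3L)
  pairs <- Map(function(v, r) list(volume = v, residual = r), vols, resids)
  nets <- build_unet(unet_config(in_edge = 16L, width = 1 / 32), seed = 1L)
  cfg <- pretrain_config(epochs = 8L, warmup_epochs = 2L, peak_lr = 3e-3,
                         batch_size = 4L, optimizer = "adam_family", seed = 5L)
  pre <- pretrain_reconstructor(nets$encoder, nets$decoder, pairs, cfg)
  expect_lt(tail(pre$log$loss, 1), pre$log$loss[1])
  expect_identical(pre$encoder$provenance, "ssl_pretrained")
  expect_identical(nrow(pre$log), 8L)
  # the preserved checkpoint is the epoch with the lowest validation loss
  expect_equal(min(pre$log$val_loss), pre$log$val_loss[which.min(pre$log$val_loss)])
})

test_that("L1 pretraining runs through the identical pipeline", {
  v <- ms_volume(array(runif(16^3), c(16, 16, 16)), patient_id = "A")
  r <- structure(list(data = array(runif(16^3, 0, 0.2), c(16, 16, 16)),
                      source_volume_id = "A"), class = "residual_volume")
  nets <- build_unet(unet_config(in_edge = 16L, width = 1 / 32), seed = 2L)
  cfg <- pretrain_config(loss = loss_spec("L1"), epochs = 3L, warmup_epochs = 1L,
                         peak_lr = 2e-3, batch_size = 1L,
                         optimizer = "adam_family", val_fraction = 0, seed = 1L)
  pre <- pretrain_reconstructor(nets$encoder, nets$decoder,
                                list(list(volume = v, residual = r)), cfg)
  expect_identical(pre$encoder$provenance, "ssl_pretrained")
  expect_true(all(is.finite(pre$log$loss)))
})

test_that("layerwise-adaptive optimization also trains the reconstructor", {
  v <- ms_volume(array(runif(16^3), c(16, 16, 16)), patient_id = "A")
  r <- structure(list(data = array(runif(16^3, 0, 0.2), c(16, 16, 16)),
                      source_volume_id = "A"), class = "residual_volume")
  nets <- build_unet(unet_config(in_edge = 16L, width = 1 / 32), seed = 3L)
  cfg <- pretrain_config(epochs = 6L, warmup_epochs = 2L, peak_lr = 0.05,
                         batch_size = 1L, optimizer = "layerwise_adaptive",
                         val_fraction = 0, augment = FALSE, seed = 1L)
  pre <- pretrain_reconstructor(nets$encoder, nets$decoder,
                                list(list(volume = v, residual = r)), cfg)
  expect_lt(tail(pre$log$loss, 1), pre$log$loss[1])
})
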