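ns <- asNamespace("msanomaly")

test_that("builders preserve shapes across cube edges", {
  for (edge in c(16L, 32L, 64L)) {
    ccfg <- cae_config(in_edge = edge, stage_channels = c(2L, 4L, 8L, 16L),
                       latent_dim = 8L)
    cae <- build_cae(ccfg, seed = 1L)
    x <- array(runif(edge^3), c(edge, edge, edge, 1L, 1L))
    rec <- cae_reconstruct(cae, x)
    expect_identical(dim(rec), dim(x))
    expect_true(all(rec > 0 & rec < 1))  # sigmoid range

    ucfg <- unet_config(in_edge = edge, width = 1 / 32)
    nets <- build_unet(ucfg, seed = 1L)
    rt_e <- ns$net_runtime(nets$encoder, FALSE)
    rt_d <- ns$net_runtime(nets$decoder, FALSE)
    enc <- ns$unet_encoder_forward(ucfg, rt_e$P, rt_e$B, x, FALSE)
    expect_identical(dim(ns$ag_value(enc$pooled)),
                     c(ucfg$stage_channels[4], 1L))
    out <- ns$unet_decoder_forward(ucfg, rt_d$P, rt_d$B, enc$bottleneck,
                                   enc$skips, FALSE)
    expect_identical(dim(ns$ag_value(out)), dim(x))
    expect_true(all(ns$ag_value(out) > 0 & ns$ag_value(out) < 1))
  }
})

test_that("an indivisible edge is a config error", {
  expect_error(cae_config(in_edge = 24L), "divisible")
  expect_error(unet_config(in_edge = 24L), "divisible")
})

test_that("seeded builds are bit-identical; different seeds differ", {
  a <- build_cae(tiny_cae_cfg(), seed = 7L)
  b <- build_cae(tiny_cae_cfg(), seed = 7L)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, build_cae(tiny_cae_cfg(), seed = 8L)$params))
  ua <- build_unet(tiny_unet_cfg(), seed = 7L)
  ub <- build_unet(tiny_unet_cfg(), seed = 7L)
  expect_identical(ua$encoder$params, ub$encoder$params)
  expect_identical(ua$decoder$params, ub$decoder$params)
})

test_that("decoder works with skip connections disabled", {
  edge <- 16L
  ucfg <- unet_config(in_edge = edge, width = 1 / 32, skip_connections = FALSE)
  nets <- build_unet(ucfg, seed = 2L)
  x <- array(runif(edge^3 * 2), c(edge, edge, edge, 1L, 2L))
  rt_e <- ns$net_runtime(nets$encoder, FALSE)
  rt_d <- ns$net_runtime(nets$decoder, FALSE)
  enc <- ns$unet_encoder_forward(ucfg, rt_e$P, rt_e$B, x, FALSE)
  out <- ns$unet_decoder_forward(ucfg, rt_d$P, rt_d$B, enc$bottleneck, enc$skips, FALSE)
  expect_identical(dim(ns$ag_value(out)), dim(x))
})

test_that("classifier head has the declared shape and normalized softmax", {
  enc <- build_unet(tiny_unet_cfg(), seed = 1L)$encoder
  clf <- build_classifier(enc, hidden = 6L, seed = 1L)
  x <- array(runif(16^3 * 3), c(16, 16, 16, 1, 3))
  rt <- ns$net_runtime(clf, FALSE)
  logits <- ns$ag_value(ns$classifier_forward(clf$config, rt$P, rt$B, x, FALSE))
  expect_identical(dim(logits), c(2L, 3L))
  p <- ns$softmax_cols(logits)
  expect_equal(colSums(p), rep(1, 3), tolerance = 1e-6)
  scores <- classifier_scores(clf, list(x[, , , 1, 1]))
  expect_length(scores, 1L)
})

test_that("head and encoder parameters are composable but separate", {
  enc <- build_unet(tiny_unet_cfg(), seed = 3L)$encoder
  clf <- build_classifier(enc, hidden = 6L, seed = 3L)
  x <- array(runif(16^3), c(16, 16, 16, 1, 1))
  feats <- function(model) {
    rt <- ns$net_runtime(model, FALSE)
    encP <- rt$P[startsWith(names(rt$P), "enc__")]
    names(encP) <- sub("^enc__", "", names(encP))
    encB <- rt$B[startsWith(names(rt$B), "enc__")]
    names(encB) <- sub("^enc__", "", names(encB))
    ns$ag_value(ns$unet_encoder_forward(model$config$encoder, encP, encB, x, FALSE)$pooled)
  }
  logits <- function(model) {
    rt <- ns$net_runtime(model, FALSE)
    ns$ag_value(ns$classifier_forward(model$config, rt$P, rt$B, x, FALSE))
  }
  base_f <- feats(clf); base_l <- logits(clf)
  clf_head <- clf
  clf_head$params$head1_w <- clf_head$params$head1_w * 2
  expect_identical(feats(clf_head), base_f)        # head change leaves features
  expect_false(identical(logits(clf_head), base_l))
  clf_enc <- clf
  clf_enc$params$enc__stem_w <- clf_enc$params$enc__stem_w * 2
  expect_false(identical(logits(clf_enc), base_l)) # encoder change moves logits
})

test_that("classifier construction enforces encoder provenance", {
  enc <- build_unet(tiny_unet_cfg(), seed = 1L)$encoder
  enc$provenance <- "cae_trained"
  expect_error(build_classifier(enc), "provenance")
})

test_that("one optimization step moves every trainable block", {
  cae <- build_cae(tiny_cae_cfg(), seed = 4L)
  before <- cae$params
  # batch of 2: with a single sample the 1^3-bottleneck batch statistics are
  # degenerate (zero variance) and gradients legitimately vanish there
  x <- ns$stack_volumes(list(array(runif(16^3), c(16, 16, 16)),
                             array(runif(16^3), c(16, 16, 16))))
  rt <- ns$net_runtime(cae, TRUE)
  opt <- ns$optimizer_new(rt$P, "sgd", lr = 0.5, momentum = 0)
  ns$ag_zero_grad(rt$P)
  out <- ns$cae_forward(cae$config, rt$P, rt$B, x, TRUE)
  ns$ag_backward(ns$op_loss_l2(out, x * 0 + 0.2))
  ns$opt_step(opt)
  after <- lapply(rt$P, ns$ag_value)
  moved <- mapply(function(a, b) !identical(a, b), before, after[names(before)])
  expect_true(all(moved))
})

test_that("halving the stage widths strictly decreases the parameter count", {
  n1 <- n_params(build_unet(unet_config(in_edge = 16L, width = 1 / 8), seed = 1L)$encoder)
  n2 <- n_params(build_unet(unet_config(in_edge = 16L, width = 1 / 16), seed = 1L)$encoder)
  n3 <- n_params(build_unet(unet_config(in_edge = 16L, width = 1 / 32), seed = 1L)$encoder)
  expect_true(n1 > n2 && n2 > n3)
})

test_that("checkpoints round-trip with provenance and config", {
  cae <- build_cae(tiny_cae_cfg(), seed = 5L)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(cae, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, cae$params)
  expect_identical(back$provenance, "random_init")
  expect_identical(back$config, cae$config)
  saveRDS(list(1), path)
  expect_error(load_checkpoint(path), "not a recognised")
  unlink(path)
})
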