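test_that("auroc matches hand counts and the pairwise oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.2, 0.8, 0.3), c(1, 0, 0, 1)), 0.75)
  expect_equal(auroc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(1)
  for (i in 1:20) {
    sc <- round(runif(30), 2)  # rounded scores exercise ties
    y <- rbinom(30, 1, 0.4)
    if (sum(y) == 0 || sum(y) == 30) next
    expect_equal(auroc(sc, y), bf_auroc(sc, y), tolerance = 1e-12)
  }
})

test_that("auprc matches rank enumeration and the prevalence baseline", {
  expect_equal(auprc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auprc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), (1 + 2 / 3) / 2)
  expect_error(auprc(c(0.1, 0.2), c(0, 0)), "positive")
  set.seed(2)
  for (i in 1:20) {
    sc <- runif(40)
    y <- rbinom(40, 1, 0.3)
    if (sum(y) == 0) next
    expect_equal(auprc(sc, y), bf_auprc(sc, y), tolerance = 1e-12)
  }
  # random scores at large n: average precision approaches the positive rate
  set.seed(3)
  ap <- replicate(20, auprc(runif(2000), rbinom(2000, 1, 0.3)))
  expect_lt(abs(mean(ap) - 0.3), 0.02)
})

test_that("f1 matches hand-worked cases", {
  expect_equal(f1_score(c(1, 1, 1, 0), c(1, 1, 1, 0)), 1)
  expect_equal(f1_score(c(1, 1, 0, 0), c(1, 1, 1, 0)), 0.8)
  expect_equal(f1_score(c(0, 0, 0), c(1, 1, 0)), 0)
})

test_that("aggregate_ci implements the Student-t interval over folds", {
  expect_equal(unname(aggregate_ci(c(0.6, 0.6, 0.6))), c(0.6, 0.6, 0.6))
  ci <- aggregate_ci(c(0.7, 0.8))
  hw <- qt(0.975, 1) * sd(c(0.7, 0.8)) / sqrt(2)
  expect_equal(unname(ci), c(0.75, 0.75 - hw, 0.75 + hw))
  set.seed(4)
  v <- runif(5)
  ci2 <- aggregate_ci(v)
  expect_true(ci2["ci_low"] <= ci2["mean"] && ci2["mean"] <= ci2["ci_high"])
  expect_error(aggregate_ci(0.5), "at least two")
})

test_that("metrics_report aggregates fold triplets", {
  pf <- data.frame(auroc = c(0.8, 0.9), auprc = c(0.7, 0.8), f1 = c(0.6, 0.7))
  rep <- metrics_report(pf)
  expect_s3_class(rep, "metrics_report")
  expect_equal(unname(rep$aggregate$auprc["mean"]), 0.75)
  expect_output(print(rep), "auprc")
})

test_that("finetune guards reject provenance mismatch and class collapse", {
  enc <- build_unet(tiny_unet_cfg(), seed = 1L)$encoder
  vols <- lapply(1:12, function(i)
    ms_volume(array(runif(16^3), c(16, 16, 16)), patient_id = sprintf("P%02d", i),
              label = if (i <= 9) "normal" else "anomalous"))
  split <- dataset_split(vols[1:8], vols[9:10], vols[11:12])
  cfg <- finetune_config(epochs = 1L, init = "ssl_pretrained", label_fraction = 1)
  expect_error(finetune_classifier(enc, split, cfg), "provenance")
  # a fraction that empties the anomalous class errors instead of training
  split2 <- dataset_split(vols[c(1:6, 10)], vols[c(7, 11)], vols[c(8, 12)])
  cfg2 <- finetune_config(epochs = 1L, init = "random_init", label_fraction = 0.05)
  expect_error(finetune_classifier(enc, split2, cfg2), "empty|leaves class")
})

test_that("finetuning separates high-contrast phantoms and returns the argmin epoch", {
  p <- tiny_phantom(seed = 1L, noise_sd = 0.01, lesion_intensity = 0.95,
                    lesion_radius_range = c(4, 5))
  samples <- lapply(1:54, function(i) {
    pp <- p; pp$seed <- 600L + i
    pp$lesion_type <- c("polyp_like", "cyst_like")[i %% 2 + 1]
    s <- if (i %% 2 == 0) generate_anomalous_volume(pp) else generate_normal_volume(pp)
    v <- s$volume; v$patient_id <- sprintf("T%02d", i); v
  })
  split <- dataset_split(samples[1:30], samples[31:44], samples[45:54])
  enc <- build_unet(unet_config(in_edge = 16L, width = 1 / 16), seed = 2L)$encoder
  cfg <- finetune_config(lr = 2e-3, epochs = 30L, batch_size = 4L,
                         label_fraction = 1, init = "random_init",
                         hidden = 8L, augment = FALSE, seed = 3L)
  ft <- finetune_classifier(enc, split, cfg)
  expect_identical(ft$best_epoch, which.min(ft$val_curve$val_loss))
  ev_val <- evaluate_classifier(ft$classifier, split$validation)
  expect_gte(ev_val$f1, 0.9)
  expect_identical(ft$classifier$provenance, "finetuned")
})

test_that("run_learning_curve accounts cells and resumes from its table", {
  p <- tiny_phantom(seed = 2L)
  samples <- lapply(1:16, function(i) {
    pp <- p; pp$seed <- 700L + i
    s <- if (i %% 2 == 0) generate_anomalous_volume(pp) else generate_normal_volume(pp)
    v <- s$volume; v$patient_id <- sprintf("L%02d", i); v
  })
  folds <- make_cv_folds(samples, k = 4L, seed = 1L)[1:2]
  encoders <- list(random_init = build_unet(unet_config(in_edge = 16L, width = 1 / 32),
                                            seed = 1L)$encoder)
  cfg <- finetune_config(lr = 1e-3, epochs = 2L, batch_size = 4L,
                         init = "random_init", hidden = 4L)
  out_dir <- file.path(tempdir(), "lc_test")
  unlink(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  lc <- run_learning_curve(encoders, folds, fractions = 1, seeds = 1L,
                           config = cfg, out_dir = out_dir)
  first_time <- as.numeric(Sys.time() - t0, units = "secs")
  expect_identical(nrow(lc$results), 2L)  # 1 fraction x 1 init x 2 folds
  expect_s3_class(lc$reports[[1]], "metrics_report")
  t0 <- Sys.time()
  lc2 <- run_learning_curve(encoders, folds, fractions = 1, seeds = 1L,
                            config = cfg, out_dir = out_dir)
  resume_time <- as.numeric(Sys.time() - t0, units = "secs")
  expect_equal(lc2$results, lc$results)   # zero retrained cells
  expect_lt(resume_time, first_time / 2)
  unlink(out_dir, recursive = TRUE)
})

test_that("the CAE-fraction ablation at fraction 1 degenerates to the main chain", {
  p <- tiny_phantom(seed = 5L)
  mk <- function(i, anom) {
    pp <- p; pp$seed <- 800L + i
    s <- if (anom) generate_anomalous_volume(pp) else generate_normal_volume(pp)
    v <- s$volume; v$patient_id <- sprintf("A%02d", i); v
  }
  labelled <- c(lapply(1:10, mk, anom = FALSE), lapply(11:20, mk, anom = TRUE))
  unlab <- lapply(21:28, function(i) { v <- mk(i, i %% 2 == 0); v$label <- NULL; v })
  split <- dataset_split(labelled[c(1:6, 11:16)], labelled[c(7:8, 17:18)],
                         labelled[c(9:10, 19:20)], unlabelled = unlab)
  tab <- run_cae_fraction_ablation(
    cae_fractions = 1.0, split = split, seeds = 1L,
    cae_cfg = tiny_cae_cfg(), cae_epochs = 2L, cae_lr = 1e-3,
    unet_cfg = unet_config(in_edge = 16L, width = 1 / 32),
    pre_cfg = pretrain_config(epochs = 2L, warmup_epochs = 1L, peak_lr = 1e-3,
                              batch_size = 4L, optimizer = "adam_family"),
    ft_cfg = finetune_config(lr = 1e-3, epochs = 2L, batch_size = 4L,
                             label_fraction = 1, init = "ssl_pretrained",
                             hidden = 4L),
    median_kernel = 3L)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$cae_fraction, 1)
  expect_match(tab$cae_checkpoint, "cae_f1_s1")  # provenance completeness
  expect_true(all(c("auroc", "auprc", "f1") %in% names(tab)))
  expect_true(all(tab$auprc >= 0 & tab$auprc <= 1))
})
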