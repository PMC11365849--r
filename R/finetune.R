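# Fine-tuning: discard the decoder, attach an MLP head to the (pretrained or
# random) encoder, train end-to-end on a stratified fraction of the labelled
# training set, select the checkpoint with the lowest validation loss, and
# evaluate AUROC/AUPRC/F1 with fold-aggregated confidence intervals.

#' Fine-tuning configuration
#'
#' Defaults mirror the full-scale recipe (AdamW, constant 1e-4, 100 epochs,
#' batch 16); small-scale runs shrink epochs and raise the rate.
#'
#' @param lr Constant learning rate (AdamW).
#' @param epochs,batch_size Optimization settings.
#' @param label_fraction Fraction of the labelled training set used,
#'   stratified by class.
#' @param init Expected encoder provenance: `"ssl_pretrained"` or
#'   `"random_init"`.
#' @param hidden Hidden width of the MLP head.
#' @param augment Apply flip/translation/noise augmentation to inputs.
#' @param seed Integer seed.
#' @return A `finetune_config`.
#' @export
finetune_config <- function(lr = 1e-4, epochs = 100L, batch_size = 16L,
                            label_fraction = 1, init = c("ssl_pretrained", "random_init"),
                            hidden = 256L, augment = TRUE, seed = 1L) {
  init <- match.arg(init)
  if (lr <= 0) stop("lr must be positive")
  if (label_fraction <= 0 || label_fraction > 1)
    stop("label_fraction must lie in (0, 1]")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 label_fraction = label_fraction, init = init,
                 hidden = as.integer(hidden), augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "finetune_config")
}

onehot2 <- function(labels) {
  y <- as.integer(labels == "anomalous")
  rbind(1 - y, y)
}

#' Fine-tune an encoder as a normal-vs-anomalous classifier
#'
#' Trains encoder + MLP head end-to-end with the two-class cross-entropy
#' (binary cross-entropy of the softmax head) on the stratified
#' `label_fraction` subset of `split$train`, and returns the parameters of
#' the epoch with the lowest validation loss.
#'
#' @param encoder A `model_state` of kind `unet_encoder` whose provenance
#'   matches `config$init`.
#' @param split A `dataset_split` (patient-disjoint).
#' @param config A [finetune_config()].
#' @return List with `classifier` (a `model_state`, provenance `finetuned`),
#'   `val_curve` (per-epoch train/validation loss) and `best_epoch`.
#' @export
finetune_classifier <- function(encoder, split, config = finetune_config()) {
  stopifnot(inherits(split, "dataset_split"))
  if (encoder$provenance != config$init)
    stop("encoder provenance ", encoder$provenance, " does not match config init ",
         config$init)
  train <- if (config$label_fraction < 1)
    stratified_fraction(split$train, config$label_fraction, seed = config$seed)
  else split$train
  labs <- vol_labels(train)
  if (length(unique(labs)) < 2L)
    stop("training subset lost a class; raise label_fraction")
  clf <- build_classifier(encoder, hidden = config$hidden, seed = config$seed)
  rt <- net_runtime(clf, trainable = TRUE)
  opt <- optimizer_new(rt$P, "adamw", lr = config$lr)
  n <- length(train)
  val_x <- stack_volumes(split$validation)
  val_y <- onehot2(vol_labels(split$validation))
  curve <- data.frame(epoch = integer(0), loss = numeric(0), val_loss = numeric(0))
  best <- list(val = Inf, P = NULL, B = NULL, epoch = NA_integer_)
  with_seed(config$seed + 17L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      tot <- 0; nb <- 0L
      for (b in seq(1L, n, by = config$batch_size)) {
        idx <- ord[b:min(b + config$batch_size - 1L, n)]
        xs <- lapply(train[idx], function(v) {
          x <- v$data
          if (config$augment) {
            a <- augment_pair(x, x)   # spatial part only matters for the input
            x <- a$volume
          }
          x
        })
        x <- stack_volumes(xs)
        y <- onehot2(labs[idx])
        ag_zero_grad(rt$P)
        logits <- classifier_forward(clf$config, rt$P, rt$B, x, training = TRUE)
        l <- op_loss_softmax_bce(logits, y)
        ag_backward(l)
        opt_step(opt)
        tot <- tot + l$value; nb <- nb + 1L
      }
      lv <- classifier_forward(clf$config, rt$P, rt$B, val_x, training = FALSE)
      vl <- op_loss_softmax_bce(lv, val_y)$value
      if (vl < best$val) {
        best$val <- vl
        best$P <- lapply(rt$P, ag_value)
        best$B <- lapply(rt$B, function(e) list(running_mean = e$running_mean,
                                                running_var = e$running_var))
        best$epoch <- ep
      }
      curve <- rbind(curve, data.frame(epoch = ep, loss = tot / nb, val_loss = vl))
    }
  })
  clf <- net_collect(clf, rt)
  if (!is.null(best$P)) {
    clf$params <- best$P
    clf$bn <- best$B
  }
  clf$provenance <- "finetuned"
  list(classifier = clf, val_curve = curve, best_epoch = best$epoch)
}

#' Evaluate a classifier on a volume set
#'
#' Scores are softmax probabilities of the anomalous class; the F1 decision
#' is the argmax class.
#'
#' @param classifier A fine-tuned `model_state` of kind `classifier`.
#' @param volumes Labelled `ms_volume`s.
#' @return List with `scores`, `labels`, `auroc`, `auprc`, `f1`.
#' @export
evaluate_classifier <- function(classifier, volumes) {
  volumes <- as_volume_list(volumes)
  scores <- classifier_scores(classifier, volumes)
  y <- as.integer(vol_labels(volumes) == "anomalous")
  list(scores = scores, labels = y,
       auroc = auroc(scores, y),
       auprc = auprc(scores, y),
       f1 = f1_score(scores > 0.5, y))
}

cell_fingerprint <- function(...) {
  paste(vapply(list(...), function(x) paste(deparse(x), collapse = ""), ""),
        collapse = "|")
}

#' Learning-curve experiment over label fractions and encoder inits
#'
#' Full factorial over (fraction, init, fold, seed): fine-tune, evaluate on
#' the fold's test set, and aggregate per (fraction, init) across folds and
#' seeds. When `out_dir` is given, completed cells (identified by a config
#' fingerprint) are reloaded instead of retrained, making reruns resumable.
#'
#' @param encoders Named list of `model_state` encoders, e.g.
#'   `list(ssl_pretrained =, random_init =)`.
#' @param folds List of `dataset_split`s.
#' @param fractions Label fractions to sweep.
#' @param seeds Integer seeds.
#' @param config Base [finetune_config()]; `label_fraction`, `init` and
#'   `seed` are overridden per cell.
#' @param out_dir Optional directory for the resumable results table.
#' @return List with `results` (tidy data.frame: fraction, init, fold, seed,
#'   auroc, auprc, f1) and `reports` (per fraction x init `metrics_report`).
#' @export
run_learning_curve <- function(encoders, folds, fractions = c(0.1),
                               seeds = 1L, config = finetune_config(),
                               out_dir = NULL) {
  stopifnot(!is.null(names(encoders)))
  res_path <- if (!is.null(out_dir)) file.path(out_dir, "learning_curve.csv")
  done <- if (!is.null(res_path) && file.exists(res_path)) {
    d <- read.csv(res_path, stringsAsFactors = FALSE,
                  colClasses = c(fingerprint = "character", fraction = "numeric",
                                 init = "character", fold = "integer",
                                 seed = "integer", auroc = "numeric",
                                 auprc = "numeric", f1 = "numeric"))
    d
  } else
    data.frame(fingerprint = character(0), fraction = numeric(0),
               init = character(0), fold = integer(0), seed = integer(0),
               auroc = numeric(0), auprc = numeric(0), f1 = numeric(0),
               stringsAsFactors = FALSE)
  rows <- done
  for (fr in fractions) for (init in names(encoders)) {
    for (fi in seq_along(folds)) for (sd in seeds) {
      fp <- cell_fingerprint(fr, init, fi, sd, config$lr, config$epochs,
                             config$batch_size, config$hidden)
      if (fp %in% rows$fingerprint) next
      cfg <- config
      cfg$label_fraction <- fr
      cfg$init <- init
      cfg$seed <- as.integer(sd)
      ft <- finetune_classifier(encoders[[init]], folds[[fi]], cfg)
      ev <- evaluate_classifier(ft$classifier, folds[[fi]]$test)
      rows <- rbind(rows, data.frame(fingerprint = fp, fraction = fr,
                                     init = init, fold = fi, seed = sd,
                                     auroc = ev$auroc, auprc = ev$auprc,
                                     f1 = ev$f1, stringsAsFactors = FALSE))
      if (!is.null(res_path)) {
        dir.create(dirname(res_path), recursive = TRUE, showWarnings = FALSE)
        write.csv(rows, res_path, row.names = FALSE)
      }
    }
  }
  reports <- list()
  for (fr in fractions) for (init in names(encoders)) {
    sub <- rows[rows$fraction == fr & rows$init == init, , drop = FALSE]
    if (nrow(sub) >= 2L)
      reports[[paste0("f", fr, "_", init)]] <-
        metrics_report(sub[, c("auroc", "auprc", "f1")],
                       config = list(fraction = fr, init = init))
  }
  list(results = rows[, setdiff(names(rows), "fingerprint")], reports = reports)
}

#' CAE-training-set-size ablation
#'
#' For each fraction of the normal training pool: retrain the CAE on that
#' fraction, regenerate median-filtered residuals on the unlabelled pool,
#' rerun self-supervised pretraining, fine-tune at the downstream label
#' fraction, and evaluate. Each row carries the CAE checkpoint id used.
#'
#' @param cae_fractions Fractions of the normal pool to sweep.
#' @param split A `dataset_split` with a non-empty unlabelled pool.
#' @param seeds Integer seeds (one full chain per seed).
#' @param cae_cfg [cae_config()] for the retrained CAEs.
#' @param cae_epochs,cae_lr CAE training settings.
#' @param unet_cfg [unet_config()] for the pretraining network.
#' @param pre_cfg [pretrain_config()] for the SSL stage.
#' @param ft_cfg [finetune_config()]; its `label_fraction` is the downstream
#'   fraction (default 0.1 in callers).
#' @param median_kernel Residual refinement kernel.
#' @return Tidy data.frame (cae_fraction, seed, cae_checkpoint, auroc, auprc,
#'   f1).
#' @export
run_cae_fraction_ablation <- function(cae_fractions, split, seeds = 1L,
                                      cae_cfg, cae_epochs = 20L, cae_lr = 1e-3,
                                      unet_cfg, pre_cfg, ft_cfg,
                                      median_kernel = 5L) {
  normals <- split$normal_train_subset
  rows <- NULL
  for (fr in cae_fractions) for (sd in seeds) {
    n_take <- max(1L, as.integer(round_half_up(fr * length(normals))))
    sub <- with_seed(sd, normals[sample(length(normals), n_take)])
    cae <- build_cae(cae_cfg, seed = sd)
    cae <- train_cae(cae, sub, epochs = cae_epochs, lr = cae_lr, seed = sd)
    resids <- generate_residual_dataset(cae, split$unlabelled, median_kernel)
    pairs <- Map(function(v, r) list(volume = v, residual = r), split$unlabelled, resids)
    nets <- build_unet(unet_cfg, seed = sd)
    pre_cfg$seed <- as.integer(sd)
    pre <- pretrain_reconstructor(nets$encoder, nets$decoder, pairs, pre_cfg)
    ft_cfg$seed <- as.integer(sd)
    ft_cfg$init <- "ssl_pretrained"
    ft <- finetune_classifier(pre$encoder, split, ft_cfg)
    ev <- evaluate_classifier(ft$classifier, split$test)
    rows <- rbind(rows, data.frame(cae_fraction = fr, seed = sd,
                                   cae_checkpoint = sprintf("cae_f%g_s%d", fr, sd),
                                   auroc = ev$auroc, auprc = ev$auprc, f1 = ev$f1))
  }
  rows
}
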