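# Self-supervised pretraining: the skip-connected encoder-decoder receives
# the MS volume as input and learns to reproduce its residual volume (the
# pseudo segmentation mask), so the encoder learns anomaly-localizing
# features before any labels are seen.

#' Self-supervised pretraining configuration
#'
#' Defaults mirror the full-scale recipe: BCE reconstruction loss, 500 epochs
#' with a 20-epoch linear warmup to a peak learning rate of 0.2 followed by
#' cosine annealing, and a layerwise-adaptive optimizer (suited to large
#' batches). Small-scale runs typically switch to `optimizer =
#' "adam_family"` with a smaller peak rate.
#'
#' @param loss A [loss_spec()]; default BCE.
#' @param epochs,warmup_epochs,peak_lr,batch_size Schedule settings; the
#'   warmup must be shorter than the run.
#' @param optimizer `"layerwise_adaptive"` (LARS-style trust-ratio SGD) or
#'   `"adam_family"` (AdamW).
#' @param augment Apply the joint augmentation policy of [augment_pair()].
#' @param noise_sd Gaussian-noise augmentation strength (input only).
#' @param val_fraction Fraction of pairs held out for the validation loss
#'   used to select the preserved checkpoint.
#' @param seed Integer seed.
#' @return A `pretrain_config`.
#' @export
pretrain_config <- function(loss = loss_spec("BCE"), epochs = 500L,
                            warmup_epochs = 20L, peak_lr = 0.2,
                            batch_size = 8L,
                            optimizer = c("layerwise_adaptive", "adam_family"),
                            augment = TRUE, noise_sd = 0.02,
                            val_fraction = 0.1, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (warmup_epochs >= epochs) stop("warmup_epochs must be smaller than epochs")
  if (peak_lr <= 0) stop("peak_lr must be positive")
  structure(list(loss = loss, epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs), peak_lr = peak_lr,
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 augment = isTRUE(augment), noise_sd = noise_sd,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "pretrain_config")
}

#' Warmup + cosine learning-rate schedule
#'
#' Linear ramp from 0 to `peak_lr` over the warmup epochs, then cosine decay
#' to 0 at the final epoch: `lr(e) = peak * e / warmup` for `e <= warmup`,
#' and `lr(e) = peak * (1 + cos(pi * (e - warmup) / (E - 1 - warmup))) / 2`
#' afterwards (epochs counted from 0). The curve is continuous at the
#' junction, where it attains the peak.
#'
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @param config A [pretrain_config()] (only `epochs`, `warmup_epochs` and
#'   `peak_lr` are used).
#' @return The learning rate.
#' @export
lr_schedule <- function(epoch, config) {
  E <- config$epochs; w <- config$warmup_epochs; peak <- config$peak_lr
  if (any(epoch < 0 | epoch >= E)) stop("epoch out of range [0, epochs)")
  ifelse(epoch <= w,
         peak * epoch / w,
         peak * (1 + cos(pi * (epoch - w) / (E - 1 - w))) / 2)
}

#' Jointly augment an (input, target) volume pair
#'
#' Spatial augmentations (axis flip; small integer translation as the affine
#' component) are applied with identical sampled parameters to both grids so
#' the voxel-wise correspondence between volume and residual target is
#' preserved; Gaussian noise is applied to the input only. Each augmentation
#' fires independently with probability `prob`. Outputs are clipped to
#' `[0, 1]`.
#'
#' @param volume,target 3D arrays of identical shape.
#' @param prob Per-augmentation firing probability.
#' @param max_shift Maximum translation in voxels per axis.
#' @param noise_sd Gaussian noise standard deviation.
#' @return `list(volume =, target =)`.
#' @export
augment_pair <- function(volume, target, prob = 0.5, max_shift = 2L,
                         noise_sd = 0.02) {
  stopifnot(all(dim(volume) == dim(target)))
  if (runif(1) < prob) {                       # flip
    ax <- sample(3L, 1L)
    volume <- flip_array(volume, ax)
    target <- flip_array(target, ax)
  }
  if (runif(1) < prob) {                       # translation (affine component)
    sh <- sample(seq(-max_shift, max_shift), 3L, replace = TRUE)
    volume <- shift_array(volume, sh)
    target <- shift_array(target, sh)
  }
  if (runif(1) < prob && noise_sd > 0) {       # noise: input only
    volume <- volume + array(rnorm(length(volume), 0, noise_sd), dim(volume))
  }
  list(volume = clip01(volume), target = clip01(target))
}

flip_array <- function(a, axis) {
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- rev(seq_len(dim(a)[axis]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Integer translation with replicated borders.
shift_array <- function(a, shift) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) pmin(pmax(seq_len(d[ax]) - shift[ax], 1L), d[ax]))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Self-supervised pretraining of the encoder-decoder on residual targets
#'
#' The network input is the MS volume; the regression target is its residual
#' volume. The per-voxel loss (BCE by default, on continuous targets in
#' `[0, 1]`) is averaged over voxels and batch. A fraction of the pairs is
#' held out; the parameters with the lowest validation loss are preserved.
#'
#' @param encoder,decoder `model_state`s from [build_unet()].
#' @param pairs List of `list(volume =, residual =)` pairs aligned by volume
#'   id (`ms_volume` + `residual_volume`).
#' @param config A [pretrain_config()].
#' @return List with the trained `encoder` (provenance `ssl_pretrained`),
#'   `decoder`, and the per-epoch `log` (epoch, lr, loss, val_loss).
#' @export
pretrain_reconstructor <- function(encoder, decoder, pairs, config = pretrain_config()) {
  stopifnot(encoder$kind == "unet_encoder", decoder$kind == "unet_decoder")
  for (p in pairs) {
    vid <- p$volume$patient_id %||% NA_character_
    rid <- p$residual$source_volume_id %||% NA_character_
    if (!is.na(vid) && !is.na(rid) && vid != rid)
      stop("misaligned pair: volume ", vid, " vs residual ", rid)
    if (config$loss$kind == "BCE" &&
        (min(p$residual$data) < 0 || max(p$residual$data) > 1))
      stop("BCE target outside [0,1]")
  }
  loss_fn <- loss_spec_fn(config$loss$kind)
  rt_e <- net_runtime(encoder, trainable = TRUE)
  rt_d <- net_runtime(decoder, trainable = TRUE)
  all_p <- c(rt_e$P, rt_d$P)
  method <- if (config$optimizer == "layerwise_adaptive") "lars" else "adamw"
  opt <- optimizer_new(all_p, method, lr = config$peak_lr)
  n <- length(pairs)
  n_val <- max(0L, min(n - 1L, round(config$val_fraction * n)))
  log <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                    val_loss = numeric(0))
  best <- list(val = Inf, P = NULL, Bn = NULL)
  with_seed(config$seed, {
    val_idx <- if (n_val > 0L) sample(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    for (ep in seq_len(config$epochs)) {
      lr <- lr_schedule(ep - 1L, config)
      ord <- sample(tr_idx)
      tot <- 0; nb <- 0L
      for (b in seq(1L, length(ord), by = config$batch_size)) {
        idx <- ord[b:min(b + config$batch_size - 1L, length(ord))]
        xs <- vector("list", length(idx)); ts <- vector("list", length(idx))
        for (j in seq_along(idx)) {
          pv <- pairs[[idx[j]]]
          if (config$augment) {
            a <- augment_pair(pv$volume$data, pv$residual$data,
                              noise_sd = config$noise_sd)
            xs[[j]] <- a$volume; ts[[j]] <- a$target
          } else {
            xs[[j]] <- pv$volume$data; ts[[j]] <- pv$residual$data
          }
        }
        x <- stack_volumes(xs)
        tgt <- stack_volumes(ts)
        ag_zero_grad(all_p)
        enc <- unet_encoder_forward(encoder$config, rt_e$P, rt_e$B, x, training = TRUE)
        out <- unet_decoder_forward(decoder$config, rt_d$P, rt_d$B,
                                    enc$bottleneck, enc$skips, training = TRUE)
        l <- loss_fn(out, tgt)
        ag_backward(l)
        opt_step(opt, lr = lr)
        tot <- tot + l$value; nb <- nb + 1L
      }
      vl <- NA_real_
      if (n_val > 0L) {
        xv <- stack_volumes(lapply(pairs[val_idx], function(p) p$volume$data))
        tv <- stack_volumes(lapply(pairs[val_idx], function(p) p$residual$data))
        encv <- unet_encoder_forward(encoder$config, rt_e$P, rt_e$B, xv, training = FALSE)
        outv <- unet_decoder_forward(decoder$config, rt_d$P, rt_d$B,
                                     encv$bottleneck, encv$skips, training = FALSE)
        vl <- loss_fn(outv, tv)$value
        if (vl < best$val) {
          best$val <- vl
          best$P <- lapply(all_p, ag_value)
          best$Be <- lapply(rt_e$B, function(e) list(running_mean = e$running_mean,
                                                     running_var = e$running_var))
          best$Bd <- lapply(rt_d$B, function(e) list(running_mean = e$running_mean,
                                                     running_var = e$running_var))
        }
      }
      log <- rbind(log, data.frame(epoch = ep, lr = lr, loss = tot / max(nb, 1L),
                                   val_loss = vl))
    }
  })
  encoder <- net_collect(encoder, rt_e)
  decoder <- net_collect(decoder, rt_d)
  if (!is.null(best$P)) {
    ne <- length(rt_e$P)
    encoder$params <- best$P[seq_len(ne)]
    decoder$params <- best$P[ne + seq_along(rt_d$P)]
    encoder$bn <- best$Be
    decoder$bn <- best$Bd
  }
  encoder$provenance <- "ssl_pretrained"
  list(encoder = encoder, decoder = decoder, log = log)
}
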