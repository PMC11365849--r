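# Unsupervised anomaly detection stage: train the CAE on normal volumes only,
# then turn its reconstruction residuals on the unlabelled pool into the
# pseudo segmentation masks that drive self-supervision.

#' Loss specification for reconstruction objectives
#'
#' @param kind `"L1"` (mean absolute error), `"L2"` (mean squared error) or
#'   `"BCE"` (per-voxel binary cross-entropy; targets must lie in `[0, 1]`).
#' @return A `loss_spec`.
#' @export
loss_spec <- function(kind = c("L1", "L2", "BCE")) {
  kind <- match.arg(toupper(kind), c("L1", "L2", "BCE"))
  structure(list(kind = kind), class = "loss_spec")
}

#' Train the convolutional autoencoder on normal MS volumes
#'
#' Minimizes the mean per-voxel reconstruction loss (L1 by default) between
#' each normal volume `x` and its reconstruction `A(x)`. No augmentation is
#' applied. Training is deterministic given `seed`.
#'
#' @param model A `model_state` of kind `cae` with provenance `random_init`.
#' @param normal_set List of `ms_volume`s, all labelled normal.
#' @param loss A [loss_spec()]; default L1.
#' @param epochs,batch_size,lr Optimization settings (Adam).
#' @param seed Integer seed governing batching.
#' @param validation Optional list of volumes for a per-epoch validation loss.
#' @return The trained `model_state` (provenance `cae_trained`) with a
#'   per-epoch training curve in `$log`.
#' @export
train_cae <- function(model, normal_set, loss = loss_spec("L1"), epochs = 20L,
                      batch_size = 8L, lr = 1e-3, seed = 1L, validation = NULL) {
  stopifnot(inherits(model, "model_state"), model$kind == "cae")
  if (model$provenance != "random_init")
    stop("CAE training expects a random_init model, got ", model$provenance)
  normal_set <- as_volume_list(normal_set)
  if (length(normal_set) == 0L) stop("normal_set is empty")
  labs <- vol_labels(normal_set)
  if (any(!is.na(labs) & labs != "normal"))
    stop("normal_set contains anomalous volumes; the UAD contract requires normal-only training")
  loss_fn <- loss_spec_fn(loss$kind)
  log <- data.frame(epoch = integer(0), loss = numeric(0), val_loss = numeric(0))
  if (epochs > 0L) {
    rt <- net_runtime(model, trainable = TRUE)
    opt <- optimizer_new(rt$P, "adamw", lr = lr)
    n <- length(normal_set)
    with_seed(seed, {
      for (ep in seq_len(epochs)) {
        ord <- sample(n)
        tot <- 0
        nb <- 0L
        for (b in seq(1L, n, by = batch_size)) {
          idx <- ord[b:min(b + batch_size - 1L, n)]
          x <- stack_volumes(normal_set[idx])
          ag_zero_grad(rt$P)
          out <- cae_forward(model$config, rt$P, rt$B, x, training = TRUE)
          l <- loss_fn(out, x)
          ag_backward(l)
          opt_step(opt)
          tot <- tot + l$value
          nb <- nb + 1L
        }
        vl <- NA_real_
        if (!is.null(validation)) {
          xv <- stack_volumes(as_volume_list(validation))
          outv <- cae_forward(model$config, rt$P, rt$B, xv, training = FALSE)
          vl <- loss_fn(outv, xv)$value
        }
        log <- rbind(log, data.frame(epoch = ep, loss = tot / nb, val_loss = vl))
      }
    })
    model <- net_collect(model, rt)
  }
  model$provenance <- "cae_trained"
  model$log <- log
  model
}

#' Residual volume |x - A(x)|
#'
#' The voxel-wise absolute reconstruction error. With inputs and sigmoid
#' outputs in `[0, 1]` the residual lies in `[0, 1]`; no thresholding is
#' applied.
#'
#' @param model A `model_state` of kind `cae`, provenance `cae_trained`.
#' @param volume An `ms_volume` or 3D array.
#' @return A `residual_volume`: list with `data` (3D array),
#'   `source_volume_id`, `cae_checkpoint_id` and a `postprocessing` record.
#' @export
compute_residual <- function(model, volume) {
  if (model$provenance != "cae_trained")
    stop("residuals require a cae_trained model, got ", model$provenance)
  x <- as_batch(volume)
  rec <- cae_reconstruct(model, x)
  if (!all(dim(rec) == dim(x))) stop("reconstruction shape mismatch")
  r <- abs(x - rec)
  dim(r) <- dim(x)[1:3]
  structure(list(data = r,
                 source_volume_id = if (inherits(volume, "ms_volume")) volume$patient_id else NA_character_,
                 cae_checkpoint_id = model$seed,
                 postprocessing = list(median_kernel = NULL)),
            class = "residual_volume")
}

#' 3D median filter
#'
#' Each voxel is replaced by the median of its `kernel^3` neighborhood;
#' borders use reflect padding. `kernel = 1` is the identity.
#'
#' @param volume 3D array (or `residual_volume`).
#' @param kernel Odd positive kernel edge; the residual-refinement default
#'   used in the ablation pipeline is 5.
#' @return Filtered object of the same type.
#' @export
median_filter3d <- function(volume, kernel = 5L) {
  if (kernel %% 2L == 0L || kernel < 1L) stop("kernel must be odd and >= 1")
  if (inherits(volume, "residual_volume")) {
    volume$data <- cpp_median_filter3d(volume$data, as.integer(kernel))
    volume$postprocessing$median_kernel <- as.integer(kernel)
    return(volume)
  }
  cpp_median_filter3d(volume, as.integer(kernel))
}

#' Scalar anomaly score of a residual volume
#'
#' The mean voxel value of the residual: non-negative, and zero iff the
#' residual is identically zero. Larger scores indicate poorer reconstruction
#' and hence likelier anomaly.
#'
#' @param residual A `residual_volume` or 3D array.
#' @return A scalar.
#' @export
anomaly_score <- function(residual) {
  d <- if (inherits(residual, "residual_volume")) residual$data else residual
  mean(d)
}

#' Residual volumes for an unlabelled pool
#'
#' Applies [compute_residual()] and, optionally, [median_filter3d()] to every
#' volume. Deterministic; output order and ids map 1:1 to the input.
#'
#' @param model A `cae_trained` model.
#' @param unlabelled List of `ms_volume`s.
#' @param median_kernel Odd kernel for residual refinement, or `NULL` to skip.
#' @return List of `residual_volume`s.
#' @export
generate_residual_dataset <- function(model, unlabelled, median_kernel = NULL) {
  lapply(seq_along(unlabelled), function(i) {
    r <- tryCatch(compute_residual(model, unlabelled[[i]]), error = function(e)
      stop("volume ", unlabelled[[i]]$patient_id %||% i, ": ", conditionMessage(e)))
    if (!is.null(median_kernel) && median_kernel > 1L)
      r <- median_filter3d(r, median_kernel)
    r
  })
}

#' Dice overlap of a thresholded residual with a lesion mask
#'
#' Thresholds the residual at its `prob` quantile and computes the Dice
#' coefficient with the ground-truth lesion mask.
#'
#' @param residual A `residual_volume` or 3D array.
#' @param mask Binary 3D array.
#' @param prob Quantile used as threshold (default 0.95).
#' @return Dice coefficient in `[0, 1]`.
#' @export
residual_dice <- function(residual, mask, prob = 0.95) {
  d <- if (inherits(residual, "residual_volume")) residual$data else residual
  thr <- quantile(d, prob)
  pred <- d > thr
  denom <- sum(pred) + sum(mask > 0)
  if (denom == 0) return(0)
  2 * sum(pred & mask > 0) / denom
}
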