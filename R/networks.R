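# Network builders: the convolutional autoencoder A(.), the skip-connected
# encoder-decoder (E, D) with a 3D ResNet18 encoder, and the classifier head.
# Models are plain `model_state` objects: named parameter arrays plus batch
# norm running statistics, so they serialize to a single checkpoint file.

#' Convolutional autoencoder configuration
#'
#' @param in_edge Edge length of the input cube in voxels; must be divisible
#'   by `2^length(stage_channels)`.
#' @param stage_channels Channel widths of the encoder stages (each stage is a
#'   stride-2 3x3x3 convolution + batch norm + leaky ReLU); the decoder
#'   mirrors them in reverse with trilinear upsampling.
#' @param latent_dim Dimension of the fully-connected latent bottleneck.
#' @param output_activation `"sigmoid"` (outputs in (0,1)) or `"identity"`.
#' @return A `cae_config` list.
#' @export
cae_config <- function(in_edge = 64L, stage_channels = c(16L, 32L, 64L, 128L),
                       latent_dim = 512L, output_activation = c("sigmoid", "identity")) {
  output_activation <- match.arg(output_activation)
  S <- length(stage_channels)
  if (latent_dim <= 0) stop("latent_dim must be positive")
  if (in_edge %% (2^S) != 0)
    stop("in_edge must be divisible by 2^", S, " (total downsampling)")
  structure(list(in_edge = as.integer(in_edge),
                 stage_channels = as.integer(stage_channels),
                 latent_dim = as.integer(latent_dim),
                 output_activation = output_activation),
            class = "cae_config")
}

#' U-Net configuration (3D ResNet18 encoder, mirrored decoder)
#'
#' @param in_edge Input cube edge in voxels.
#' @param stage_channels Channel widths of the four residual stages; the
#'   reference design is `c(64, 128, 256, 512)`, scalable by a width factor
#'   for small-scale runs.
#' @param width Multiplier applied to `stage_channels` (e.g. `1/8`).
#' @param skip_connections Pass encoder feature maps to the decoder.
#' @return A `unet_config` list.
#' @export
unet_config <- function(in_edge = 64L, stage_channels = c(64L, 128L, 256L, 512L),
                        width = 1, skip_connections = TRUE) {
  ch <- as.integer(pmax(2L, round(stage_channels * width)))
  if (length(ch) != 4L) stop("exactly four encoder stages are supported")
  if (in_edge %% 16L != 0L) stop("in_edge must be divisible by 16")
  structure(list(in_edge = as.integer(in_edge), stage_channels = ch,
                 skip_connections = isTRUE(skip_connections)),
            class = "unet_config")
}

init_conv <- function(k, cin, cout) {
  sd <- sqrt(2 / (k^3 * cin))
  array(rnorm(k^3 * cin * cout, 0, sd), dim = c(k, k, k, cin, cout))
}
init_linear <- function(nout, nin) {
  matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

new_model_state <- function(kind, config, params, bn, provenance, seed) {
  structure(list(format = "msanomaly-checkpoint-1",
                 kind = kind, config = config, params = params, bn = bn,
                 provenance = provenance, seed = as.integer(seed)),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("<model_state> kind=%s provenance=%s params=%d tensors (%s values)\n",
              x$kind, x$provenance, length(x$params),
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameter values in a model
#' @param model A `model_state`.
#' @return Integer count.
#' @export
n_params <- function(model) sum(vapply(model$params, length, 0L))

bn_init <- function(C) list(running_mean = numeric(C), running_var = rep(1, C))

# Convert stored parameter arrays into autodiff nodes and batch norm records
# into mutable environments for a training/inference pass.
net_runtime <- function(model, trainable = TRUE) {
  P <- if (trainable) lapply(model$params, ag_param) else lapply(model$params, ag_node)
  B <- lapply(model$bn, function(s) {
    e <- new.env(parent = emptyenv())
    e$running_mean <- s$running_mean
    e$running_var <- s$running_var
    e
  })
  list(P = P, B = B, config = model$config, kind = model$kind)
}

net_collect <- function(model, rt) {
  model$params <- lapply(rt$P, ag_value)
  model$bn <- lapply(rt$B, function(e)
    list(running_mean = e$running_mean, running_var = e$running_var))
  model
}

# ---------------------------------------------------------------------------
# CAE
# ---------------------------------------------------------------------------

#' Build a 3D convolutional autoencoder
#'
#' Encoder stages are 3x3x3 stride-2 convolutions with batch normalization and
#' leaky ReLU; a fully connected latent bottleneck sits between encoder and
#' decoder; decoder stages are trilinear upsampling followed by a 3x3x3
#' convolution, batch norm and leaky ReLU, with a sigmoid output layer.
#'
#' @param config A [cae_config()].
#' @param seed Integer seed for the parameter initialisation; the same seed
#'   yields bit-identical parameters.
#' @return A `model_state` with provenance `random_init`.
#' @export
build_cae <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cae_config"))
  with_seed(seed, {
    ch <- config$stage_channels
    S <- length(ch)
    edge_b <- config$in_edge / 2^S
    flat <- as.integer(edge_b^3 * ch[S])
    P <- list()
    B <- list()
    cin <- 1L
    for (i in seq_len(S)) {
      P[[paste0("enc", i, "_w")]] <- init_conv(3, cin, ch[i])
      P[[paste0("enc", i, "_b")]] <- numeric(ch[i])
      P[[paste0("enc", i, "_g")]] <- rep(1, ch[i])
      P[[paste0("enc", i, "_be")]] <- numeric(ch[i])
      B[[paste0("enc", i, "_bn")]] <- bn_init(ch[i])
      cin <- ch[i]
    }
    P$fc_enc_w <- init_linear(config$latent_dim, flat)
    P$fc_enc_b <- numeric(config$latent_dim)
    P$fc_dec_w <- init_linear(flat, config$latent_dim)
    P$fc_dec_b <- numeric(flat)
    for (i in seq_len(S)) {
      cin_d <- ch[S - i + 1L]
      cout_d <- if (i == S) ch[1L] else ch[S - i]
      P[[paste0("dec", i, "_w")]] <- init_conv(3, cin_d, cout_d)
      P[[paste0("dec", i, "_b")]] <- numeric(cout_d)
      P[[paste0("dec", i, "_g")]] <- rep(1, cout_d)
      P[[paste0("dec", i, "_be")]] <- numeric(cout_d)
      B[[paste0("dec", i, "_bn")]] <- bn_init(cout_d)
    }
    P$out_w <- init_conv(3, ch[1L], 1L)
    P$out_b <- numeric(1L)
    new_model_state("cae", config, P, B, "random_init", seed)
  })
}

cae_forward <- function(config, P, B, x, training = FALSE) {
  ch <- config$stage_channels
  S <- length(ch)
  h <- ag_wrap(x)
  for (i in seq_len(S)) {
    h <- op_conv3d(h, P[[paste0("enc", i, "_w")]], P[[paste0("enc", i, "_b")]],
                   stride = 2L, pad = 1L)
    h <- op_batchnorm(h, P[[paste0("enc", i, "_g")]], P[[paste0("enc", i, "_be")]],
                      B[[paste0("enc", i, "_bn")]], training = training)
    h <- op_leaky_relu(h)
  }
  db <- dim(ag_value(h))
  z <- op_linear(op_flatten(h), P$fc_enc_w, P$fc_enc_b)
  h <- op_linear(z, P$fc_dec_w, P$fc_dec_b)
  h <- op_leaky_relu(h)
  h <- op_reshape(h, db)
  for (i in seq_len(S)) {
    h <- op_upsample(h, 2L)
    h <- op_conv3d(h, P[[paste0("dec", i, "_w")]], P[[paste0("dec", i, "_b")]],
                   stride = 1L, pad = 1L)
    h <- op_batchnorm(h, P[[paste0("dec", i, "_g")]], P[[paste0("dec", i, "_be")]],
                      B[[paste0("dec", i, "_bn")]], training = training)
    h <- op_leaky_relu(h)
  }
  h <- op_conv3d(h, P$out_w, P$out_b, stride = 1L, pad = 1L)
  if (config$output_activation == "sigmoid") h <- op_sigmoid(h)
  h
}

# ---------------------------------------------------------------------------
# 3D ResNet18 encoder + mirrored decoder
# ---------------------------------------------------------------------------

resnet_block_params <- function(P, B, name, cin, cout, stride) {
  P[[paste0(name, "_c1_w")]] <- init_conv(3, cin, cout)
  P[[paste0(name, "_c1_b")]] <- numeric(cout)
  P[[paste0(name, "_g1")]] <- rep(1, cout)
  P[[paste0(name, "_be1")]] <- numeric(cout)
  B[[paste0(name, "_bn1")]] <- bn_init(cout)
  P[[paste0(name, "_c2_w")]] <- init_conv(3, cout, cout)
  P[[paste0(name, "_c2_b")]] <- numeric(cout)
  P[[paste0(name, "_g2")]] <- rep(1, cout)
  P[[paste0(name, "_be2")]] <- numeric(cout)
  B[[paste0(name, "_bn2")]] <- bn_init(cout)
  if (stride != 1L || cin != cout) {
    P[[paste0(name, "_dw")]] <- init_conv(1, cin, cout)
    P[[paste0(name, "_db")]] <- numeric(cout)
    P[[paste0(name, "_dg")]] <- rep(1, cout)
    P[[paste0(name, "_dbe")]] <- numeric(cout)
    B[[paste0(name, "_dbn")]] <- bn_init(cout)
  }
  list(P = P, B = B)
}

resnet_block_forward <- function(P, B, name, h, stride, training) {
  shortcut <- h
  out <- op_conv3d(h, P[[paste0(name, "_c1_w")]], P[[paste0(name, "_c1_b")]],
                   stride = stride, pad = 1L)
  out <- op_batchnorm(out, P[[paste0(name, "_g1")]], P[[paste0(name, "_be1")]],
                      B[[paste0(name, "_bn1")]], training = training)
  out <- op_relu(out)
  out <- op_conv3d(out, P[[paste0(name, "_c2_w")]], P[[paste0(name, "_c2_b")]],
                   stride = 1L, pad = 1L)
  out <- op_batchnorm(out, P[[paste0(name, "_g2")]], P[[paste0(name, "_be2")]],
                      B[[paste0(name, "_bn2")]], training = training)
  if (!is.null(P[[paste0(name, "_dw")]])) {
    shortcut <- op_conv3d(shortcut, P[[paste0(name, "_dw")]], P[[paste0(name, "_db")]],
                          stride = stride, pad = 0L)
    shortcut <- op_batchnorm(shortcut, P[[paste0(name, "_dg")]], P[[paste0(name, "_dbe")]],
                             B[[paste0(name, "_dbn")]], training = training)
  }
  op_relu(op_add(out, shortcut))
}

#' Build the U-Net: a 3D ResNet18 encoder and a mirrored decoder
#'
#' The encoder follows the basic-block ResNet18 recipe (four stages of two
#' residual blocks, stage strides 1/2/2/2) with a 3x3x3 stride-2 stem in place
#' of the large-image stem, giving a total downsampling factor of 16. The
#' decoder mirrors the encoder channels in reverse with trilinear upsampling;
#' skip connections pass the stem and first three stage outputs to the
#' decoder. The decoder output is a 1-channel cube of input shape through a
#' sigmoid.
#'
#' @param config A [unet_config()].
#' @param seed Integer initialisation seed.
#' @return A list with elements `encoder` and `decoder`, both `model_state`.
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  with_seed(seed, {
    ch <- config$stage_channels
    P <- list(); B <- list()
    P$stem_w <- init_conv(3, 1L, ch[1])
    P$stem_b <- numeric(ch[1])
    P$stem_g <- rep(1, ch[1])
    P$stem_be <- numeric(ch[1])
    B$stem_bn <- bn_init(ch[1])
    strides <- c(1L, 2L, 2L, 2L)
    cin <- ch[1]
    for (s in 1:4) {
      for (b in 1:2) {
        nm <- sprintf("st%db%d", s, b)
        pb <- resnet_block_params(P, B, nm, if (b == 1L) cin else ch[s], ch[s],
                                  if (b == 1L) strides[s] else 1L)
        P <- pb$P; B <- pb$B
      }
      cin <- ch[s]
    }
    enc <- new_model_state("unet_encoder", config, P, B, "random_init", seed)

    dch_in <- c(ch[4], ch[3], ch[2], ch[1])
    dch_out <- c(ch[3], ch[2], ch[1], ch[1])
    skip_ch <- c(ch[3], ch[2], ch[1], ch[1])  # stage3, stage2, stage1, stem
    Pd <- list(); Bd <- list()
    for (i in 1:4) {
      cin_d <- dch_in[i] + if (config$skip_connections) skip_ch[i] else 0L
      Pd[[paste0("dec", i, "_w")]] <- init_conv(3, cin_d, dch_out[i])
      Pd[[paste0("dec", i, "_b")]] <- numeric(dch_out[i])
      Pd[[paste0("dec", i, "_g")]] <- rep(1, dch_out[i])
      Pd[[paste0("dec", i, "_be")]] <- numeric(dch_out[i])
      Bd[[paste0("dec", i, "_bn")]] <- bn_init(dch_out[i])
    }
    Pd$out_w <- init_conv(3, ch[1], 1L)
    Pd$out_b <- numeric(1L)
    dec <- new_model_state("unet_decoder", config, Pd, Bd, "random_init", seed)
    list(encoder = enc, decoder = dec)
  })
}

# Encoder forward: returns bottleneck map, the four skip maps and the pooled
# feature vector.
unet_encoder_forward <- function(config, P, B, x, training = FALSE) {
  h <- op_conv3d(ag_wrap(x), P$stem_w, P$stem_b, stride = 2L, pad = 1L)
  h <- op_batchnorm(h, P$stem_g, P$stem_be, B$stem_bn, training = training)
  stem <- op_relu(h)
  strides <- c(1L, 2L, 2L, 2L)
  h <- stem
  stage_out <- vector("list", 4L)
  for (s in 1:4) {
    for (b in 1:2) {
      nm <- sprintf("st%db%d", s, b)
      h <- resnet_block_forward(P, B, nm, h, if (b == 1L) strides[s] else 1L, training)
    }
    stage_out[[s]] <- h
  }
  list(bottleneck = h,
       skips = list(stage_out[[3]], stage_out[[2]], stage_out[[1]], stem),
       pooled = op_global_pool(h))
}

unet_decoder_forward <- function(config, P, B, bottleneck, skips, training = FALSE) {
  h <- bottleneck
  for (i in 1:4) {
    if (i < 4L) h <- op_upsample(h, 2L)  # stage 4 runs at the stem resolution
    if (config$skip_connections) h <- op_concat_c(h, skips[[i]])
    h <- op_conv3d(h, P[[paste0("dec", i, "_w")]], P[[paste0("dec", i, "_b")]],
                   stride = 1L, pad = 1L)
    h <- op_batchnorm(h, P[[paste0("dec", i, "_g")]], P[[paste0("dec", i, "_be")]],
                      B[[paste0("dec", i, "_bn")]], training = training)
    h <- op_leaky_relu(h)
  }
  h <- op_upsample(h, 2L)
  h <- op_conv3d(h, P$out_w, P$out_b, stride = 1L, pad = 1L)
  op_sigmoid(h)
}

# ---------------------------------------------------------------------------
# Classifier = encoder + global average pooling + MLP head
# ---------------------------------------------------------------------------

#' Attach a classification head to an encoder
#'
#' The encoder's bottleneck feature map is globally average-pooled and passed
#' through an MLP (feature dim -> `hidden` -> `n_classes`).
#'
#' @param encoder A `model_state` of kind `unet_encoder` with provenance
#'   `random_init` or `ssl_pretrained`.
#' @param hidden Hidden width of the MLP head.
#' @param n_classes Number of output classes.
#' @param seed Seed for the head initialisation.
#' @return A `model_state` of kind `classifier`; its provenance mirrors the
#'   encoder's until fine-tuning.
#' @export
build_classifier <- function(encoder, hidden = 256L, n_classes = 2L, seed = 1L) {
  stopifnot(inherits(encoder, "model_state"), encoder$kind == "unet_encoder")
  if (!encoder$provenance %in% c("random_init", "ssl_pretrained"))
    stop("encoder provenance must be random_init or ssl_pretrained, got ",
         encoder$provenance)
  with_seed(seed, {
    feat <- encoder$config$stage_channels[4]
    P <- setNames(encoder$params, paste0("enc__", names(encoder$params)))
    B <- setNames(encoder$bn, paste0("enc__", names(encoder$bn)))
    P$head1_w <- init_linear(hidden, feat)
    P$head1_b <- numeric(hidden)
    P$head2_w <- init_linear(n_classes, hidden)
    P$head2_b <- numeric(n_classes)
    cfg <- list(encoder = encoder$config, hidden = as.integer(hidden),
                n_classes = as.integer(n_classes),
                encoder_provenance = encoder$provenance)
    new_model_state("classifier", cfg, P, B, encoder$provenance, seed)
  })
}

classifier_forward <- function(config, P, B, x, training = FALSE) {
  encP <- P[startsWith(names(P), "enc__")]
  names(encP) <- sub("^enc__", "", names(encP))
  encB <- B[startsWith(names(B), "enc__")]
  names(encB) <- sub("^enc__", "", names(encB))
  enc <- unet_encoder_forward(config$encoder, encP, encB, x, training = training)
  h <- op_linear(enc$pooled, P$head1_w, P$head1_b)
  h <- op_relu(h)
  op_linear(h, P$head2_w, P$head2_b)
}

#' Classifier scores for a set of volumes
#'
#' @param model A `model_state` of kind `classifier`.
#' @param volumes List of `ms_volume` objects (or 3D arrays).
#' @return Numeric vector of anomaly probabilities (softmax of the anomalous
#'   logit), one per volume.
#' @export
classifier_scores <- function(model, volumes) {
  stopifnot(model$kind == "classifier")
  x <- stack_volumes(volumes)
  rt <- net_runtime(model, trainable = FALSE)
  logits <- ag_value(classifier_forward(model$config, rt$P, rt$B, x, training = FALSE))
  p <- softmax_cols(logits)
  p[2L, ]
}

#' Reconstruct volumes with a CAE
#'
#' @param model A `model_state` of kind `cae`.
#' @param x A `(D,H,W,1,N)` array, a 3D array, or an `ms_volume`.
#' @return A `(D,H,W,1,N)` array of reconstructions.
#' @export
cae_reconstruct <- function(model, x) {
  stopifnot(model$kind == "cae")
  x <- as_batch(x)
  rt <- net_runtime(model, trainable = FALSE)
  ag_value(cae_forward(model$config, rt$P, rt$B, x, training = FALSE))
}

as_batch <- function(x) {
  if (inherits(x, "ms_volume")) x <- x$data
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L, 1L)
  x
}

stack_volumes <- function(volumes) {
  if (is.array(volumes)) return(as_batch(volumes))
  arrs <- lapply(volumes, function(v) if (inherits(v, "ms_volume")) v$data else v)
  d <- dim(arrs[[1L]])
  out <- array(0, c(d, 1L, length(arrs)))
  for (i in seq_along(arrs)) out[, , , 1L, i] <- arrs[[i]]
  out
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single RDS files embedding the architecture config,
#' parameters, batch norm statistics, provenance and seed (format tag
#' `msanomaly-checkpoint-1`).
#'
#' @param model A `model_state`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `model_state`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "model_state"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "model_state") || !identical(m$format, "msanomaly-checkpoint-1"))
    stop("not a recognised msanomaly checkpoint: ", path)
  m
}
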