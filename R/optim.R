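# Optimizers operating on named lists of ag_param nodes.
#
# adamw: decoupled weight decay Adam (used for fine-tuning).
# lars:  layerwise adaptive rate scaling on SGD-momentum -- the trust ratio
#        ||w|| / (||g|| + wd*||w||) rescales the update per parameter tensor;
#        1-d tensors (biases, batch-norm scales) are excluded from both the
#        trust ratio and weight decay, as is conventional.

optimizer_new <- function(params, method = c("adamw", "adam", "lars", "sgd"),
                          lr = 1e-3, weight_decay = 0, momentum = 0.9,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  method <- match.arg(method)
  o <- new.env(parent = emptyenv())
  o$method <- method
  o$lr <- lr
  o$weight_decay <- weight_decay
  o$momentum <- momentum
  o$beta1 <- beta1; o$beta2 <- beta2; o$eps <- eps
  o$t <- 0L
  o$m <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  o$v <- lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value)))
  o$params <- params
  o
}

opt_step <- function(o, lr = NULL) {
  lr <- lr %||% o$lr
  o$t <- o$t + 1L
  for (i in seq_along(o$params)) {
    p <- o$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    g <- as.numeric(g)
    w <- p$value
    matrixlike <- !is.null(dim(w)) && length(dim(w)) > 1L
    if (o$method %in% c("adamw", "adam")) {
      o$m[[i]] <- o$beta1 * o$m[[i]] + (1 - o$beta1) * g
      o$v[[i]] <- o$beta2 * o$v[[i]] + (1 - o$beta2) * g^2
      mh <- as.numeric(o$m[[i]]) / (1 - o$beta1^o$t)
      vh <- as.numeric(o$v[[i]]) / (1 - o$beta2^o$t)
      upd <- mh / (sqrt(vh) + o$eps)
      if (o$method == "adamw" && matrixlike && o$weight_decay > 0)
        upd <- upd + o$weight_decay * as.numeric(w)
    } else if (o$method == "lars") {
      wd <- if (matrixlike) o$weight_decay else 0
      gd <- g + wd * as.numeric(w)
      trust <- 1
      if (matrixlike) {
        wn <- sqrt(sum(w^2)); gn <- sqrt(sum(gd^2))
        if (wn > 0 && gn > 0) trust <- wn / (gn + 1e-9)
      }
      o$m[[i]] <- o$momentum * as.numeric(o$m[[i]]) + gd
      upd <- trust * as.numeric(o$m[[i]])
    } else { # sgd with momentum
      o$m[[i]] <- o$momentum * as.numeric(o$m[[i]]) + g
      upd <- as.numeric(o$m[[i]])
    }
    nv <- as.numeric(w) - lr * upd
    if (!is.null(dim(w))) dim(nv) <- dim(w)
    p$value <- nv
  }
  invisible(o)
}
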