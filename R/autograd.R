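#' @useDynLib msanomaly, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom qt median quantile sd setNames
#' @importFrom utils read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode autodiff. Each node is an environment holding a value
# (an R array), an optional backward closure, and its parent nodes. The tape
# is implicit: calling an op on nodes builds the graph; ag_backward() walks it
# in reverse topological order and accumulates gradients.
# ---------------------------------------------------------------------------

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  .ag$counter <- .ag$counter + 1L
  e$id <- .ag$counter
  class(e) <- "ag_node"
  e
}

ag_param <- function(value) {
  n <- ag_node(value)
  n$is_param <- TRUE
  n
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x
ag_wrap <- function(x) if (inherits(x, "ag_node")) x else ag_node(x)

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

ag_backward <- function(root, grad = NULL) {
  topo <- vector("list", 256L)
  ntopo <- 0L
  seen <- new.env(parent = emptyenv())
  # iterative post-order DFS (avoids deep recursion on long graphs)
  stack <- list(list(node = root, i = 0L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    node <- top$node
    key <- as.character(node$id)
    if (top$i == 0L && !is.null(seen[[key]])) {
      stack[[length(stack)]] <- NULL
      next
    }
    seen[[key]] <- TRUE
    if (top$i < length(node$parents)) {
      stack[[length(stack)]]$i <- top$i + 1L
      p <- node$parents[[top$i + 1L]]
      pkey <- as.character(p$id)
      if (is.null(seen[[pkey]])) stack[[length(stack) + 1L]] <- list(node = p, i = 0L)
    } else {
      ntopo <- ntopo + 1L
      if (ntopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[ntopo]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  topo <- topo[seq_len(ntopo)]
  root$grad <- if (is.null(grad)) {
    g <- array(1, dim = if (is.null(dim(root$value))) length(root$value) else dim(root$value))
    g
  } else grad
  for (i in rev(seq_len(ntopo))) {
    node <- topo[[i]]
    if (is.null(node$backward) || is.null(node$grad)) next
    gs <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- node$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# The DFS above marks nodes as seen before children are expanded, which would
# skip shared subgraphs; re-expansion is prevented per-node instead, so a node
# reached twice still contributes both gradient paths (grads accumulate on the
# node itself, not per-edge).

# ---------------------------------------------------------------------------
# Ops. All volumetric tensors are (D,H,W,C,N) arrays; feature matrices (F,N).
# ---------------------------------------------------------------------------

op_conv3d <- function(x, w, b, stride = 1L, pad = 1L) {
  x <- ag_wrap(x); w <- ag_wrap(w); b <- ag_wrap(b)
  xv <- x$value; wv <- w$value
  out <- cpp_conv3d_fwd(xv, wv, b$value, as.integer(stride), as.integer(pad))
  ag_node(out, list(x, w, b), function(g) {
    dim(g) <- dim(out)
    gw <- cpp_conv3d_bwd_weight(g, xv, dim(wv), as.integer(stride), as.integer(pad))
    list(cpp_conv3d_bwd_input(g, wv, dim(xv), as.integer(stride), as.integer(pad)),
         gw$gw, gw$gb)
  })
}

op_upsample <- function(x, factor = 2L) {
  x <- ag_wrap(x)
  xv <- x$value
  out <- cpp_upsample3d_fwd(xv, as.integer(factor))
  ag_node(out, list(x), function(g) {
    dim(g) <- dim(out)
    list(cpp_upsample3d_bwd(g, dim(xv), as.integer(factor)))
  })
}

op_leaky_relu <- function(x, slope = 0.01) {
  x <- ag_wrap(x)
  xv <- x$value
  pos <- xv > 0
  out <- xv * ifelse(pos, 1, slope)
  ag_node(out, list(x), function(g) list(g * ifelse(pos, 1, slope)))
}

op_relu <- function(x) {
  x <- ag_wrap(x)
  xv <- x$value
  pos <- xv > 0
  ag_node(xv * pos, list(x), function(g) list(g * pos))
}

op_sigmoid <- function(x) {
  x <- ag_wrap(x)
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

op_add <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

op_concat_c <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  stopifnot(all(da[c(1:3, 5)] == db[c(1:3, 5)]))
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- av
  out[, , , da[4] + seq_len(db[4]), ] <- bv
  ag_node(out, list(a, b), function(g) {
    dim(g) <- dim(out)
    ga <- g[, , , seq_len(da[4]), , drop = FALSE]
    gb <- g[, , , da[4] + seq_len(db[4]), , drop = FALSE]
    dim(ga) <- da; dim(gb) <- db
    list(ga, gb)
  })
}

op_flatten <- function(x) {
  x <- ag_wrap(x)
  d <- dim(x$value)
  out <- x$value
  dim(out) <- c(prod(d[1:4]), d[5])
  ag_node(out, list(x), function(g) { dim(g) <- d; list(g) })
}

op_reshape <- function(x, dims) {
  x <- ag_wrap(x)
  d <- dim(x$value)
  out <- x$value
  dim(out) <- dims
  ag_node(out, list(x), function(g) { dim(g) <- d; list(g) })
}

op_global_pool <- function(x) {
  x <- ag_wrap(x)
  d <- dim(x$value)
  S <- prod(d[1:3])
  m <- x$value
  dim(m) <- c(S, d[4] * d[5])
  out <- matrix(colMeans(m), d[4], d[5])
  ag_node(out, list(x), function(g) {
    gx <- array(rep(as.vector(g) / S, each = S), dim = d)
    list(gx)
  })
}

op_linear <- function(x, w, b) {
  # x: (F, N); w: (out, F); b: length out
  x <- ag_wrap(x); w <- ag_wrap(w); b <- ag_wrap(b)
  xv <- x$value; wv <- w$value
  out <- wv %*% xv + b$value
  ag_node(out, list(x, w, b), function(g) {
    list(crossprod(wv, g), tcrossprod(g, xv), rowSums(g))
  })
}

# Batch normalization over (spatial x batch) per channel. `state` is an
# environment carrying running_mean / running_var used in eval mode.
op_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  x <- ag_wrap(x); gamma <- ag_wrap(gamma); beta <- ag_wrap(beta)
  xv <- x$value
  d <- dim(xv)
  C <- d[4]; S <- prod(d[1:3]); N <- d[5]
  m <- S * N
  xm <- xv
  dim(xm) <- c(S, C, N)
  gv <- gamma$value; bv <- beta$value
  out <- array(0, d)
  dim(out) <- c(S, C, N)
  xhat <- array(0, c(S, C, N))
  invstd <- numeric(C)
  for (c in seq_len(C)) {
    slab <- xm[, c, ]
    if (training) {
      mu <- mean(slab)
      va <- mean((slab - mu)^2)
      state$running_mean[c] <- (1 - momentum) * state$running_mean[c] + momentum * mu
      state$running_var[c] <- (1 - momentum) * state$running_var[c] + momentum * va
    } else {
      mu <- state$running_mean[c]
      va <- state$running_var[c]
    }
    invstd[c] <- 1 / sqrt(va + eps)
    xh <- (slab - mu) * invstd[c]
    xhat[, c, ] <- xh
    out[, c, ] <- gv[c] * xh + bv[c]
  }
  dim(out) <- d
  ag_node(out, list(x, gamma, beta), function(g) {
    dim(g) <- d
    gm <- g
    dim(gm) <- c(S, C, N)
    gx <- array(0, c(S, C, N))
    ggamma <- numeric(C)
    gbeta <- numeric(C)
    for (c in seq_len(C)) {
      gy <- gm[, c, ]
      xh <- xhat[, c, ]
      ggamma[c] <- sum(gy * xh)
      gbeta[c] <- sum(gy)
      if (training) {
        gxh <- gy * gv[c]
        gx[, c, ] <- invstd[c] / m * (m * gxh - sum(gxh) - xh * sum(gxh * xh))
      } else {
        gx[, c, ] <- gy * gv[c] * invstd[c]
      }
    }
    dim(gx) <- d
    list(gx, ggamma, gbeta)
  })
}

# ---------------------------------------------------------------------------
# Losses (mean-reduced scalars)
# ---------------------------------------------------------------------------

op_loss_l1 <- function(pred, target) {
  pred <- ag_wrap(pred)
  dlt <- pred$value - target
  n <- length(dlt)
  ag_node(sum(abs(dlt)) / n, list(pred), function(g) list(as.numeric(g) * sign(dlt) / n))
}

op_loss_l2 <- function(pred, target) {
  pred <- ag_wrap(pred)
  dlt <- pred$value - target
  n <- length(dlt)
  ag_node(sum(dlt^2) / n, list(pred), function(g) list(as.numeric(g) * 2 * dlt / n))
}

op_loss_bce <- function(pred, target, eps = 1e-7) {
  if (any(target < 0 | target > 1)) stop("BCE target must lie in [0,1]")
  pred <- ag_wrap(pred)
  p <- pmin(pmax(pred$value, eps), 1 - eps)
  n <- length(p)
  v <- -sum(target * log(p) + (1 - target) * log(1 - p)) / n
  ag_node(v, list(pred), function(g) {
    gr <- as.numeric(g) * (p - target) / (p * (1 - p)) / n
    dim(gr) <- dim(pred$value)
    list(gr)
  })
}

# Two-class cross-entropy on a (2, N) logit matrix against one-hot targets;
# this is the binary cross-entropy of the softmax head.
op_loss_softmax_bce <- function(logits, onehot) {
  logits <- ag_wrap(logits)
  lv <- logits$value
  mx <- apply(lv, 2, max)
  e <- exp(sweep(lv, 2, mx))
  p <- sweep(e, 2, colSums(e), "/")
  n <- ncol(lv)
  v <- -sum(onehot * log(pmax(p, 1e-12))) / n
  ag_node(v, list(logits), function(g) list(as.numeric(g) * (p - onehot) / n))
}

softmax_cols <- function(logits) {
  mx <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  sweep(e, 2, colSums(e), "/")
}

loss_spec_fn <- function(kind = c("L1", "L2", "BCE")) {
  kind <- match.arg(toupper(kind), c("L1", "L2", "BCE"))
  switch(kind, L1 = op_loss_l1, L2 = op_loss_l2, BCE = op_loss_bce)
}
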