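# Minimal reverse-mode autodiff over dense arrays.
#
# Batched image tensors use the internal layout (H, W, C, N); fully connected
# activations use (features, N) matrices; losses are length-1 numerics. Nodes
# are environments carrying a value, a gradient slot and a backward closure
# that scatters the incoming gradient to the parents. Graphs are rebuilt every
# forward pass (define-by-run); only parameter nodes persist across steps.

.ag_counter <- new.env(parent = emptyenv())
.ag_counter$id <- 0L

ag_node <- function(value, parents = list(), backward = NULL, is_param = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$is_param <- is_param
  class(e) <- "ag_node"
  e
}

ag_param <- function(value) ag_node(value, is_param = TRUE)
ag_const <- function(value) ag_node(value)

ag_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Reverse topological order by iterative post-order DFS from the loss node.
# Visited nodes are marked with a per-traversal token written onto the node
# itself: keying a lookup environment by node-id strings would intern one
# permanent symbol per node and degrade the whole session over time.
ag_toposort <- function(root) {
  token <- .ag_counter$visit <- (.ag_counter$visit %||% 0L) + 1L
  order <- vector("list", 256L)
  n_out <- 0L
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (top$stage == 1L) {
      if (identical(node$vtoken, token)) next
      node$vtoken <- token
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (!identical(p$vtoken, token)) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_out <- n_out + 1L
      if (n_out > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_out]] <- node
    }
  }
  order[seq_len(n_out)]
}

# Backpropagate from a scalar loss node. Parameter gradients accumulate in
# node$grad; call ag_zero_grads() on the parameter list between steps.
ag_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  topo <- ag_toposort(loss)
  for (i in rev(seq_along(topo))) {
    node <- topo[[i]]
    if (!is.null(node$backward) && !is.null(node$grad)) {
      node$backward(node$grad)
    }
  }
  invisible(NULL)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- primitive ops ---------------------------------------------------------

ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  dw <- dim(w$value)
  kh <- dw[1]; kw <- dw[2]; cin <- dw[3]; cout <- dw[4]
  if (cin != C) stop("conv2d: input has ", C, " channels, kernel expects ", cin)
  Ho <- (H + 2L * pad - kh) %/% stride + 1L
  Wo <- (W + 2L * pad - kw) %/% stride + 1L
  Wmat <- matrix(w$value, kh * kw * cin, cout)
  pointwise <- kh == 1L && kw == 1L && stride == 1L && pad == 0L
  cols <- if (pointwise) {
    conv_unpack_cpp(x$value, H, W, C, N)       # 1x1: plain channel gather
  } else {
    im2col_cpp(x$value, H, W, C, N, kh, kw, stride, pad)
  }
  y <- crossprod(Wmat, cols)                   # cout x (Ho*Wo*N)
  out <- conv_pack_cpp(y, b$value, Ho, Wo, cout, N)
  dim(out) <- c(Ho, Wo, cout, N)
  node <- ag_node(out, parents = list(x, w, b))
  # a leaf constant (raw input batch) needs no input gradient
  x_is_leaf <- is.null(x$backward) && !x$is_param && length(x$parents) == 0L
  node$backward <- function(g) {
    dY <- conv_unpack_cpp(g, Ho, Wo, cout, N)  # cout x (Ho*Wo*N)
    ag_accum(w, array(tcrossprod(cols, dY), dw))
    ag_accum(b, rowSums(dY))
    if (!x_is_leaf) {
      dcols <- Wmat %*% dY
      dx <- if (pointwise) {
        conv_pack_cpp(dcols, numeric(C), H, W, C, N)
      } else {
        col2im_cpp(dcols, H, W, C, N, kh, kw, stride, pad)
      }
      dim(dx) <- d
      ag_accum(x, dx)
    }
  }
  node
}

# Batch normalisation over (H, W, N) per channel. `layer` is an environment
# holding running_mean / running_var buffers that are updated in training mode.
ag_batchnorm <- function(x, gamma, beta, layer, training,
                         momentum = 0.1, eps = 1e-5, relu = FALSE) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  HW <- H * W
  M <- HW * N
  if (training) {
    st <- bn_stats_cpp(x$value, HW, C, N)
    mu <- st$mean
    v <- st$var
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    layer$running_var <- (1 - momentum) * layer$running_var + momentum * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  istd <- 1 / sqrt(v + eps)
  sc <- gamma$value * istd
  shift <- beta$value - mu * sc
  y <- bn_affine_cpp(x$value, sc, shift, HW, C, N)
  if (relu) y[y < 0] <- 0
  dim(y) <- d
  node <- ag_node(y, parents = list(x, gamma, beta))
  if (training) {
    xhat <- bn_affine_cpp(x$value, istd, -mu * istd, HW, C, N)
    dim(xhat) <- d
    node$backward <- function(g) {
      if (relu) g <- g * (y > 0)
      dots <- bn_dots_cpp(g, xhat, HW, C, N)
      a <- gamma$value * istd
      dx <- bn_bwd_cpp(g, xhat, a, -a * dots$dbeta / M,
                       -a * dots$dgamma / M, HW, C, N)
      dim(dx) <- d
      ag_accum(x, dx)
      ag_accum(gamma, dots$dgamma)
      ag_accum(beta, dots$dbeta)
    }
  } else {
    node$backward <- function(g) {
      if (relu) g <- g * (y > 0)
      xhat <- bn_affine_cpp(x$value, istd, -mu * istd, HW, C, N)
      dots <- bn_dots_cpp(g, xhat, HW, C, N)
      dg <- bn_affine_cpp(g, sc, numeric(C), HW, C, N)
      dim(dg) <- d
      ag_accum(x, dg)
      ag_accum(gamma, dots$dgamma)
      ag_accum(beta, dots$dbeta)
    }
  }
  node
}

ag_relu <- function(x) {
  y <- x$value
  y[y < 0] <- 0
  node <- ag_node(y, parents = list(x))
  node$backward <- function(g) ag_accum(x, g * (x$value > 0))
  node
}

ag_tanh <- function(x) {
  y <- tanh(x$value)
  # keep the output in the open interval: double-precision tanh rounds to
  # exactly +/-1 for |x| > ~19, where the gradient is zero anyway
  eps <- 1e-12
  y[y >= 1] <- 1 - eps
  y[y <= -1] <- -1 + eps
  node <- ag_node(y, parents = list(x))
  node$backward <- function(g) ag_accum(x, g * (1 - y * y))
  node
}

ag_add <- function(a, b) {
  node <- ag_node(a$value + b$value, parents = list(a, b))
  node$backward <- function(g) {
    ag_accum(a, g)
    ag_accum(b, g)
  }
  node
}

# Concatenate along the channel axis of (H, W, C, N).
ag_concat_ch <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  Ca <- da[3]; Cb <- db[3]
  out <- array(0, c(da[1], da[2], Ca + Cb, da[4]))
  out[, , seq_len(Ca), ] <- a$value
  out[, , Ca + seq_len(Cb), ] <- b$value
  node <- ag_node(out, parents = list(a, b))
  node$backward <- function(g) {
    ag_accum(a, g[, , seq_len(Ca), , drop = FALSE])
    ag_accum(b, g[, , Ca + seq_len(Cb), , drop = FALSE])
  }
  node
}

# Nearest-neighbour x2 upsampling (deterministic).
ag_upsample2 <- function(x) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]
  ri <- rep(seq_len(H), each = 2)
  ci <- rep(seq_len(W), each = 2)
  y <- x$value[ri, ci, , , drop = FALSE]
  node <- ag_node(y, parents = list(x))
  node$backward <- function(g) {
    o1 <- seq(1L, 2L * H, by = 2L); o2 <- o1 + 1L
    p1 <- seq(1L, 2L * W, by = 2L); p2 <- p1 + 1L
    dx <- g[o1, p1, , , drop = FALSE] + g[o2, p1, , , drop = FALSE] +
      g[o1, p2, , , drop = FALSE] + g[o2, p2, , , drop = FALSE]
    ag_accum(x, dx)
  }
  node
}

# Inverted dropout; draws its mask from R's global RNG stream so full runs are
# reproducible under set.seed().
ag_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  mask <- array((stats::runif(length(x$value)) >= p) / (1 - p), dim(x$value))
  node <- ag_node(x$value * mask, parents = list(x))
  node$backward <- function(g) ag_accum(x, g * mask)
  node
}

# Flatten (H, W, C, N) to a (features, N) matrix.
ag_flatten <- function(x) {
  d <- dim(x$value)
  nf <- prod(d[1:3]); N <- d[4]
  node <- ag_node(matrix(x$value, nf, N), parents = list(x))
  node$backward <- function(g) ag_accum(x, array(g, d))
  node
}

# Fully connected layer: w is (features, out), x is (features, N).
ag_fc <- function(x, w, b) {
  y <- crossprod(w$value, x$value) + b$value
  node <- ag_node(y, parents = list(x, w, b))
  node$backward <- function(g) {
    ag_accum(w, tcrossprod(x$value, g))
    ag_accum(b, rowSums(g))
    ag_accum(x, w$value %*% g)
  }
  node
}

# Channel-wise softmax on (H, W, C, N).
ag_softmax_ch <- function(x) {
  v <- x$value
  d <- dim(v)
  C <- d[3]
  m <- v[, , 1, , drop = FALSE]
  if (C > 1) for (c in 2:C) m <- pmax(m, v[, , c, , drop = FALSE])
  e <- exp(v - m[, , rep(1, C), , drop = FALSE])
  s <- e[, , 1, , drop = FALSE]
  if (C > 1) for (c in 2:C) s <- s + e[, , c, , drop = FALSE]
  p <- e / s[, , rep(1, C), , drop = FALSE]
  node <- ag_node(p, parents = list(x))
  node$backward <- function(g) {
    gp <- g * p
    sgp <- gp[, , 1, , drop = FALSE]
    if (C > 1) for (c in 2:C) sgp <- sgp + gp[, , c, , drop = FALSE]
    ag_accum(x, gp - p * sgp[, , rep(1, C), , drop = FALSE])
  }
  node
}

ag_slice_ch <- function(x, ch) {
  d <- dim(x$value)
  node <- ag_node(array(x$value[, , ch, ], d[c(1, 2, 4)]), parents = list(x))
  node$backward <- function(g) {
    dx <- array(0, d)
    dx[, , ch, ] <- g
    ag_accum(x, dx)
  }
  node
}

## ---- loss heads ------------------------------------------------------------

# Mean squared error against a fixed target array.
ag_mse <- function(x, target) {
  diff <- x$value - target
  n <- length(diff)
  node <- ag_node(sum(diff * diff) / n, parents = list(x))
  node$backward <- function(g) ag_accum(x, g * 2 * diff / n)
  node
}

# Soft Dice loss on foreground probabilities, averaged over the batch.
# prob: node with (H, W, N); target: (H, W, N) binary array.
ag_dice_loss <- function(prob, target, smooth = 1) {
  p <- prob$value
  d <- dim(p)
  N <- d[3]
  per <- numeric(N)
  grads <- array(0, d)
  for (n in seq_len(N)) {
    pn <- p[, , n]
    tn <- target[, , n]
    A <- sum(pn * tn); P <- sum(pn); Tt <- sum(tn)
    den <- P + Tt + smooth
    if (den == 0) {
      per[n] <- 0                      # empty-vs-empty: perfect by convention
    } else {
      per[n] <- 1 - (2 * A + smooth) / den
      grads[, , n] <- -(2 * tn * den - (2 * A + smooth)) / (den * den)
    }
  }
  node <- ag_node(mean(per), parents = list(prob))
  node$backward <- function(g) ag_accum(prob, g * grads / N)
  node
}

# Softmax cross-entropy on (2, N) logits against integer labels (1 or 2,
# indexing the row that should win). Probabilities are clamped before log.
ag_softmax_ce <- function(logits, labels, clamp = 1e-7) {
  z <- logits$value
  N <- ncol(z)
  m <- apply(z, 2, max)
  e <- exp(sweep(z, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  picked <- p[cbind(labels, seq_len(N))]
  val <- mean(-log(pmin(pmax(picked, clamp), 1 - clamp)))
  node <- ag_node(val, parents = list(logits))
  node$backward <- function(g) {
    onehot <- matrix(0, nrow(z), N)
    onehot[cbind(labels, seq_len(N))] <- 1
    ag_accum(logits, g * (p - onehot) / N)
  }
  node
}

# Scalar combination a + k * b for scalar loss nodes.
ag_axpy <- function(a, b, k) {
  node <- ag_node(a$value + k * b$value, parents = list(a, b))
  node$backward <- function(g) {
    ag_accum(a, g)
    ag_accum(b, g * k)
  }
  node
}

ag_scale <- function(a, k) {
  node <- ag_node(k * a$value, parents = list(a))
  node$backward <- function(g) ag_accum(a, g * k)
  node
}

## ---- optimiser -------------------------------------------------------------

adam_new <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$beta1 <- beta1
  opt$beta2 <- beta2
  opt$eps <- eps
  opt$t <- 0L
  # shape-preserving zeros; m and v must be distinct allocations because the
  # Adam kernel updates them in place
  opt$m <- lapply(params, function(p) p$value * 0)
  opt$v <- lapply(params, function(p) p$value * 0)
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    d <- dim(p$value)
    newv <- adam_update_cpp(p$value, p$grad, opt$m[[i]], opt$v[[i]],
                            opt$lr, opt$beta1, opt$beta2, opt$eps, bc1, bc2)
    if (!is.null(d)) dim(newv) <- d
    p$value <- newv
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
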