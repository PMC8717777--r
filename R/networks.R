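# The four computation graphs of the co-optimization framework:
#   R — encoder-decoder reconstructor (Tanh output, no skips),
#   S — encoder-decoder segmenter (U-style skip connections, softmax output),
#   D — convolutional discriminator (real vs reconstructed),
#   T — transfer block (Conv1x1 -> BN -> ReLU) fusing R's bottleneck into S's.
# R and S share the same encoder architecture (independently initialised):
# a ResNet-style stem plus `n_stages` stages of bottleneck residual blocks
# with channel doubling, the first block of each stage downsampling by 2.

#' Network architecture configuration
#'
#' @param in_channels number of input modality channels.
#' @param height,width spatial input size in pixels; must be divisible by
#'   `2^n_stages`.
#' @param base_width feature channels after the stem; stage k carries
#'   `base_width * 2^(k-1)` channels.
#' @param n_stages encoder downsampling stages.
#' @param num_classes segmentation classes (background + foreground = 2).
#' @param skip_fusion how residual blocks combine the convolution path with
#'   the identity path: `"concat"` (concat + 1x1 projection, the default) or
#'   `"add"` (elementwise).
#' @param blocks_per_stage residual blocks per encoder stage (2 gives the
#'   ResNet-18-style layout; 1 is the desk-scale setting).
#' @param fc_width neurons in the discriminator's hidden FC layer.
#' @return A `network_config` list.
#' @export
network_config <- function(in_channels, height = 64, width = 64,
                           base_width = 32, n_stages = 4, num_classes = 2,
                           skip_fusion = c("concat", "add"),
                           blocks_per_stage = 2, fc_width = 512) {
  skip_fusion <- match.arg(skip_fusion)
  stopifnot(in_channels >= 1, base_width >= 1, n_stages >= 1,
            num_classes >= 2, blocks_per_stage >= 1, fc_width >= 1)
  div <- 2^n_stages
  if (height %% div != 0 || width %% div != 0) {
    stop("input size ", height, "x", width, " is not divisible by 2^",
         n_stages, "; pad the slices to a multiple of ", div)
  }
  structure(list(in_channels = as.integer(in_channels),
                 height = as.integer(height), width = as.integer(width),
                 base_width = as.integer(base_width),
                 n_stages = as.integer(n_stages),
                 num_classes = as.integer(num_classes),
                 skip_fusion = skip_fusion,
                 blocks_per_stage = as.integer(blocks_per_stage),
                 fc_width = as.integer(fc_width)),
            class = "network_config")
}

## ---- layer constructors ----------------------------------------------------

he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

conv_layer <- function(kh, kw, cin, cout, stride = 1L, pad = 0L) {
  structure(list(w = ag_param(he_init(kh, kw, cin, cout)),
                 b = ag_param(numeric(cout)),
                 stride = as.integer(stride), pad = as.integer(pad)),
            class = "conv_layer")
}

conv_fwd <- function(layer, x) {
  ag_conv2d(x, layer$w, layer$b, stride = layer$stride, pad = layer$pad)
}

bn_layer <- function(C) {
  e <- new.env(parent = emptyenv())
  e$gamma <- ag_param(rep(1, C))
  e$beta <- ag_param(rep(0, C))
  e$running_mean <- numeric(C)
  e$running_var <- rep(1, C)
  class(e) <- "bn_layer"
  e
}

bn_fwd <- function(layer, x, training) {
  ag_batchnorm(x, layer$gamma, layer$beta, layer, training)
}

bn_relu_fwd <- function(layer, x, training) {
  ag_batchnorm(x, layer$gamma, layer$beta, layer, training, relu = TRUE)
}

fc_layer <- function(fin, fout) {
  structure(list(w = ag_param(matrix(stats::rnorm(fin * fout,
                                                  sd = sqrt(2 / fin)),
                                     fin, fout)),
                 b = ag_param(numeric(fout))),
            class = "fc_layer")
}

cbr <- function(kh, cin, cout, stride = 1L) {
  # Conv-BN-ReLU unit; 3x3 convs use pad 1 so stride-1 keeps spatial dims
  pad <- if (kh == 3) 1L else 0L
  list(conv = conv_layer(kh, kh, cin, cout, stride, pad), bn = bn_layer(cout))
}

cbr_fwd <- function(unit, x, training) {
  bn_relu_fwd(unit$bn, conv_fwd(unit$conv, x), training)
}

## ---- residual block --------------------------------------------------------

#' Create parameters for a bottleneck residual block
#'
#' Three convolutions (1x1, 3x3, 1x1) with BN/ReLU between them, combined
#' with the identity path by the configured fusion: `"concat"` concatenates
#' the two paths and projects back to `cout` with a 1x1 convolution,
#' `"add"` sums them elementwise. The stride-2 variant halves the spatial
#' dims (the identity path is then a strided 1x1 projection).
#'
#' @param cin,cout input/output channel counts.
#' @param stride 1 (dims preserved) or 2 (halved).
#' @param fusion `"concat"` or `"add"`.
#' @return A `res_block` parameter list.
#' @export
res_block_params <- function(cin, cout, stride = 1L, fusion = "concat") {
  mid <- max(cout %/% 2L, 1L)
  needs_proj <- stride != 1L || cin != cout
  structure(list(
    conv1 = conv_layer(1, 1, cin, mid, stride = stride),
    bn1 = bn_layer(mid),
    conv2 = conv_layer(3, 3, mid, mid, pad = 1L),
    bn2 = bn_layer(mid),
    conv3 = conv_layer(1, 1, mid, cout),
    bn3 = bn_layer(cout),
    shortcut = if (needs_proj) {
      list(conv = conv_layer(1, 1, cin, cout, stride = stride),
           bn = bn_layer(cout))
    },
    proj = if (fusion == "concat") conv_layer(1, 1, 2L * cout, cout),
    cin = as.integer(cin), cout = as.integer(cout),
    stride = as.integer(stride), fusion = fusion
  ), class = "res_block")
}

res_block_fwd <- function(p, x, training) {
  h <- bn_relu_fwd(p$bn1, conv_fwd(p$conv1, x), training)
  h <- bn_relu_fwd(p$bn2, conv_fwd(p$conv2, h), training)
  h <- bn_fwd(p$bn3, conv_fwd(p$conv3, h), training)
  id <- if (is.null(p$shortcut)) x else {
    bn_fwd(p$shortcut$bn, conv_fwd(p$shortcut$conv, x), training)
  }
  if (p$fusion == "add") ag_add(h, id) else conv_fwd(p$proj, ag_concat_ch(h, id))
}

#' Apply a residual block to a feature map
#'
#' Shape contract: a stride-1 block preserves spatial dims, a stride-2 block
#' halves them; the output has the block's declared channel count. With all
#' convolution weights zero and `fusion = "add"` the block is the identity.
#'
#' @param feature c x h x w numeric array.
#' @param block_params a [res_block_params()] object whose `cin` matches the
#'   feature's channel count.
#' @param training use batch statistics in BN (default: running statistics).
#' @return c_out x h' x w' array.
#' @export
residual_block <- function(feature, block_params, training = FALSE) {
  stopifnot(inherits(block_params, "res_block"), length(dim(feature)) == 3)
  if (dim(feature)[1] != block_params$cin) {
    stop("residual_block: feature has ", dim(feature)[1],
         " channels, block expects ", block_params$cin)
  }
  x <- ag_const(feature_to_batch(feature))
  out <- res_block_fwd(block_params, x, training)
  batch_to_feature(out$value)
}

feature_to_batch <- function(f) {
  # (c, h, w) -> (h, w, c, 1)
  a <- aperm(f, c(2, 3, 1))
  dim(a) <- c(dim(a), 1L)
  a
}

# drop the batch axis of (H, W, C, n) safely even when C == 1
batch_to_feature <- function(b, n = 1L) {
  d <- dim(b)
  aperm(array(b[, , , n], d[1:3]), c(3, 1, 2))
}

## ---- encoder (shared by R and S) ------------------------------------------

new_encoder <- function(cfg) {
  w <- cfg$base_width
  stem <- cbr(3, cfg$in_channels, w)
  widths <- w * 2^(seq_len(cfg$n_stages) - 1L)
  cin <- w
  stages <- lapply(seq_len(cfg$n_stages), function(k) {
    blocks <- vector("list", cfg$blocks_per_stage)
    blocks[[1]] <- res_block_params(cin, widths[k], stride = 2L,
                                    fusion = cfg$skip_fusion)
    if (cfg$blocks_per_stage > 1) {
      for (j in 2:cfg$blocks_per_stage) {
        blocks[[j]] <- res_block_params(widths[k], widths[k],
                                        fusion = cfg$skip_fusion)
      }
    }
    cin <<- widths[k]
    blocks
  })
  list(stem = stem, stages = stages, widths = widths)
}

encoder_fwd <- function(enc, x, training) {
  h <- cbr_fwd(enc$stem, x, training)
  skips <- list(h)                      # full-resolution skip
  n <- length(enc$stages)
  for (k in seq_len(n)) {
    for (blk in enc$stages[[k]]) h <- res_block_fwd(blk, h, training)
    if (k < n) skips[[k + 1L]] <- h     # skips at H/2 ... H/2^(n-1)
  }
  list(skips = skips, bottleneck = h)
}

## ---- segmenter -------------------------------------------------------------

new_segmenter <- function(cfg) {
  enc <- new_encoder(cfg)
  w <- cfg$base_width
  skip_ch <- c(w, enc$widths[-cfg$n_stages])     # channels of skips, level 1..n
  dec <- vector("list", cfg$n_stages)
  hin <- enc$widths[cfg$n_stages]
  for (j in seq_len(cfg$n_stages)) {
    sc <- skip_ch[cfg$n_stages - j + 1L]
    dec[[j]] <- list(c1 = cbr(3, hin + sc, sc), c2 = cbr(3, sc, sc))
    hin <- sc
  }
  head <- conv_layer(1, 1, w, cfg$num_classes)
  list(encoder = enc, decoder = dec, head = head)
}

seg_fwd <- function(s, x, training, dropout = 0, fused_bottleneck = NULL,
                    enc_out = NULL) {
  if (is.null(enc_out)) enc_out <- encoder_fwd(s$encoder, x, training)
  h <- fused_bottleneck %||% enc_out$bottleneck
  n <- length(s$decoder)
  for (j in seq_len(n)) {
    h <- ag_upsample2(h)
    h <- ag_concat_ch(h, enc_out$skips[[n - j + 1L]])
    h <- cbr_fwd(s$decoder[[j]]$c1, h, training)
    h <- cbr_fwd(s$decoder[[j]]$c2, h, training)
    h <- ag_dropout(h, dropout, training)
  }
  probs <- ag_softmax_ch(conv_fwd(s$head, h))
  list(probs = probs, bottleneck = enc_out$bottleneck, enc_out = enc_out)
}

## ---- reconstructor ---------------------------------------------------------

new_reconstructor <- function(cfg) {
  enc <- new_encoder(cfg)
  widths <- enc$widths
  n <- cfg$n_stages
  chans <- c(rev(widths)[-1], cfg$base_width)    # 4w, 2w, w, w for n = 4
  dec <- vector("list", n)
  hin <- widths[n]
  for (j in seq_len(n)) {
    dec[[j]] <- cbr(3, hin, chans[j])
    hin <- chans[j]
  }
  head <- conv_layer(1, 1, hin, cfg$in_channels)
  list(encoder = enc, decoder = dec, head = head)
}

recon_fwd <- function(r, x, training, dropout = 0) {
  enc_out <- encoder_fwd(r$encoder, x, training)
  h <- enc_out$bottleneck
  for (unit in r$decoder) {
    h <- ag_upsample2(h)
    h <- cbr_fwd(unit, h, training)
    h <- ag_dropout(h, dropout, training)
  }
  out <- ag_tanh(conv_fwd(r$head, h))
  list(reconstruction = out, middle_feature = enc_out$bottleneck)
}

## ---- discriminator ---------------------------------------------------------

new_discriminator <- function(cfg) {
  w <- cfg$base_width
  chans <- c(w, 2L * w, 4L * w, 8L * w)
  convs <- vector("list", 4)
  cin <- cfg$in_channels
  for (j in 1:4) {
    convs[[j]] <- cbr(3, cin, chans[j], stride = 2L)
    cin <- chans[j]
  }
  flat <- (cfg$height %/% 16L) * (cfg$width %/% 16L) * chans[4]
  list(convs = convs,
       fc1 = fc_layer(flat, cfg$fc_width),
       fc2 = fc_layer(cfg$fc_width, 2L))
}

# Returns (2, N) logits; row 1 = reconstructed/fake, row 2 = real.
disc_fwd <- function(d, x, training) {
  h <- x
  for (unit in d$convs) h <- cbr_fwd(unit, h, training)
  h <- ag_relu(ag_fc(ag_flatten(h), d$fc1$w, d$fc1$b))
  ag_fc(h, d$fc2$w, d$fc2$b)
}

## ---- transfer block --------------------------------------------------------

new_transfer <- function(cin, cout) {
  list(conv = conv_layer(1, 1, cin, cout), bn = bn_layer(cout))
}

transfer_fwd <- function(t_params, mid_r, bottleneck_s, training) {
  mapped <- bn_relu_fwd(t_params$bn, conv_fwd(t_params$conv, mid_r), training)
  ag_add(mapped, bottleneck_s)
}

#' Fuse the reconstructor's bottleneck into the segmenter's
#'
#' Applies Conv1x1 -> BN -> ReLU to the reconstruction branch's middle
#' feature and adds the (nonnegative) result elementwise onto the
#' segmentation branch's bottleneck. Both features must share spatial dims.
#'
#' @param middle_feature_r,bottleneck_feature_s c x h x w arrays.
#' @param t_params transfer-block parameters ([new_transfer()] or the `t`
#'   component of a model state).
#' @param training use batch BN statistics.
#' @return Array shaped like `bottleneck_feature_s`.
#' @export
transfer_fuse <- function(middle_feature_r, bottleneck_feature_s, t_params,
                          training = FALSE) {
  da <- dim(middle_feature_r); db <- dim(bottleneck_feature_s)
  if (!all(da[2:3] == db[2:3])) {
    stop("transfer_fuse: spatial dims differ (", paste(da[2:3], collapse = "x"),
         " vs ", paste(db[2:3], collapse = "x"), ")")
  }
  out <- transfer_fwd(t_params, ag_const(feature_to_batch(middle_feature_r)),
                      ag_const(feature_to_batch(bottleneck_feature_s)),
                      training)
  batch_to_feature(out$value)
}

## ---- model state -----------------------------------------------------------

#' Initialise a full model state (R, S, D, T)
#'
#' The reconstructor and segmenter share the encoder architecture but are
#' independently initialised (distinct draws from the seeded stream).
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialisation.
#' @return A `model_state` with components `r`, `s`, `d`, `t`, `config`,
#'   `step`.
#' @export
new_model_state <- function(config, seed = 1) {
  stopifnot(inherits(config, "network_config"))
  set.seed(as.integer(seed) %% 2147483647L)
  bott <- config$base_width * 2L^(config$n_stages - 1L)
  structure(list(
    r = new_reconstructor(config),
    s = new_segmenter(config),
    d = new_discriminator(config),
    t = new_transfer(bott, bott),
    config = config,
    step = 0L,
    use_fusion = FALSE
  ), class = "model_state")
}

# Recursively collect ag_param nodes from a (nested) parameter structure.
collect_params <- function(x) {
  if (inherits(x, "ag_node")) return(if (x$is_param) list(x) else list())
  if (inherits(x, "bn_layer")) return(list(x$gamma, x$beta))
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

# Plain-value tree of parameters and BN buffers (for checkpoints / hashing).
state_values <- function(x) {
  if (inherits(x, "ag_node")) return(x$value)
  if (inherits(x, "bn_layer")) {
    return(list(gamma = x$gamma$value, beta = x$beta$value,
                running_mean = x$running_mean, running_var = x$running_var))
  }
  if (is.list(x)) {
    keep <- !vapply(x, is.null, logical(1))
    out <- lapply(x[keep], state_values)
    atom <- vapply(x[keep], function(e) !is.list(e) && !is.environment(e) &&
                     !inherits(e, "ag_node"), logical(1))
    out[atom] <- x[keep][atom]          # carry scalars (stride, fusion, ...)
    return(out)
  }
  x
}

state_assign <- function(x, v) {
  if (inherits(x, "ag_node")) {
    x$value <- v
    return(invisible(NULL))
  }
  if (inherits(x, "bn_layer")) {
    x$gamma$value <- v$gamma
    x$beta$value <- v$beta
    x$running_mean <- v$running_mean
    x$running_var <- v$running_var
    return(invisible(NULL))
  }
  if (is.list(x)) {
    keep <- which(!vapply(x, is.null, logical(1)))
    for (i in seq_along(keep)) state_assign(x[[keep[i]]], v[[i]])
  }
  invisible(NULL)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds all parameter values and BN running statistics for
#' R, S, D and T plus the architecture config and step counter; loading
#' reproduces forward outputs exactly (bitwise, in eval mode).
#'
#' @param state a `model_state`.
#' @param path checkpoint file path (RDS).
#' @return `path` (save) or the restored `model_state` (load).
#' @export
save_model_state <- function(state, path) {
  stopifnot(inherits(state, "model_state"))
  saveRDS(list(format = "coseg-checkpoint-1",
               values = state_values(state[c("r", "s", "d", "t")]),
               config = state$config, step = state$step,
               use_fusion = state$use_fusion),
          path)
  invisible(path)
}

#' @rdname save_model_state
#' @export
load_model_state <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "coseg-checkpoint-1")) {
    stop("not a recognised checkpoint file: ", path)
  }
  state <- new_model_state(ck$config, seed = 1)
  for (part in c("r", "s", "d", "t")) {
    state_assign(state[[part]], ck$values[[part]])
  }
  state$step <- ck$step
  state$use_fusion <- ck$use_fusion %||% FALSE
  state
}

# In-memory snapshot/restore used for best-epoch checkpointing.
snapshot_values <- function(state) state_values(state[c("r", "s", "d", "t")])
restore_values <- function(state, snap) {
  for (part in c("r", "s", "d", "t")) state_assign(state[[part]], snap[[part]])
  invisible(state)
}

## ---- user-facing forward passes -------------------------------------------

# Accepts a multimodal_slice, a C x H x W array, or a list of either;
# returns an (H, W, C, N) batch plus the case ids.
as_input_batch <- function(x, cfg) {
  if (inherits(x, "multimodal_slice") || (is.array(x) && length(dim(x)) == 3)) {
    x <- list(x)
  }
  vals <- lapply(x, function(e) {
    v <- if (inherits(e, "multimodal_slice")) e$values else
      if (inherits(e, "sample_record")) e$image$values else e
    stopifnot(length(dim(v)) == 3)
    v
  })
  d <- dim(vals[[1]])
  if (d[1] != cfg$in_channels) {
    stop("input has ", d[1], " channels but the model expects ",
         cfg$in_channels)
  }
  div <- 2L^cfg$n_stages
  if (d[2] %% div != 0 || d[3] %% div != 0) {
    stop("input dims ", d[2], "x", d[3], " not divisible by 2^", cfg$n_stages,
         "; pad the slices to a multiple of ", div)
  }
  batch <- array(0, c(d[2], d[3], d[1], length(vals)))
  for (n in seq_along(vals)) batch[, , , n] <- aperm(vals[[n]], c(2, 3, 1))
  batch
}

split_batch <- function(b) {
  lapply(seq_len(dim(b)[4]), function(n) batch_to_feature(b, n))
}

#' Segmenter forward pass (eval mode)
#'
#' @param state a `model_state`.
#' @param x a `multimodal_slice`, C x H x W array, or list of either.
#' @param fused_bottleneck optional c x h x w feature (from [transfer_fuse()])
#'   replacing the segmenter's bottleneck; only valid for single-image input.
#' @return num_classes x H x W array of per-pixel class probabilities (single
#'   input) or a list of them; probabilities at each pixel sum to 1.
#' @export
forward_segmenter <- function(state, x, fused_bottleneck = NULL) {
  single <- inherits(x, "multimodal_slice") ||
    (is.array(x) && length(dim(x)) == 3)
  batch <- as_input_batch(x, state$config)
  fused <- NULL
  if (!is.null(fused_bottleneck)) {
    stopifnot(dim(batch)[4] == 1L)
    fused <- ag_const(feature_to_batch(fused_bottleneck))
  }
  out <- seg_fwd(state$s, ag_const(batch), training = FALSE,
                 fused_bottleneck = fused)
  res <- split_batch(out$probs$value)
  if (single) res[[1]] else res
}

#' Reconstructor forward pass (eval mode)
#'
#' @inheritParams forward_segmenter
#' @return List with `reconstruction` (same C x H x W shape as the input,
#'   values in (-1, 1)) and `middle_feature` (the encoder bottleneck,
#'   c x h x w); lists of each for batch input.
#' @export
forward_reconstructor <- function(state, x) {
  single <- inherits(x, "multimodal_slice") ||
    (is.array(x) && length(dim(x)) == 3)
  batch <- as_input_batch(x, state$config)
  out <- recon_fwd(state$r, ag_const(batch), training = FALSE)
  rec <- split_batch(out$reconstruction$value)
  mid <- split_batch(out$middle_feature$value)
  if (single) {
    list(reconstruction = rec[[1]], middle_feature = mid[[1]])
  } else {
    list(reconstruction = rec, middle_feature = mid)
  }
}

#' Discriminator forward pass (eval mode)
#'
#' @inheritParams forward_segmenter
#' @return n x 2 matrix of probability pairs, columns
#'   `(P(reconstructed), P(real))`, each row summing to 1.
#' @export
forward_discriminator <- function(state, x) {
  batch <- as_input_batch(x, state$config)
  logits <- disc_fwd(state$d, ag_const(batch), training = FALSE)$value
  p <- apply(logits, 2, function(z) {
    e <- exp(z - max(z))
    e / sum(e)
  })
  out <- t(p)
  colnames(out) <- c("p_reconstructed", "p_real")
  out
}
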