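# Co-optimization training: unsupervised pretraining of the reconstruction
# branch, then a joint loop that each step draws one labeled and one
# pseudo-unlabeled batch, injects the reconstructor's bottleneck feature into
# the segmenter through the transfer block, and minimises
# loss_mix = loss_s + lambda * loss_r while the discriminator takes its own
# adversarial step. Validation Dice is monitored per epoch and the best
# checkpoint is returned (early stopping, ties to the earlier epoch).

merge_defaults <- function(user, defaults) {
  for (nm in names(user)) defaults[[nm]] <- user[[nm]]
  defaults
}

derive_seed <- function(seed, salt) {
  as.integer((abs(as.numeric(seed)) %% 65521 * 48271 +
                sum(utf8ToInt(salt))) %% 2147483629)
}

#' Training configuration
#'
#' Defaults follow the method's published regime: the reconstruction branch
#' pretrains with Adam at learning rate 1e-5 for 300 epochs, mini-batch 3,
#' dropout 0.01; the joint segmentation phase uses learning rate 1e-4 for 80
#' epochs, mini-batch 3, dropout 0.01; validation split 0.2 of the labeled
#' set; lambda 0.2; early stopping on validation Dice.
#'
#' @param recon,seg,network,early_stop named lists overriding the defaults
#'   shown above (`network` feeds [network_config()]).
#' @param lam weight of the reconstruction loss in the mixed objective.
#' @param validation_split fraction of the labeled set held out to monitor
#'   validation Dice.
#' @param seed master seed; initialisation, shuffling and dropout derive
#'   deterministic streams from it.
#' @param freeze_recon keep the reconstructor fixed during the joint phase.
#' @return A `train_config` list.
#' @export
train_config <- function(recon = list(), seg = list(), network = list(),
                         lam = 0.2, validation_split = 0.2, seed = 1,
                         early_stop = list(), freeze_recon = FALSE) {
  cfg <- list(
    recon = merge_defaults(recon, list(epochs = 300L, lr = 1e-5, batch = 3L,
                                       dropout = 0.01, adv_weight = 1.0)),
    seg = merge_defaults(seg, list(epochs = 80L, lr = 1e-4, batch = 3L,
                                   dropout = 0.01)),
    network = merge_defaults(network, list(base_width = 32L, n_stages = 4L,
                                           num_classes = 2L,
                                           skip_fusion = "concat",
                                           blocks_per_stage = 2L,
                                           fc_width = 512L)),
    early_stop = merge_defaults(early_stop, list(patience = 20L)),
    lam = lam, validation_split = validation_split,
    seed = as.integer(seed), freeze_recon = freeze_recon
  )
  stopifnot(cfg$recon$lr > 0, cfg$seg$lr > 0, cfg$recon$batch >= 1,
            cfg$seg$batch >= 1, cfg$recon$epochs >= 0, cfg$seg$epochs >= 0,
            cfg$lam >= 0, cfg$validation_split >= 0, cfg$validation_split < 1)
  structure(cfg, class = "train_config")
}

#' Desk-scale training configuration
#'
#' A scaled-down regime for single-CPU phantom experiments: narrow networks
#' (base width 4, one residual block per stage), short schedules (2
#' reconstruction pretraining epochs, 10 joint epochs) and a learning rate of
#' 1e-3 scaled up to match the much smaller step budget. See the methods
#' vignette for the reasoning.
#'
#' @inheritParams train_config
#' @param ... further overrides passed to [train_config()].
#' @export
desk_train_config <- function(seed = 1, lam = 0.2, ...) {
  args <- merge_defaults(list(...), list(
    recon = list(epochs = 2L, lr = 1e-3, batch = 3L),
    seg = list(epochs = 10L, lr = 1e-3, batch = 3L),
    network = list(base_width = 4L, blocks_per_stage = 1L, fc_width = 512L),
    early_stop = list(patience = 3L),
    lam = lam, seed = seed
  ))
  do.call(train_config, args)
}

net_config_for <- function(records, config) {
  d <- dim(records[[1]]$image$values)
  do.call(network_config, c(list(in_channels = d[1], height = d[2],
                                 width = d[3]), config$network))
}

records_batch <- function(records, cfg) {
  as_input_batch(records, cfg)
}

records_masks <- function(records) {
  d <- dim(records[[1]]$mask)
  y <- array(0, c(d[1], d[2], length(records)))
  for (n in seq_along(records)) y[, , n] <- records[[n]]$mask
  y
}

sub_batch <- function(x, idx) x[, , , idx, drop = FALSE]

effective_batch <- function(batch, n, what) {
  if (batch > n) {
    warning(what, ": batch size ", batch, " exceeds ", n,
            " records; reducing to ", n, call. = FALSE)
    return(n)
  }
  batch
}

real_label <- function(n) rep(2L, n)   # logits row 2 = real
fake_label <- function(n) rep(1L, n)

#' Pretrain the reconstruction branch (with discriminator) unsupervised
#'
#' Alternates, per mini-batch, a discriminator step (cross-entropy on real
#' inputs vs reconstructions) and a reconstructor step (MSE plus the
#' generator-side adversarial term). Deterministic given the config seed.
#' The returned state carries the weights of the best (lowest generator
#' loss) epoch.
#'
#' @param records pseudo-unlabeled `sample_record`s (labels ignored).
#' @param config a [train_config()].
#' @return List with `state` (a `model_state`) and `history` (one row per
#'   epoch: mse, generator and discriminator losses).
#' @export
pretrain_reconstruction <- function(records, config) {
  stopifnot(length(records) >= 1, inherits(config, "train_config"))
  net_cfg <- net_config_for(records, config)
  state <- new_model_state(net_cfg, seed = derive_seed(config$seed, "init"))
  X <- records_batch(records, net_cfg)
  n <- dim(X)[4]
  batch <- effective_batch(config$recon$batch, n, "pretrain_reconstruction")
  params_r <- collect_params(state$r)
  params_d <- collect_params(state$d)
  opt_r <- adam_new(params_r, config$recon$lr)
  opt_d <- adam_new(params_d, config$recon$lr)
  history <- NULL
  best <- Inf
  best_snap <- NULL
  set.seed(derive_seed(config$seed, "pretrain"))
  epochs <- config$recon$epochs
  if (epochs >= 1) for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    mse_acc <- gen_acc <- d_acc <- 0
    steps <- ceiling(n / batch)
    for (s in seq_len(steps)) {
      idx <- perm[((s - 1) * batch + 1):min(s * batch, n)]
      xb <- ag_const(sub_batch(X, idx))
      r_out <- recon_fwd(state$r, xb, training = TRUE,
                         dropout = config$recon$dropout)
      rec <- r_out$reconstruction
      # discriminator step: one forward over [real; reconstruction-detached]
      both <- ag_const(array(c(xb$value, rec$value),
                             dim(xb$value) + c(0, 0, 0, length(idx))))
      logit_both <- disc_fwd(state$d, both, training = TRUE)
      loss_d <- ag_scale(ag_softmax_ce(logit_both,
                                       c(real_label(length(idx)),
                                         fake_label(length(idx)))), 2)
      ag_backward(loss_d)
      adam_step(opt_d)
      ag_zero_grads(params_d)
      # reconstructor step (gradient flows through D, only R updates)
      mse <- ag_mse(rec, xb$value)
      logit_gen <- disc_fwd(state$d, rec, training = FALSE)
      gen <- ag_axpy(mse, ag_softmax_ce(logit_gen, real_label(length(idx))),
                     config$recon$adv_weight)
      ag_backward(gen)
      adam_step(opt_r)
      ag_zero_grads(c(params_r, params_d))
      mse_acc <- mse_acc + mse$value
      gen_acc <- gen_acc + gen$value
      d_acc <- d_acc + loss_d$value
    }
    row <- data.frame(epoch = ep, loss_mse = mse_acc / steps,
                      loss_gen = gen_acc / steps, loss_d = d_acc / steps)
    history <- rbind(history, row)
    if (row$loss_gen < best) {
      best <- row$loss_gen
      best_snap <- snapshot_values(state)
    }
  }
  if (!is.null(best_snap)) restore_values(state, best_snap)
  list(state = state,
       history = history %||% data.frame(epoch = integer(), loss_mse = numeric(),
                                         loss_gen = numeric(),
                                         loss_d = numeric()))
}

fg_channel <- function(cfg) cfg$num_classes  # last class = foreground

#' Jointly co-optimize segmentation and reconstruction branches
#'
#' Each step draws a labeled and a pseudo-unlabeled mini-batch (reshuffled
#' every epoch). The reconstructor runs on the unlabeled batch (giving
#' `loss_r`); its encoder also runs on the labeled batch and the transfer
#' block adds the mapped bottleneck feature onto the segmenter's bottleneck
#' before decoding (giving `loss_s`, a soft Dice loss with smoothing 1).
#' Segmenter, transfer block and (unless frozen) reconstructor update on
#' `loss_mix = loss_s + lam * loss_r`; the discriminator then takes its own
#' step. With `lam = 0` the run is fully decoupled: no reconstruction
#' forward, no fusion — exactly a supervised segmenter.
#'
#' Validation Dice is evaluated each epoch; the returned state is the best
#' validation checkpoint (ties to the earlier epoch), with early stopping
#' after `early_stop$patience` epochs without improvement.
#'
#' @param split a [split_dataset()] result with at least one labeled record
#'   (and one pseudo-unlabeled record when `lam > 0`).
#' @param config a [train_config()].
#' @param state optional `model_state` to start from (typically the result
#'   of [pretrain_reconstruction()]); a fresh seeded state otherwise.
#' @return List with `state`, `history` (per-epoch losses and validation
#'   Dice), `best_epoch`, `best_val_dc`.
#' @export
train_cooptimized <- function(split, config, state = NULL) {
  stopifnot(inherits(split, "dataset_split"), inherits(config, "train_config"))
  lam <- config$lam
  if (length(split$labeled) == 0) {
    stop("no labeled records: supervised Dice loss undefined ",
         "(lambda = 0 is meaningless without labels)")
  }
  if (lam > 0 && length(split$pseudo_unlabeled) == 0) {
    stop("lambda > 0 requires pseudo-unlabeled records")
  }
  net_cfg <- net_config_for(split$labeled, config)
  if (is.null(state)) {
    state <- new_model_state(net_cfg, seed = derive_seed(config$seed, "init"))
  }
  state$use_fusion <- lam > 0
  Xl <- records_batch(split$labeled, net_cfg)
  Yl <- records_masks(split$labeled)
  n_lab <- dim(Xl)[4]
  batch <- effective_batch(config$seg$batch, n_lab, "train_cooptimized")
  if (lam > 0) {
    Xu <- records_batch(split$pseudo_unlabeled, net_cfg)
    n_unl <- dim(Xu)[4]
    batch_u <- min(config$recon$batch, n_unl)
  }
  params_s <- collect_params(state$s)
  params_t <- collect_params(state$t)
  params_r <- collect_params(state$r)
  params_d <- collect_params(state$d)
  opt_st <- adam_new(c(params_s, params_t), config$seg$lr)
  if (lam > 0) {
    opt_r <- adam_new(params_r, config$recon$lr)
    opt_d <- adam_new(params_d, config$recon$lr)
  }
  fg <- fg_channel(net_cfg)
  history <- NULL
  best_dc <- -Inf
  best_epoch <- 0L
  best_snap <- NULL
  stall <- 0L
  set.seed(derive_seed(config$seed, "joint"))
  epochs <- config$seg$epochs
  if (epochs >= 1) for (ep in seq_len(epochs)) {
    perm_l <- sample.int(n_lab)
    if (lam > 0) perm_u <- sample.int(n_unl)
    steps <- ceiling(n_lab / batch)
    ls_acc <- lr_acc <- mix_acc <- 0
    for (s in seq_len(steps)) {
      idx_l <- perm_l[((s - 1) * batch + 1):min(s * batch, n_lab)]
      xl <- ag_const(sub_batch(Xl, idx_l))
      yl <- Yl[, , idx_l, drop = FALSE]
      if (lam > 0) {
        pos <- ((s - 1) * batch_u) %% n_unl
        idx_u <- perm_u[(pos + seq_len(batch_u) - 1L) %% n_unl + 1L]
        xu <- ag_const(sub_batch(Xu, idx_u))
        r_out <- recon_fwd(state$r, xu, training = TRUE,
                           dropout = config$recon$dropout)
        rec <- r_out$reconstruction
        logit_gen <- disc_fwd(state$d, rec, training = FALSE)
        loss_r <- ag_axpy(ag_mse(rec, xu$value),
                          ag_softmax_ce(logit_gen, real_label(length(idx_u))),
                          config$recon$adv_weight)
        mid_l <- encoder_fwd(state$r$encoder, xl, training = TRUE)$bottleneck
        enc_s <- encoder_fwd(state$s$encoder, xl, training = TRUE)
        fused <- transfer_fwd(state$t, mid_l, enc_s$bottleneck,
                              training = TRUE)
        seg_out <- seg_fwd(state$s, xl, training = TRUE,
                           dropout = config$seg$dropout,
                           fused_bottleneck = fused, enc_out = enc_s)
        loss_s <- ag_dice_loss(ag_slice_ch(seg_out$probs, fg), yl, smooth = 1)
        loss_mix <- ag_axpy(loss_s, loss_r, lam)
        ag_backward(loss_mix)
        adam_step(opt_st)
        if (!config$freeze_recon) adam_step(opt_r)
        ag_zero_grads(c(params_s, params_t, params_r, params_d))
        # discriminator step: one forward over [real; reconstruction-detached]
        both <- ag_const(array(c(xu$value, rec$value),
                               dim(xu$value) + c(0, 0, 0, length(idx_u))))
        logit_both <- disc_fwd(state$d, both, training = TRUE)
        loss_d <- ag_scale(ag_softmax_ce(logit_both,
                                         c(real_label(length(idx_u)),
                                           fake_label(length(idx_u)))), 2)
        ag_backward(loss_d)
        adam_step(opt_d)
        ag_zero_grads(params_d)
        lr_val <- loss_r$value
        mix_val <- loss_mix$value
      } else {
        seg_out <- seg_fwd(state$s, xl, training = TRUE,
                           dropout = config$seg$dropout)
        loss_s <- ag_dice_loss(ag_slice_ch(seg_out$probs, fg), yl, smooth = 1)
        ag_backward(loss_s)
        adam_step(opt_st)
        ag_zero_grads(c(params_s, params_t))
        lr_val <- NA_real_
        mix_val <- loss_s$value
      }
      ls_acc <- ls_acc + loss_s$value
      lr_acc <- lr_acc + (if (is.na(lr_val)) 0 else lr_val)
      mix_acc <- mix_acc + mix_val
    }
    val <- validation_scores(state, split$validation, config)
    history <- rbind(history, data.frame(
      epoch = ep, loss_s = ls_acc / steps,
      loss_r = if (lam > 0) lr_acc / steps else NA_real_,
      loss_mix = mix_acc / steps, val_dc = val$dc,
      val_loss_s = val$loss_s, val_loss_mix = val$loss_mix))
    val_dc <- val$dc
    state$step <- state$step + steps
    if (!is.na(val_dc)) {
      if (val_dc > best_dc) {
        best_dc <- val_dc
        best_epoch <- ep
        best_snap <- snapshot_values(state)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop$patience) break
      }
    } else {
      best_epoch <- ep   # no validation set: keep the final epoch
    }
  }
  if (!is.null(best_snap)) restore_values(state, best_snap)
  list(state = state,
       history = history %||% data.frame(epoch = integer(), loss_s = numeric(),
                                         loss_r = numeric(),
                                         loss_mix = numeric(),
                                         val_dc = numeric(),
                                         val_loss_s = numeric(),
                                         val_loss_mix = numeric()),
       best_epoch = best_epoch,
       best_val_dc = if (is.finite(best_dc)) best_dc else NA_real_)
}


# Eval-mode validation scores: hard-mask Dice (the early-stopping monitor)
# plus the soft losses behind verification curves. Consumes no RNG.
validation_scores <- function(state, records, config) {
  if (length(records) == 0) {
    return(list(dc = NA_real_, loss_s = NA_real_, loss_mix = NA_real_))
  }
  cfg <- state$config
  fg <- fg_channel(cfg)
  lam <- config$lam
  dcs <- numeric(length(records))
  ls <- numeric(length(records))
  lr_terms <- 0
  pos <- 0L
  for (start in seq(1, length(records), by = 8L)) {
    recs <- records[start:min(start + 7L, length(records))]
    x <- ag_const(records_batch(recs, cfg))
    enc_s <- encoder_fwd(state$s$encoder, x, training = FALSE)
    fused <- NULL
    if (isTRUE(state$use_fusion)) {
      mid <- encoder_fwd(state$r$encoder, x, training = FALSE)$bottleneck
      fused <- transfer_fwd(state$t, mid, enc_s$bottleneck, training = FALSE)
    }
    probs <- seg_fwd(state$s, x, training = FALSE, fused_bottleneck = fused,
                     enc_out = enc_s)$probs$value
    if (lam > 0) {
      r_out <- recon_fwd(state$r, x, training = FALSE)
      logit <- disc_fwd(state$d, r_out$reconstruction, training = FALSE)
      ce <- ag_softmax_ce(logit, real_label(length(recs)))$value
      mse <- mean((r_out$reconstruction$value - x$value)^2)
      lr_terms <- lr_terms + (mse + config$recon$adv_weight * ce) * length(recs)
    }
    for (n in seq_along(recs)) {
      pos <- pos + 1L
      p <- probs[, , , n]
      bg_max <- apply(p[, , -fg, drop = FALSE], c(1, 2), max)
      hard <- (p[, , fg] > bg_max) * 1
      dcs[pos] <- as.numeric(dice_coefficient(hard, recs[[n]]$mask))
      ls[pos] <- soft_dice_loss(p[, , fg], recs[[n]]$mask, smooth = 1)
    }
  }
  loss_s <- mean(ls)
  loss_r <- if (lam > 0) lr_terms / length(records) else 0
  list(dc = mean(dcs), loss_s = loss_s, loss_mix = loss_s + lam * loss_r)
}

#' Predict binary lesion masks
#'
#' Eval-mode forward pass; when the state was trained with fusion
#' (`lam > 0`) the reconstructor's encoder and the transfer block are applied
#' exactly as during training. Foreground is the argmax class (ties go to
#' background). Deterministic.
#'
#' @param state a trained `model_state`.
#' @param records list of `sample_record`s (masks not required).
#' @param chunk mini-batch size used for the forward passes.
#' @return Named list (by case id) of H x W 0/1 matrices.
#' @export
predict_masks <- function(state, records, chunk = 8L) {
  stopifnot(inherits(state, "model_state"))
  cfg <- state$config
  fg <- fg_channel(cfg)
  out <- list()
  for (start in seq(1, length(records), by = chunk)) {
    recs <- records[start:min(start + chunk - 1L, length(records))]
    x <- ag_const(records_batch(recs, cfg))
    enc_s <- encoder_fwd(state$s$encoder, x, training = FALSE)
    fused <- NULL
    if (isTRUE(state$use_fusion)) {
      mid <- encoder_fwd(state$r$encoder, x, training = FALSE)$bottleneck
      fused <- transfer_fwd(state$t, mid, enc_s$bottleneck, training = FALSE)
    }
    probs <- seg_fwd(state$s, x, training = FALSE, fused_bottleneck = fused,
                     enc_out = enc_s)$probs$value
    for (n in seq_along(recs)) {
      p <- probs[, , , n]
      bg_max <- apply(p[, , -fg, drop = FALSE], c(1, 2), max)
      out[[recs[[n]]$case_id]] <- (p[, , fg] > bg_max) * 1
    }
  }
  out
}

#' Write a training history to CSV
#'
#' @param history data.frame as returned in `$history` by the trainers.
#' @param path output path.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
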