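# Experiment runners: label-fraction ablation, lambda sweep, and the
# standard desk-scale phantom benchmark they run on.

#' Generate the standard phantom benchmark datasets
#'
#' Training and held-out test phantom cohorts with the study geometry:
#' 64 x 64 slices, 6 modality channels, 2 mm isotropic spacing, Gaussian
#' intensity noise. The test cohort uses an independent seed stream.
#'
#' @param n_train,n_test cohort sizes (defaults 200 / 50).
#' @param seed master seed.
#' @param noise_sd intensity noise level.
#' @return List with `train` and `test` record lists and the two configs.
#' @export
phantom_benchmark <- function(n_train = 200, n_test = 50, seed = 1,
                              noise_sd = 0.05) {
  cfg_train <- phantom_config(n_cases = n_train, seed = derive_seed(seed, "train"))
  cfg_test <- phantom_config(n_cases = n_test, seed = derive_seed(seed, "test"))
  cfg_train$noise_sd <- noise_sd
  cfg_test$noise_sd <- noise_sd
  list(train = generate_dataset(cfg_train), test = generate_dataset(cfg_test),
       config_train = cfg_train, config_test = cfg_test)
}

fit_split <- function(split, config) {
  pre <- NULL
  state <- NULL
  if (config$lam > 0 && config$recon$epochs > 0) {
    pre <- pretrain_reconstruction(split$pseudo_unlabeled, config)
    state <- pre$state
  }
  fit <- train_cooptimized(split, config, state = state)
  fit$pretrain_history <- pre$history
  fit
}

#' Label-fraction ablation on held-out phantoms
#'
#' Trains one co-optimized model per label fraction (fraction 1.0 is the
#' fully supervised analogue of the semi-supervised family) on the same
#' training pool, evaluates each on the test records and tabulates mean and
#' sd of Dice, ASSD and Hausdorff distance — the layout of the published
#' fraction ablation.
#'
#' @param train_records training pool (`sample_record`s with masks).
#' @param test_records held-out records with masks.
#' @param fractions label fractions to evaluate.
#' @param config a [train_config()].
#' @param keep_states return the trained states (memory-heavy).
#' @return List with `table` (one row per fraction), `reports` and
#'   `histories` (per fraction), and optionally `states`.
#' @export
run_label_fraction_experiment <- function(train_records, test_records,
                                          fractions = c(0.1, 0.2, 0.5, 0.8, 1.0),
                                          config = train_config(),
                                          keep_states = FALSE) {
  stopifnot(length(test_records) >= 1)
  truths <- stats::setNames(lapply(test_records, function(r) r$mask),
                            vapply(test_records, function(r) r$case_id,
                                   character(1)))
  spacing <- test_records[[1]]$spacing_mm
  rows <- list()
  reports <- list()
  histories <- list()
  states <- list()
  for (f in fractions) {
    split <- split_dataset(train_records, f, config$validation_split,
                           seed = config$seed)
    fit <- fit_split(split, config)
    preds <- predict_masks(fit$state, test_records)
    rep <- evaluate_cases(preds, truths, spacing)
    s <- rep$summary
    key <- sprintf("%g", f)
    rows[[key]] <- data.frame(
      fraction = f, n_labeled = length(split$labeled) + length(split$validation),
      dc_mean = s$mean[1], dc_sd = s$sd[1],
      assd_mean = s$mean[3], assd_sd = s$sd[3],
      hd_mean = s$mean[2], hd_sd = s$sd[2],
      best_epoch = fit$best_epoch)
    reports[[key]] <- rep
    histories[[key]] <- fit$history
    if (keep_states) states[[key]] <- fit$state
  }
  out <- list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              reports = reports, histories = histories)
  if (keep_states) out$states <- states
  out
}

#' Sweep the reconstruction-loss weight lambda
#'
#' Trains on identical data, split and seeds for every lambda in the grid
#' (the reconstruction branch is pretrained once and every lambda > 0 run
#' starts from a copy of it), and returns the per-epoch mixed-loss
#' histories — the data behind training/validation loss-curve comparisons —
#' plus the final validation Dice per lambda.
#'
#' @param train_records training pool.
#' @param lams lambda grid (default the published 0.0 ... 1.0 grid).
#' @param label_fraction fraction of labels to use (default 0.8).
#' @param config a [train_config()].
#' @return List with `histories` (named by lambda) and `table`
#'   (lambda, best validation Dice, best epoch).
#' @export
run_lambda_sweep <- function(train_records,
                             lams = c(0.0, 0.2, 0.4, 0.6, 0.8, 1.0),
                             label_fraction = 0.8,
                             config = train_config()) {
  split <- split_dataset(train_records, label_fraction,
                         config$validation_split, seed = config$seed)
  pre <- NULL
  if (any(lams > 0) && config$recon$epochs > 0) {
    pre <- pretrain_reconstruction(split$pseudo_unlabeled, config)
    pre_snap <- snapshot_values(pre$state)
    net_cfg <- pre$state$config
  }
  histories <- list()
  rows <- list()
  for (lam in lams) {
    cfg <- config
    cfg$lam <- lam
    state <- NULL
    if (lam > 0 && !is.null(pre)) {
      state <- new_model_state(net_cfg, seed = derive_seed(config$seed, "init"))
      restore_values(state, pre_snap)
    }
    fit <- train_cooptimized(split, cfg, state = state)
    key <- sprintf("%g", lam)
    histories[[key]] <- fit$history
    rows[[key]] <- data.frame(lam = lam, best_val_dc = fit$best_val_dc,
                              best_epoch = fit$best_epoch)
  }
  list(histories = histories,
       table = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Plot mixed-loss curves from a lambda sweep
#'
#' @param sweep result of [run_lambda_sweep()].
#' @param metric history column to plot (default `loss_mix`).
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_lambda_curves <- function(sweep, metric = "loss_mix") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_lambda_curves requires the ggplot2 package")
  }
  df <- do.call(rbind, lapply(names(sweep$histories), function(k) {
    h <- sweep$histories[[k]]
    data.frame(lambda = k, epoch = h$epoch, value = h[[metric]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$lambda)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = metric, colour = "lambda")
}

#' Run the desk-scale benchmark for one seed
#'
#' Generates the standard phantom benchmark (200 training / 50 test slices,
#' 64 x 64, 6 channels, 2 mm spacing), then trains the co-optimized model
#' (lambda = 0.2) at the requested label fractions plus, optionally, the
#' purely supervised run (lambda = 0) at 20% labels, and evaluates every
#' model on the held-out test phantoms.
#'
#' @param seed seed controlling data generation, splits, initialisation and
#'   shuffling for this replicate.
#' @param fractions label fractions for the co-optimized runs.
#' @param include_supervised also run the lambda = 0 baseline at 20% labels.
#' @param n_train,n_test cohort sizes.
#' @return data.frame with one row per run: seed, lam, fraction, mean/sd test
#'   Dice, mean ASSD and HD (mm), best epoch.
#' @export
run_benchmark_suite <- function(seed = 1, fractions = c(0.1, 0.2, 0.5, 1.0),
                                include_supervised = TRUE,
                                n_train = 200, n_test = 50) {
  bench <- phantom_benchmark(n_train = n_train, n_test = n_test, seed = seed)
  truths <- stats::setNames(lapply(bench$test, function(r) r$mask),
                            vapply(bench$test, function(r) r$case_id,
                                   character(1)))
  spacing <- bench$test[[1]]$spacing_mm
  eval_fit <- function(fit, lam, fraction) {
    preds <- predict_masks(fit$state, bench$test)
    s <- evaluate_cases(preds, truths, spacing)$summary
    data.frame(seed = seed, lam = lam, fraction = fraction,
               dc_mean = s$mean[1], dc_sd = s$sd[1],
               hd_mean = s$mean[2], assd_mean = s$mean[3],
               best_epoch = fit$best_epoch)
  }
  rows <- list()
  for (f in fractions) {
    cfg <- desk_train_config(seed = seed, lam = 0.2)
    split <- split_dataset(bench$train, f, cfg$validation_split,
                           seed = cfg$seed)
    fit <- fit_split(split, cfg)
    rows[[sprintf("semi_%g", f)]] <- eval_fit(fit, 0.2, f)
  }
  if (include_supervised) {
    cfg0 <- desk_train_config(seed = seed, lam = 0)
    split0 <- split_dataset(bench$train, 0.2, cfg0$validation_split,
                            seed = cfg0$seed)
    fit0 <- fit_split(split0, cfg0)
    rows[["supervised_0.2"]] <- eval_fit(fit0, 0, 0.2)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
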