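test_that("reconstruction pretraining reduces MSE and is reproducible", {
  ds <- tiny_dataset(n_cases = 10)
  for (seed in 1:3) {
    cfg <- tiny_train_config(seed = seed, recon_epochs = 12)
    out <- pretrain_reconstruction(ds, cfg)
    expect_lt(tail(out$history$loss_mse, 1), out$history$loss_mse[1])
  }
  cfg <- tiny_train_config(seed = 5, recon_epochs = 3)
  h1 <- pretrain_reconstruction(ds, cfg)$history
  h2 <- pretrain_reconstruction(ds, cfg)$history
  expect_identical(h1, h2)
})

test_that("zero pretraining epochs returns an initialised state and no history", {
  ds <- tiny_dataset(n_cases = 4)
  cfg <- tiny_train_config(recon_epochs = 0)
  out <- pretrain_reconstruction(ds, cfg)
  expect_s3_class(out$state, "model_state")
  expect_equal(nrow(out$history), 0)
})

test_that("batches larger than the dataset are reduced with a warning", {
  ds <- tiny_dataset(n_cases = 2)
  cfg <- tiny_train_config(recon_epochs = 1)
  expect_warning(pretrain_reconstruction(ds, cfg), "reducing")
})

test_that("joint training is deterministic under a fixed seed", {
  ds <- tiny_dataset(n_cases = 12)
  cfg <- tiny_train_config(seed = 3, lam = 0.2, seg_epochs = 2,
                           recon_epochs = 1)
  sp <- split_dataset(ds, 0.5, cfg$validation_split, seed = cfg$seed)
  run <- function() {
    pre <- pretrain_reconstruction(sp$pseudo_unlabeled, cfg)
    train_cooptimized(sp, cfg, state = pre$state)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  p1 <- predict_masks(f1$state, ds[1:3])
  p2 <- predict_masks(f2$state, ds[1:3])
  expect_identical(p1, p2)
})

test_that("lambda zero fully decouples the reconstruction branch", {
  ds <- tiny_dataset(n_cases = 12)
  cfg <- tiny_train_config(seed = 4, lam = 0, seg_epochs = 2)
  sp <- split_dataset(ds, 0.5, cfg$validation_split, seed = cfg$seed)
  st <- new_model_state(coseg:::net_config_for(sp$labeled, cfg),
                        seed = coseg:::derive_seed(cfg$seed, "init"))
  r_before <- coseg:::state_values(st$r)
  t_before <- coseg:::state_values(st$t)
  fit <- train_cooptimized(sp, cfg, state = st)
  expect_identical(coseg:::state_values(fit$state$r), r_before)
  expect_identical(coseg:::state_values(fit$state$t), t_before)
  expect_false(isTRUE(fit$state$use_fusion))
  expect_true(all(is.na(fit$history$loss_r)))
  expect_equal(fit$history$loss_mix, fit$history$loss_s)
})

test_that("the returned checkpoint is the best validation epoch", {
  ds <- tiny_dataset(n_cases = 12)
  cfg <- tiny_train_config(seed = 6, lam = 0.2, seg_epochs = 4,
                           recon_epochs = 1)
  sp <- split_dataset(ds, 0.5, cfg$validation_split, seed = cfg$seed)
  fit <- train_cooptimized(sp, cfg,
                           state = pretrain_reconstruction(
                             sp$pseudo_unlabeled, cfg)$state)
  expect_equal(fit$best_val_dc, max(fit$history$val_dc))
  expect_equal(fit$best_epoch,
               which(fit$history$val_dc == fit$best_val_dc)[1])
  expect_gte(fit$best_val_dc, fit$history$val_dc[1])
  # re-evaluating the returned state reproduces the recorded best Dice
  preds <- predict_masks(fit$state, sp$validation)
  dcs <- vapply(sp$validation, function(r) {
    as.numeric(dice_coefficient(preds[[r$case_id]], r$mask))
  }, numeric(1))
  expect_equal(mean(dcs), fit$best_val_dc, tolerance = 1e-6)
})

test_that("prediction is deterministic with binary H x W output", {
  ds <- tiny_dataset(n_cases = 6)
  cfg <- tiny_train_config(seed = 2, lam = 0, seg_epochs = 1)
  sp <- split_dataset(ds, 1.0, 0.25, seed = 1)
  fit <- train_cooptimized(sp, cfg)
  p1 <- predict_masks(fit$state, ds[1:2])
  p2 <- predict_masks(fit$state, ds[1:2])
  expect_identical(p1, p2)
  expect_equal(dim(p1[[1]]), c(32, 32))
  expect_true(all(p1[[1]] %in% c(0, 1)))
})

test_that("training without labeled records is rejected", {
  ds <- tiny_dataset(n_cases = 6)
  sp <- split_dataset(ds, 1.0, 0, seed = 1)
  sp$labeled <- list()
  expect_error(train_cooptimized(sp, tiny_train_config()), "labeled")
})

test_that("lambda sweep shares data and reduces to supervised at zero", {
  ds <- tiny_dataset(n_cases = 12)
  cfg <- tiny_train_config(seed = 9, seg_epochs = 2, recon_epochs = 1)
  sweep <- run_lambda_sweep(ds, lams = c(0, 0.2, 0.4, 0.6, 0.8, 1.0),
                            label_fraction = 0.8, config = cfg)
  expect_length(sweep$histories, 6)
  expect_equal(nrow(sweep$table), 6)
  h0 <- sweep$histories[["0"]]
  # lambda = 0 curve is exactly the supervised segmentation loss curve,
  # for the training stream and the verification stream alike
  expect_equal(h0$loss_mix, h0$loss_s)
  expect_equal(h0$val_loss_mix, h0$val_loss_s)
  expect_true(all(is.finite(h0$val_loss_s)))
  sup <- train_cooptimized(split_dataset(ds, 0.8, cfg$validation_split,
                                         seed = cfg$seed),
                           { c0 <- cfg; c0$lam <- 0; c0 })
  expect_equal(h0$loss_s, sup$history$loss_s)
})

test_that("label-fraction runner tabulates one row per fraction", {
  ds <- tiny_dataset(n_cases = 12)
  test_ds <- tiny_dataset(n_cases = 4, seed = 99)
  cfg <- tiny_train_config(seed = 1, seg_epochs = 1, recon_epochs = 1)
  out <- run_label_fraction_experiment(ds, test_ds, fractions = c(1.0),
                                       config = cfg)
  expect_equal(nrow(out$table), 1)
  out2 <- run_label_fraction_experiment(ds, test_ds,
                                        fractions = c(0.5, 1.0),
                                        config = cfg)
  expect_equal(nrow(out2$table), 2)
  expect_true(all(c("dc_mean", "assd_mean", "hd_mean") %in%
                    colnames(out2$table)))
})
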