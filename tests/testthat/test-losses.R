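test_that("soft dice loss matches hand-evaluated cases", {
  t1 <- matrix(c(1, 0, 0, 0), 2, 2)
  p_half <- matrix(c(0.5, 0, 0, 0), 2, 2)
  # 1 - (2 * 0.5) / (0.5 + 1) = 1/3, independently: elementwise sums
  num <- 2 * sum(p_half * t1)
  den <- sum(p_half) + sum(t1)
  expect_equal(soft_dice_loss(p_half, t1, smooth = 0), 1 - num / den)
  expect_equal(soft_dice_loss(p_half, t1, smooth = 0), 1 / 3)
  expect_equal(soft_dice_loss(t1, t1, smooth = 0), 0)
  disj <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_equal(soft_dice_loss(t1, disj, smooth = 0), 1)
  expect_message(
    z <- soft_dice_loss(matrix(0, 2, 2), matrix(0, 2, 2), smooth = 0),
    "convention")
  expect_equal(z, 0)
  expect_error(soft_dice_loss(t1 * 2, t1), "probabilities")
})

test_that("soft dice on hard masks equals 1 - dice_coefficient", {
  set.seed(21)
  for (k in 1:20) {
    a <- random_blob_mask(16, 16)
    b <- random_blob_mask(16, 16)
    expect_equal(soft_dice_loss(a, b, smooth = 0),
                 1 - dice_coefficient(a, b), tolerance = 1e-12)
  }
})

test_that("reconstruction loss components match hand computation", {
  x <- array(0.25, c(2, 2, 2))
  r <- x + 0.5                      # constant difference 0.5 -> MSE 0.25
  conf <- matrix(c(0.2, 0.8), 1, 2)  # (P(fake), P(real))
  out <- reconstruction_loss(x, r, d_on_fake = conf, d_on_real = conf,
                             adv_weight = 1)
  expect_equal(out$mse, 0.25)
  expect_equal(out$generator_side, 0.25 - log(0.8))
  expect_equal(out$discriminator_side, -log(0.8) - log(0.2))
  # r_out identical to x: MSE term vanishes
  out2 <- reconstruction_loss(x, x, conf, conf)
  expect_equal(out2$mse, 0)
  # certain-fake verdict with the real label: clamped log keeps it finite
  certain <- matrix(c(1, 0), 1, 2)
  out3 <- reconstruction_loss(x, r, certain, conf)
  expect_true(is.finite(out3$generator_side))
  expect_equal(out3$generator_side, 0.25 - log(1e-7))
  # malformed probability pairs are rejected
  expect_error(reconstruction_loss(x, r, matrix(c(0.7, 0.7), 1, 2), conf),
               "sum to 1")
})

test_that("mix loss is linear and reduces to loss_s at lambda zero", {
  expect_equal(mix_loss(0.3, 0.2, 1.0), 0.5)
  set.seed(22)
  for (k in 1:1000) {
    ls <- runif(1, 0, 2)
    lr <- runif(1, 0, 5)
    expect_identical(mix_loss(ls, lr, 0), ls)
  }
  # monotone nondecreasing in loss_r for positive lambda
  for (k in 1:200) {
    ls <- runif(1); lam <- runif(1, 0.01, 1)
    r1 <- runif(1, 0, 3); r2 <- r1 + runif(1, 0, 3)
    expect_gte(mix_loss(ls, r2, lam), mix_loss(ls, r1, lam))
  }
})
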