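test_that("residual blocks satisfy their shape contracts", {
  set.seed(31)
  blk <- res_block_params(16, 16, stride = 1, fusion = "concat")
  f <- array(rnorm(16 * 32 * 32), c(16, 32, 32))
  out <- residual_block(f, blk)
  expect_equal(dim(out), c(16, 32, 32))
  blk2 <- res_block_params(16, 32, stride = 2, fusion = "concat")
  out2 <- residual_block(f, blk2)
  expect_equal(dim(out2), c(32, 16, 16))
  expect_error(residual_block(array(0, c(8, 32, 32)), blk), "channels")
})

test_that("zero-weight residual block with add fusion is the identity", {
  set.seed(32)
  blk <- zero_conv_weights(res_block_params(8, 8, stride = 1, fusion = "add"))
  f <- array(rnorm(8 * 16 * 16), c(8, 16, 16))
  expect_equal(residual_block(f, blk), f, tolerance = 1e-12)
  expect_equal(residual_block(f, blk, training = TRUE), f, tolerance = 1e-12)
})

test_that("segmenter emits a valid categorical distribution at every pixel", {
  set.seed(33)
  for (k in 1:10) {
    st <- new_model_state(tiny_net_config(), seed = k)
    x <- array(rnorm(3 * 32 * 32), c(3, 32, 32))
    p <- forward_segmenter(st, x)
    expect_equal(dim(p), c(2, 32, 32))
    expect_true(all(p >= 0))
    expect_lt(max(abs(p[1, , ] + p[2, , ] - 1)), 1e-5)
  }
  # batches preserve order
  st <- new_model_state(tiny_net_config(), seed = 1)
  xs <- lapply(1:3, function(i) array(rnorm(3 * 32 * 32), c(3, 32, 32)))
  pb <- forward_segmenter(st, xs)
  expect_length(pb, 3)
  expect_equal(pb[[2]], forward_segmenter(st, xs[[2]]), tolerance = 1e-12)
})

test_that("reconstructor output stays in (-1, 1) with the right bottleneck dims", {
  set.seed(34)
  st <- new_model_state(tiny_net_config(), seed = 2)
  x <- array(rnorm(3 * 32 * 32, sd = 3), c(3, 32, 32))
  out <- forward_reconstructor(st, x)
  expect_equal(dim(out$reconstruction), c(3, 32, 32))
  expect_true(all(abs(out$reconstruction) < 1))
  # 3 downsampling stages: 32 / 2^3 = 4
  expect_equal(dim(out$middle_feature), c(16, 4, 4))
  # eval-mode forward is deterministic
  out2 <- forward_reconstructor(st, x)
  expect_identical(out$reconstruction, out2$reconstruction)
})

test_that("discriminator returns probability pairs summing to one", {
  set.seed(35)
  st <- new_model_state(tiny_net_config(), seed = 3)
  xs <- lapply(1:3, function(i) array(rnorm(3 * 32 * 32), c(3, 32, 32)))
  p <- forward_discriminator(st, xs)
  expect_equal(dim(p), c(3, 2))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(rowSums(p) - 1)), 1e-5)
})

test_that("transfer fusion is additive with the expected degenerate forms", {
  set.seed(36)
  st <- new_model_state(tiny_net_config(), seed = 4)
  a <- array(abs(rnorm(16 * 4 * 4)), c(16, 4, 4))
  b <- array(rnorm(16 * 4 * 4), c(16, 4, 4))
  # zeroed T: fused equals S's bottleneck exactly
  st$t$conv$w$value[] <- 0
  st$t$conv$b$value[] <- 0
  expect_identical(transfer_fuse(a, b, st$t), b)
  # identity T (1x1 identity kernel, BN neutralised): fused = a + b
  for (c in 1:16) st$t$conv$w$value[1, 1, c, c] <- 1
  st$t$bn$gamma$value[] <- sqrt(1 + 1e-5)   # cancel the unit-variance BN scale
  expect_equal(transfer_fuse(a, b, st$t), a + b, tolerance = 1e-9)
  expect_error(transfer_fuse(array(0, c(16, 8, 8)), b, st$t), "spatial dims")
})

test_that("convolution distributes over feature-map addition", {
  set.seed(37)
  f1 <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  f2 <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  K <- array(rnorm(3 * 3 * 3 * 2), c(3, 3, 3, 2))
  conv_pkg <- function(f) {
    w <- coseg:::ag_param(K)
    b <- coseg:::ag_param(numeric(2))
    x <- coseg:::ag_const(coseg:::feature_to_batch(f))
    coseg:::batch_to_feature(coseg:::ag_conv2d(x, w, b, pad = 1L)$value)
  }
  lhs <- conv_pkg(f1 + f2)
  rhs <- conv_pkg(f1) + conv_pkg(f2)
  expect_lt(max(abs(lhs - rhs)), 1e-5)
  # and the package convolution agrees with a brute-force oracle
  expect_lt(max(abs(conv_pkg(f1) - oracle_conv(f1, K))), 1e-5)
})

test_that("checkpoints reproduce forward outputs exactly", {
  set.seed(38)
  st <- new_model_state(tiny_net_config(), seed = 5)
  x <- array(rnorm(3 * 32 * 32), c(3, 32, 32))
  p1 <- forward_segmenter(st, x)
  r1 <- forward_reconstructor(st, x)$reconstruction
  path <- withr::local_tempfile(fileext = ".rds")
  save_model_state(st, path)
  st2 <- load_model_state(path)
  expect_identical(forward_segmenter(st2, x), p1)
  expect_identical(forward_reconstructor(st2, x)$reconstruction, r1)
})

test_that("R and S encoders share architecture but not initial weights", {
  st <- new_model_state(tiny_net_config(), seed = 6)
  pr <- coseg:::collect_params(st$r$encoder)
  ps <- coseg:::collect_params(st$s$encoder)
  expect_equal(length(pr), length(ps))
  shapes <- function(ps) lapply(ps, function(p) dim(p$value) %||% length(p$value))
  `%||%` <- coseg:::`%||%`
  expect_equal(shapes(pr), shapes(ps))
  same <- mapply(function(a, b) identical(a$value, b$value), pr, ps)
  # BN parameters initialise identically (constants); conv weights must not
  conv_idx <- which(vapply(pr, function(p) length(dim(p$value)) == 4,
                           logical(1)))
  expect_false(any(same[conv_idx]))
})

test_that("indivisible input sizes fail with a padding hint", {
  expect_error(network_config(3, height = 60, width = 64, n_stages = 4),
               "pad")
  st <- new_model_state(tiny_net_config(), seed = 7)
  expect_error(forward_segmenter(st, array(0, c(3, 30, 30))), "pad")
})
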