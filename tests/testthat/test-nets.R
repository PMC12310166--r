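test_that("squeeze averages each channel over space", {
  f <- array(0, c(2, 2, 3))
  f[, , 1] <- 7; f[, , 2] <- 0; f[, , 3] <- c(1, 2, 3, 4)
  expect_equal(se_squeeze(f), c(7, 0, 2.5))
  f3 <- array(5, c(2, 2, 2, 2))
  expect_equal(se_squeeze(f3), c(5, 5))
})

test_that("excitation produces coefficients strictly inside (0,1)", {
  spec <- block_spec(4, 4, seed = 2)
  for (s in 1:10) {
    set.seed(s)
    z <- rnorm(4, sd = 3)
    sc <- se_excite(z, spec)
    expect_true(all(sc > 0 & sc < 1))
  }
  # zeroed weights give sigma(0) = 0.5 everywhere
  spec0 <- spec
  for (nm in grep("se", names(spec0$params), value = TRUE))
    spec0$params[[nm]][] <- 0
  expect_equal(se_excite(c(1, 0, -2, 3), spec0), rep(0.5, 4))
  # hand evaluation with tiny fixed weights
  sp1 <- block_spec(2, 2, reduction = 1, seed = 1)
  sp1$params[["blk.se.fc1.W"]] <- matrix(c(1, 0, 0, 1), 2, 2)
  sp1$params[["blk.se.fc1.b"]] <- c(0, 0)
  sp1$params[["blk.se.fc2.W"]] <- matrix(c(0.5, 0, 0, -0.5), 2, 2)
  sp1$params[["blk.se.fc2.b"]] <- c(0.1, 0.1)
  z <- c(1, 0)
  h <- pmax(z, 0)
  want <- 1 / (1 + exp(-(c(0.5 * h[1], -0.5 * h[2]) + 0.1)))
  expect_equal(se_excite(z, sp1), want)
})

test_that("se_apply scales channels and keeps shape", {
  f <- array(rnorm(32), c(4, 4, 2))
  expect_equal(se_apply(f, c(1, 1)), f)
  expect_equal(se_apply(f, c(0, 0)), f * 0)
  half <- se_apply(array(2, c(3, 3, 1)), 0.5)
  expect_equal(half, array(1, c(3, 3, 1)))
  expect_error(se_apply(f, c(1, 2, 3)), "channel")
})

test_that("the multi-residual block preserves spatial shape and is
           differentiable through both paths", {
  spec <- block_spec(1, 4, seed = 5)
  x <- array(rnorm(8 * 8) * 0.3, c(8, 8, 1))
  y <- multi_residual_block(x, spec)
  expect_equal(dim(y), c(8, 8, 4))
  expect_true(all(is.finite(y)) && all(y >= 0))      # ReLU output
  # finite-difference gradient through the block is nonzero
  s0 <- sum(multi_residual_block(x, spec))
  eps <- 1e-4
  nonzero <- 0
  for (i in c(1, 20, 40)) {
    x2 <- x; x2[i] <- x2[i] + eps
    g <- (sum(multi_residual_block(x2, spec)) - s0) / eps
    nonzero <- nonzero + (abs(g) > 1e-6)
  }
  expect_gte(nonzero, 2)
  # zeroing the 3x3 convolutions leaves the identity path alive
  spec_id <- spec
  spec_id$params[["blk.conv1.W"]][] <- 0
  spec_id$params[["blk.conv2.W"]][] <- 0
  y_id <- multi_residual_block(x, spec_id)
  x3 <- x * 2
  y_id2 <- multi_residual_block(x3, spec_id)
  expect_gt(sum(abs(y_id2 - y_id)), 0)
})

test_that("pixel attention gates lie in (0,1) and never amplify the skip", {
  for (s in 1:5) {
    set.seed(s)
    skip <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    gate <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    r <- pixel_attention(skip, gate, seed = s)
    expect_true(all(r$alpha > 0 & r$alpha < 1))
    expect_equal(dim(r$output), dim(skip))
    expect_true(all(abs(r$output) <= abs(skip) + 1e-12))
  }
})

test_that("network builders obey shape, range and determinism contracts", {
  cfg <- net_config(dims = 2, depth = 2, base_filters = 4, seed = 9)
  net <- build_mraunet(cfg)
  x <- array(rnorm(32 * 32), c(32, 32, 1))
  tape <- hepannot:::ag_tape()
  out <- hepannot:::segnet_forward(net, x, tape)$out$val
  expect_equal(dim(out), c(32, 32, 1))
  expect_true(all(out >= 0 & out <= 1))
  # same seed, same weights
  net2 <- build_mraunet(cfg)
  expect_identical(net$params, net2$params)
  # more parameters than the plain U-Net at equal base filters
  expect_gt(n_params(net), n_params(build_unet(cfg)))
  # seresunet output in [0,1]
  snet <- build_seresunet(cfg)
  outs <- hepannot:::segnet_forward(snet, x, hepannot:::ag_tape())$out$val
  expect_true(all(outs >= 0 & outs <= 1))
})

test_that("the 3-D network uses LeakyReLU everywhere but the sigmoid head", {
  cfg <- net_config(dims = 3, depth = 2, base_filters = 2, seed = 3)
  net <- build_unet3d(cfg)
  acts <- net$layers$activation
  conv_acts <- acts[net$layers$type == "conv3x3"]
  expect_true(all(conv_acts == "leakyrelu"))
  expect_equal(acts[net$layers$name == "head"], "sigmoid")
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  out <- hepannot:::segnet_forward(net, x, hepannot:::ag_tape())$out$val
  expect_equal(dim(out), c(8, 8, 8, 1))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("prediction pads and un-pads to the input shape", {
  net <- build_unet(net_config(dims = 2, depth = 2, base_filters = 2,
                               seed = 1))
  v <- volume(array(rnorm(3 * 30 * 30), c(3, 30, 30)))  # not divisible by 4
  p <- predict_segnet(net, v)
  expect_equal(dim(p), c(3, 30, 30))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("training is deterministic and reduces the loss on a toy case", {
  set.seed(2)
  x <- array(rnorm(16 * 16, sd = 0.5), c(16, 16))
  y <- array(0, c(16, 16)); y[5:12, 5:12] <- 1
  x <- x + y
  cfg <- net_config(dims = 2, depth = 2, base_filters = 4, seed = 7)
  tc <- train_config(epochs = 15, seed = 3)
  f1 <- train_segnet(build_unet(cfg), list(list(x = x, y = y)), tc)
  f2 <- train_segnet(build_unet(cfg), list(list(x = x, y = y)), tc)
  expect_identical(f1$history, f2$history)
  expect_lt(tail(f1$history, 1), f1$history[1])
  expect_true(all(is.finite(f1$history)))
})
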