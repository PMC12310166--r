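# Finite-difference verification of the reverse-mode engine: every layer
# type used by the networks, checked against central differences.

fd_check <- function(build, params, n_probe = 3, eps = 1e-6, tol = 1e-4) {
  # build(tape, leaves) must return a scalar node
  tape <- hepannot:::ag_tape()
  leaves <- lapply(names(params), function(nm)
    hepannot:::ag_leaf(tape, params[[nm]], nm))
  names(leaves) <- names(params)
  out <- build(tape, leaves)
  hepannot:::ag_backward(tape, out)
  grads <- hepannot:::ag_named_grads(tape)
  val_at <- function(p) {
    t2 <- hepannot:::ag_tape()
    l2 <- lapply(names(p), function(nm) hepannot:::ag_leaf(t2, p[[nm]], nm))
    names(l2) <- names(p)
    build(t2, l2)$val
  }
  worst <- 0
  for (nm in names(params)) {
    for (probe in seq_len(n_probe)) {
      i <- sample.int(length(params[[nm]]), 1)
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      vp <- val_at(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      vm <- val_at(p2)
      fd <- (vp - vm) / (2 * eps)
      worst <- max(worst, abs(fd - grads[[nm]][i]))
    }
  }
  worst
}

test_that("convolution gradients match finite differences (2-D and 3-D)", {
  set.seed(5)
  w2 <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  p <- list(x = array(rnorm(8 * 8 * 2), c(8, 8, 2)),
            W = matrix(rnorm(18 * 3, 0, 0.3), 18, 3), b = rnorm(3))
  expect_lt(fd_check(function(t, L)
    hepannot:::ag_sum_prod(t, hepannot:::ag_conv(t, L$x, L$W, L$b, 3), w2),
    p), 1e-5)
  w3 <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  p3 <- list(x = array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2)),
             W = matrix(rnorm(54 * 2, 0, 0.2), 54, 2), b = rnorm(2))
  expect_lt(fd_check(function(t, L)
    hepannot:::ag_sum_prod(t, hepannot:::ag_conv(t, L$x, L$W, L$b, 3), w3),
    p3), 1e-5)
})

test_that("transposed convolution and max pooling gradients match finite
           differences", {
  set.seed(6)
  wT <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  p <- list(x = array(rnorm(8 * 8 * 2), c(8, 8, 2)),
            W = matrix(rnorm(2 * 12, 0, 0.3), 2, 12), b = rnorm(3))
  expect_lt(fd_check(function(t, L)
    hepannot:::ag_sum_prod(t, hepannot:::ag_convT(t, L$x, L$W, L$b, 3), wT),
    p), 1e-5)
  wp <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  pm <- list(x = array(rnorm(8 * 8 * 2), c(8, 8, 2)))
  expect_lt(fd_check(function(t, L)
    hepannot:::ag_sum_prod(t, hepannot:::ag_maxpool(t, L$x), wp), pm), 1e-5)
})

test_that("normalization, SE gating and the combined loss backpropagate
           correctly", {
  set.seed(7)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  wbn <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  pbn <- list(x = x, g = rnorm(2) + 1, be = rnorm(2))
  expect_lt(fd_check(function(t, L) {
    st <- new.env()
    hepannot:::ag_sum_prod(t,
      hepannot:::ag_batchnorm(t, L$x, L$g, L$be, st, "bn", TRUE), wbn)
  }, pbn, eps = 1e-5, tol = 1e-3), 1e-3)
  pse <- list(x = x, W1 = matrix(rnorm(4, 0, 0.5), 2, 2), b1 = rnorm(2),
              W2 = matrix(rnorm(4, 0, 0.5), 2, 2), b2 = rnorm(2))
  wse <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  expect_lt(fd_check(function(t, L) {
    z <- hepannot:::ag_global_mean(t, L$x)
    h <- hepannot:::ag_relu(t, hepannot:::ag_dense(t, z, L$W1, L$b1))
    s <- hepannot:::ag_sigmoid(t, hepannot:::ag_dense(t, h, L$W2, L$b2))
    hepannot:::ag_sum_prod(t, hepannot:::ag_scale_channels(t, L$x, s), wse)
  }, pse), 1e-5)
  y <- array(rbinom(128, 1, 0.4), c(8, 8, 2))
  ploss <- list(x = x)
  expect_lt(fd_check(function(t, L)
    hepannot:::ag_combined_loss(t, hepannot:::ag_sigmoid(t, L$x), y),
    ploss), 1e-5)
})

test_that("a full MRAU-Net forward/backward pass matches finite
           differences", {
  set.seed(8)
  cfg <- net_config(dims = 2, depth = 2, base_filters = 4, seed = 3)
  net <- build_mraunet(cfg)
  net$params <- lapply(net$params, function(p) p * 0.3)
  x <- array(rnorm(16 * 16) * 0.5, c(16, 16, 1))
  y <- array(rbinom(256, 1, 0.3), c(16, 16, 1))
  tape <- hepannot:::ag_tape()
  fw <- hepannot:::segnet_forward(net, x, tape)
  loss <- hepannot:::ag_combined_loss(tape, fw$out, y)
  hepannot:::ag_backward(tape, loss)
  g <- hepannot:::ag_named_grads(tape)
  lossfn <- function(params) {
    nt <- net; nt$params <- params
    t2 <- hepannot:::ag_tape()
    f2 <- hepannot:::segnet_forward(nt, x, t2)
    hepannot:::ag_combined_loss(t2, f2$out, y)$val
  }
  eps <- 1e-6
  for (nm in c("enc1.conv1.W", "att1.psi.W", "up2.W", "head.b",
               "bottleneck.w2.W")) {
    i <- sample.int(length(net$params[[nm]]), 1)
    p2 <- net$params
    p2[[nm]][i] <- p2[[nm]][i] + eps; lp <- lossfn(p2)
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; lm <- lossfn(p2)
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - g[[nm]][i]), 1e-4 + 1e-2 * abs(fd))
  }
})
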