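## Network builders: plain U-Net (liver), multi-residual attention U-Net
## (tumor), SE-residual U-Net (2-D partition) and a 3-D U-Net (3-D
## partition), all on the shared autodiff engine.
##
## All builders produce a `hep_segnet`: a named parameter list, an
## introspectable layer table, and a forward pass selected by `arch`.
## Encoder depth is `depth` blocks with 2x max pooling between levels, a
## bottleneck block, and `depth` transposed-convolution decoder blocks;
## input spatial sizes must be divisible by 2^depth.

#' Network configuration
#'
#' @param dims 2 or 3.
#' @param depth number of encoder/decoder levels (default 4).
#' @param base_filters channels at the first level, doubling per level
#'   (default 32).
#' @param in_channels input channels (1 for intensity, 4 for the
#'   coordinate-augmented partition input).
#' @param reduction squeeze-and-excitation bottleneck ratio (default 16,
#'   clamped to the channel count).
#' @param se_position where the SE gate sits in the multi-residual block:
#'   on the second convolution's output before the identity addition
#'   (`"pre_add"`, default) or after the final ReLU (`"post_relu"`).
#' @param seed weight-initialization seed.
#' @export
net_config <- function(dims = 2, depth = 4, base_filters = 32,
                       in_channels = 1, reduction = 16,
                       se_position = c("pre_add", "post_relu"), seed = 1) {
  stopifnot(dims %in% c(2, 3), depth >= 1, base_filters >= 1,
            in_channels >= 1)
  structure(list(dims = dims, depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 in_channels = as.integer(in_channels),
                 reduction = as.integer(reduction),
                 se_position = match.arg(se_position),
                 seed = as.integer(seed)),
            class = "hep_net_config")
}

replace_seed <- function(cfg, seed) { cfg$seed <- as.integer(seed); cfg }

#' Training configuration
#'
#' @param epochs number of passes over the training cases.
#' @param batch_size gradient-averaging batch size (default 4).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed shuffling/augmentation seed.
#' @param loss_weights a [loss_weights()] record.
#' @param augment_flips random in-plane flips during training.
#' @export
train_config <- function(epochs = 50, batch_size = 4, learning_rate = 1e-3,
                         seed = 1, loss_weights = hepannot::loss_weights(),
                         augment_flips = FALSE) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 loss_weights = loss_weights,
                 augment_flips = isTRUE(augment_flips)),
            class = "hep_train_config")
}

## ---- parameter construction ----------------------------------------------

he_init <- function(nrow_, ncol_, fan_in) {
  matrix(stats::rnorm(nrow_ * ncol_, 0, sqrt(2 / fan_in)), nrow_, ncol_)
}

net_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$params <- list()
  env$layers <- data.frame(name = character(), type = character(),
                           activation = character(),
                           stringsAsFactors = FALSE)
  env
}

add_layer <- function(b, name, type, activation = "") {
  b$layers <- rbind(b$layers, data.frame(name = name, type = type,
                                         activation = activation,
                                         stringsAsFactors = FALSE))
}

init_conv <- function(b, name, k, nd, cin, cout, activation = "") {
  fan <- k^nd * cin
  b$params[[paste0(name, ".W")]] <- he_init(fan, cout, fan)
  b$params[[paste0(name, ".b")]] <- numeric(cout)
  add_layer(b, name, sprintf("conv%dx%d", k, k), activation)
}

init_convT <- function(b, name, nd, cin, cout) {
  b$params[[paste0(name, ".W")]] <- he_init(cin, 2^nd * cout, cin)
  b$params[[paste0(name, ".b")]] <- numeric(cout)
  add_layer(b, name, "convT2x2", "")
}

init_dense <- function(b, name, cin, cout, activation = "") {
  b$params[[paste0(name, ".W")]] <- he_init(cin, cout, cin)
  b$params[[paste0(name, ".b")]] <- numeric(cout)
  add_layer(b, name, "dense", activation)
}

init_bn <- function(b, name, c) {
  b$params[[paste0(name, ".gamma")]] <- rep(1, c)
  b$params[[paste0(name, ".beta")]] <- numeric(c)
  add_layer(b, name, "batchnorm", "")
}

se_bottleneck <- function(c, reduction) max(1L, c %/% min(reduction, c))

init_se <- function(b, name, c, reduction) {
  cr <- se_bottleneck(c, reduction)
  init_dense(b, paste0(name, ".fc1"), c, cr, "relu")
  init_dense(b, paste0(name, ".fc2"), cr, c, "sigmoid")
}

init_double_conv <- function(b, name, nd, cin, cout, act = "relu",
                             bn = FALSE) {
  init_conv(b, paste0(name, ".conv1"), 3, nd, cin, cout, act)
  if (bn) init_bn(b, paste0(name, ".bn1"), cout)
  init_conv(b, paste0(name, ".conv2"), 3, nd, cout, cout, act)
  if (bn) init_bn(b, paste0(name, ".bn2"), cout)
}

init_mr_block <- function(b, name, nd, cin, cout, reduction) {
  init_conv(b, paste0(name, ".conv1"), 3, nd, cin, cout, "relu")
  init_conv(b, paste0(name, ".w1"), 1, nd, cin, cout)
  init_conv(b, paste0(name, ".conv2"), 3, nd, cout, cout, "relu")
  init_conv(b, paste0(name, ".w2"), 1, nd, cout, cout)
  init_se(b, paste0(name, ".se"), cout, reduction)
}

init_seres_block <- function(b, name, nd, cin, cout, reduction) {
  init_conv(b, paste0(name, ".conv1"), 3, nd, cin, cout, "relu")
  init_conv(b, paste0(name, ".conv2"), 3, nd, cout, cout, "relu")
  init_conv(b, paste0(name, ".proj"), 1, nd, cin, cout)
  init_se(b, paste0(name, ".se"), cout, reduction)
}

init_attention_gate <- function(b, name, nd, c_skip, c_gate) {
  init_conv(b, paste0(name, ".l1"), 3, nd, c_skip, c_skip, "")
  init_conv(b, paste0(name, ".l2"), 3, nd, c_gate, c_skip, "")
  init_conv(b, paste0(name, ".psi"), 1, nd, c_skip, 1, "sigmoid")
}

build_net_params <- function(arch, cfg) {
  nd <- cfg$dims
  b <- net_builder()
  ch <- cfg$base_filters * 2^(0:cfg$depth)
  bn <- arch == "unet3d"
  act <- if (bn) "leakyrelu" else "relu"
  block_init <- switch(arch,
    unet = , unet3d = function(name, cin, cout)
      init_double_conv(b, name, nd, cin, cout, act, bn),
    mraunet = function(name, cin, cout)
      init_mr_block(b, name, nd, cin, cout, cfg$reduction),
    seresunet = function(name, cin, cout)
      init_seres_block(b, name, nd, cin, cout, cfg$reduction))
  cin <- cfg$in_channels
  for (l in seq_len(cfg$depth)) {
    block_init(sprintf("enc%d", l), cin, ch[l])
    cin <- ch[l]
  }
  block_init("bottleneck", cin, ch[cfg$depth + 1])
  for (l in rev(seq_len(cfg$depth))) {
    cprev <- if (l == cfg$depth) ch[cfg$depth + 1] else ch[l + 1]
    init_convT(b, sprintf("up%d", l), nd, cprev, ch[l])
    if (arch == "mraunet")
      init_attention_gate(b, sprintf("att%d", l), nd, ch[l], ch[l])
    block_init(sprintf("dec%d", l), 2 * ch[l], ch[l])
  }
  init_conv(b, "head", 1, nd, ch[1], 1, "sigmoid")
  b
}

#' Build a segmentation network
#'
#' `build_unet()` is the plain double-convolution U-Net used for liver
#' segmentation; `build_mraunet()` adds multi-residual blocks with
#' squeeze-and-excitation channel attention and pixel-wise attention gates
#' on the skip connections (the tumor network); `build_seresunet()` uses
#' SE-gated residual blocks (2-D partition models); `build_unet3d()` is the
#' 3-D variant with batch normalization and LeakyReLU activations, 3x3x3
#' convolutions, 2x2x2 pooling/transposed convolutions and a final 1x1x1
#' sigmoid head.
#'
#' @param cfg a [net_config()].
#' @return a `hep_segnet`.
#' @export
build_unet <- function(cfg = net_config()) new_segnet("unet", cfg)

#' @rdname build_unet
#' @export
build_mraunet <- function(cfg = net_config()) new_segnet("mraunet", cfg)

#' @rdname build_unet
#' @export
build_seresunet <- function(cfg = net_config()) new_segnet("seresunet", cfg)

#' @rdname build_unet
#' @export
build_unet3d <- function(cfg = net_config(dims = 3)) {
  if (cfg$dims != 3) stopf("build_unet3d requires dims = 3")
  new_segnet("unet3d", cfg)
}

new_segnet <- function(arch, cfg) {
  b <- with_seed(cfg$seed, build_net_params(arch, cfg))
  structure(list(arch = arch, dims = cfg$dims, cfg = cfg,
                 params = b$params, layers = b$layers,
                 state = new.env(parent = emptyenv())),
            class = "hep_segnet")
}

#' Number of trainable parameters of a network
#' @param net a `hep_segnet`.
#' @export
n_params <- function(net) sum(vapply(net$params, length, numeric(1)))

#' @export
print.hep_segnet <- function(x, ...) {
  cat(sprintf("<%s (%d-D): depth %d, base %d, %d parameters>\n",
              x$arch, x$dims, x$cfg$depth, x$cfg$base_filters,
              n_params(x)))
  invisible(x)
}

## ---- forward passes -------------------------------------------------------

# ctx: tape, pn (named leaf nodes), state, training, cfg
fwd_conv <- function(ctx, x, name, k)
  ag_conv(ctx$tape, x, ctx$pn[[paste0(name, ".W")]],
          ctx$pn[[paste0(name, ".b")]], k)

fwd_convT <- function(ctx, x, name, cout)
  ag_convT(ctx$tape, x, ctx$pn[[paste0(name, ".W")]],
           ctx$pn[[paste0(name, ".b")]], cout)

fwd_dense <- function(ctx, x, name)
  ag_dense(ctx$tape, x, ctx$pn[[paste0(name, ".W")]],
           ctx$pn[[paste0(name, ".b")]])

fwd_bn <- function(ctx, x, name)
  ag_batchnorm(ctx$tape, x, ctx$pn[[paste0(name, ".gamma")]],
               ctx$pn[[paste0(name, ".beta")]], ctx$state, name,
               ctx$training)

fwd_se <- function(ctx, x, name) {
  z <- ag_global_mean(ctx$tape, x)
  h <- ag_relu(ctx$tape, fwd_dense(ctx, z, paste0(name, ".fc1")))
  s <- ag_sigmoid(ctx$tape, fwd_dense(ctx, h, paste0(name, ".fc2")))
  ag_scale_channels(ctx$tape, x, s)
}

fwd_double_conv <- function(ctx, x, name, bn = FALSE) {
  act <- if (bn) function(t, v) ag_lrelu(t, v) else ag_relu
  h <- fwd_conv(ctx, x, paste0(name, ".conv1"), 3)
  if (bn) h <- fwd_bn(ctx, h, paste0(name, ".bn1"))
  h <- act(ctx$tape, h)
  h <- fwd_conv(ctx, h, paste0(name, ".conv2"), 3)
  if (bn) h <- fwd_bn(ctx, h, paste0(name, ".bn2"))
  act(ctx$tape, h)
}

# Two chained weighted-identity sub-units; the SE gate sits on the second
# convolution path (default) or after the final ReLU.
fwd_mr_block <- function(ctx, x, name) {
  t <- ctx$tape
  r1 <- ag_relu(t, ag_add(t, fwd_conv(ctx, x, paste0(name, ".conv1"), 3),
                          fwd_conv(ctx, x, paste0(name, ".w1"), 1)))
  c2 <- fwd_conv(ctx, r1, paste0(name, ".conv2"), 3)
  w2 <- fwd_conv(ctx, r1, paste0(name, ".w2"), 1)
  if (ctx$cfg$se_position == "pre_add") {
    y <- ag_relu(t, ag_add(t, fwd_se(ctx, c2, paste0(name, ".se")), w2))
  } else {
    y <- fwd_se(ctx, ag_relu(t, ag_add(t, c2, w2)), paste0(name, ".se"))
  }
  y
}

fwd_seres_block <- function(ctx, x, name) {
  t <- ctx$tape
  h <- ag_relu(t, fwd_conv(ctx, x, paste0(name, ".conv1"), 3))
  h <- fwd_conv(ctx, h, paste0(name, ".conv2"), 3)
  h <- fwd_se(ctx, h, paste0(name, ".se"))
  p <- fwd_conv(ctx, x, paste0(name, ".proj"), 1)
  ag_relu(t, ag_add(t, h, p))
}

# Attention gate: alpha = sigmoid(conv1x1(relu(L1(skip) + L2(gate))));
# output alpha (.) skip.
fwd_attention_gate <- function(ctx, skip, gate, name) {
  t <- ctx$tape
  a <- ag_relu(t, ag_add(t, fwd_conv(ctx, skip, paste0(name, ".l1"), 3),
                         fwd_conv(ctx, gate, paste0(name, ".l2"), 3)))
  alpha <- ag_sigmoid(t, fwd_conv(ctx, a, paste0(name, ".psi"), 1))
  ag_mul_pixel(t, skip, alpha)
}

segnet_forward <- function(net, x, tape, training = FALSE) {
  cfg <- net$cfg
  pn <- lapply(names(net$params), function(nm)
    ag_leaf(tape, net$params[[nm]], nm))
  names(pn) <- names(net$params)
  ctx <- list(tape = tape, pn = pn, state = net$state,
              training = training, cfg = cfg)
  bn <- net$arch == "unet3d"
  block <- switch(net$arch,
    unet = , unet3d = function(v, name) fwd_double_conv(ctx, v, name, bn),
    mraunet = function(v, name) fwd_mr_block(ctx, v, name),
    seresunet = function(v, name) fwd_seres_block(ctx, v, name))
  ch <- cfg$base_filters * 2^(0:cfg$depth)
  cur <- ag_leaf(tape, x)
  input_node <- cur
  enc <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    cur <- block(cur, sprintf("enc%d", l))
    enc[[l]] <- cur
    cur <- ag_maxpool(tape, cur)
  }
  cur <- block(cur, "bottleneck")
  for (l in rev(seq_len(cfg$depth))) {
    up <- fwd_convT(ctx, cur, sprintf("up%d", l), ch[l])
    skip <- enc[[l]]
    if (net$arch == "mraunet")
      skip <- fwd_attention_gate(ctx, skip, up, sprintf("att%d", l))
    cur <- ag_concat_c(tape, skip, up)
    cur <- block(cur, sprintf("dec%d", l))
  }
  out <- ag_sigmoid(tape, fwd_conv(ctx, cur, "head", 1))
  list(out = out, input = input_node, pn = pn)
}

## ---- standalone block operations on plain arrays --------------------------

#' Squeeze: per-channel global average pooling
#'
#' Collapses a feature map (spatial dims x channels, channel last) to one
#' scalar per channel by averaging over all spatial positions.
#'
#' @param f numeric array, channel as the last dimension.
#' @return numeric vector, one value per channel.
#' @export
se_squeeze <- function(f) {
  d <- dim(f)
  colMeans(matrix(f, nrow = prod(d[-length(d)])))
}

#' Specification of an SE / multi-residual block with concrete weights
#'
#' @param in_channels,out_channels channel counts.
#' @param reduction SE bottleneck ratio.
#' @param seed weight seed.
#' @param dims spatial dimensionality (2 or 3).
#' @export
block_spec <- function(in_channels, out_channels, reduction = 16, seed = 1,
                       dims = 2) {
  b <- net_builder()
  with_seed(seed, init_mr_block(b, "blk", dims, in_channels, out_channels,
                                reduction))
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 reduction = reduction, dims = dims, params = b$params),
            class = "hep_block_spec")
}

#' Excitation: two-layer bottleneck with sigmoid gate
#'
#' `s = sigmoid(F2 relu(F1 z))`; every component lies strictly in (0, 1).
#'
#' @param z channel descriptor (output of [se_squeeze()]).
#' @param spec a [block_spec()] (its SE weights are used).
#' @export
se_excite <- function(z, spec) {
  W1 <- spec$params[["blk.se.fc1.W"]]; b1 <- spec$params[["blk.se.fc1.b"]]
  W2 <- spec$params[["blk.se.fc2.W"]]; b2 <- spec$params[["blk.se.fc2.b"]]
  if (length(z) != nrow(W1)) stopf("se_excite: channel mismatch")
  h <- pmax(as.vector(z %*% W1) + b1, 0)
  1 / (1 + exp(-(as.vector(h %*% W2) + b2)))
}

#' Apply channel attention coefficients to a feature map
#'
#' @param f feature map, channel last.
#' @param s attention coefficients, one per channel.
#' @export
se_apply <- function(f, s) {
  d <- dim(f)
  if (length(s) != d[length(d)]) stopf("se_apply: channel mismatch")
  f * rep(s, each = prod(d[-length(d)]))
}

#' Run a multi-residual block forward on a plain array
#'
#' @param x feature map with `spec$in_channels` channels (channel last).
#' @param spec a [block_spec()].
#' @param se_position see [net_config()].
#' @export
multi_residual_block <- function(x, spec, se_position = "pre_add") {
  d <- dim(x)
  if (d[length(d)] != spec$in_channels)
    stopf("multi_residual_block: channel mismatch")
  tape <- ag_tape()
  fake <- list(arch = "mraunet",
               cfg = list(se_position = se_position),
               state = new.env(parent = emptyenv()))
  pn <- lapply(names(spec$params), function(nm)
    ag_leaf(tape, spec$params[[nm]], nm))
  names(pn) <- names(spec$params)
  ctx <- list(tape = tape, pn = pn, state = fake$state, training = FALSE,
              cfg = fake$cfg)
  fwd_mr_block(ctx, ag_leaf(tape, x), "blk")$val
}

#' Pixel-wise attention gate on plain arrays
#'
#' Computes `alpha = sigmoid(conv1x1(relu(L1(skip) + L2(gate))))` and
#' returns `alpha (.) skip` together with the attention field.
#'
#' @param skip,gate feature maps of equal spatial shape (channel last).
#' @param seed weight seed for the two 3x3 transforms and the 1x1 collapse.
#' @return list with `output` and `alpha`.
#' @export
pixel_attention <- function(skip, gate, seed = 1) {
  ds <- dim(skip); dg <- dim(gate)
  nd <- length(ds) - 1L
  if (!identical(ds[seq_len(nd)], dg[seq_len(nd)]))
    stopf("pixel_attention: spatial shape mismatch")
  b <- net_builder()
  with_seed(seed,
            init_attention_gate(b, "att", nd, ds[nd + 1L], dg[nd + 1L]))
  tape <- ag_tape()
  pn <- lapply(names(b$params), function(nm) ag_leaf(tape, b$params[[nm]], nm))
  names(pn) <- names(b$params)
  ctx <- list(tape = tape, pn = pn, state = NULL, training = FALSE)
  sn <- ag_leaf(tape, skip); gn <- ag_leaf(tape, gate)
  a <- ag_relu(tape, ag_add(tape, fwd_conv(ctx, sn, "att.l1", 3),
                            fwd_conv(ctx, gn, "att.l2", 3)))
  alpha <- ag_sigmoid(tape, fwd_conv(ctx, a, "att.psi", 1))
  out <- ag_mul_pixel(tape, sn, alpha)
  list(output = out$val, alpha = alpha$val)
}
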