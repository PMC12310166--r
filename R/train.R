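## Gradient-based training of segmentation networks (Adam on the combined
## Dice + BCE + MCC loss) and the padded/unpadded predictor.

scale_intensity <- function(a) a / 100

# Coerce a training sample (x with or without channel axis) to channel-last.
with_channel <- function(x, nd) {
  d <- dim(x)
  if (length(d) == nd) array(x, c(d, 1)) else x
}

flip_axis <- function(a, ax) {
  idx <- rep(list(quote(expr = )), length(dim(a)))
  idx[[ax]] <- rev(seq_len(dim(a)[ax]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

adam_state <- function() new.env(parent = emptyenv())

adam_step <- function(st, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- (st$t %||% 0) + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- st[[paste0("m.", nm)]] %||% (g * 0)
    v <- st[[paste0("v.", nm)]] %||% (g * 0)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    st[[paste0("m.", nm)]] <- m
    st[[paste0("v.", nm)]] <- v
    mh <- m / (1 - beta1^st$t)
    vh <- v / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  params
}

#' Train a segmentation network
#'
#' Minimizes the combined Dice + BCE + MCC loss with Adam. Each sample is
#' one (input, binary target) pair: a 2-D slice (h, w[, c]) for 2-D
#' networks or a volume (d, h, w[, c]) for the 3-D network. Gradients are
#' averaged over mini-batches; when `tc$augment_flips` is set, random
#' in-plane flips are applied to input and target together. A fixed
#' `tc$seed` makes the loss history reproducible.
#'
#' @param net a `hep_segnet` from one of the builders.
#' @param samples list of `list(x = , y = )` pairs.
#' @param tc a [train_config()].
#' @return list with the trained `net` and the per-epoch mean loss
#'   `history`.
#' @export
train_segnet <- function(net, samples, tc = train_config()) {
  stopifnot(inherits(net, "hep_segnet"), length(samples) >= 1)
  nd <- net$dims
  xs <- lapply(samples, function(s) with_channel(s$x, nd))
  ys <- lapply(samples, function(s) {
    y <- s$y
    if (inherits(y, "hep_mask")) y <- y$data
    array(as.numeric(y != 0), dim(y)[seq_len(nd)])
  })
  for (x in xs) {
    sp <- dim(x)[seq_len(nd)]
    if (any(sp %% 2^net$cfg$depth != 0))
      stopf("input spatial size (%s) not divisible by 2^depth = %d",
            paste(sp, collapse = "x"), 2^net$cfg$depth)
  }
  params <- net$params
  opt <- adam_state()
  history <- numeric(tc$epochs)
  n <- length(xs)
  with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (bstart in seq(1, n, by = tc$batch_size)) {
        bidx <- ord[bstart:min(n, bstart + tc$batch_size - 1)]
        gsum <- NULL
        for (i in bidx) {
          x <- xs[[i]]; y <- ys[[i]]
          if (tc$augment_flips) {
            for (ax in (nd - 1):nd) {        # in-plane axes
              if (stats::runif(1) < 0.5) {
                x <- flip_axis(x, ax)
                y <- flip_axis(array(y, c(dim(y), 1)), ax)
                y <- array(y, dim(y)[seq_len(nd)])
              }
            }
          }
          tape <- ag_tape()
          net_tmp <- net; net_tmp$params <- params
          fw <- segnet_forward(net_tmp, x, tape, training = TRUE)
          prob <- fw$out
          yv <- array(y, dim(prob$val))
          loss <- ag_combined_loss(tape, prob, yv, tc$loss_weights)
          if (!is.finite(loss$val))
            stopf("non-finite loss at epoch %d", epoch)
          ep_loss <- ep_loss + loss$val
          ag_backward(tape, loss)
          g <- ag_named_grads(tape)
          g <- g[names(g) %in% names(params)]
          gsum <- if (is.null(gsum)) g
                  else Map(`+`, gsum, g[names(gsum)])
        }
        gmean <- lapply(gsum, function(g) g / length(bidx))
        params <- adam_step(opt, params, gmean, tc$learning_rate)
      }
      history[epoch] <- ep_loss / n
    }
  })
  net$params <- params
  list(net = net, history = history)
}

#' Wrap a fixed probability map or function as a pseudo-network
#'
#' Oracle stand-ins for trained models: either a mask/probability array
#' returned verbatim, or a function mapping the input volume to a
#' probability map. Used to exercise downstream stages with ground truth
#' injected.
#'
#' @param x a `hep_mask`, probability array, or function(volume) -> array.
#' @param id identifier reported in annotation provenance.
#' @export
oracle_segnet <- function(x, id = "oracle") {
  structure(list(source = x, id = id), class = "hep_oracle_net")
}

#' Predict a per-voxel probability map
#'
#' For 2-D networks the volume is processed slice-by-slice along z; for
#' 3-D networks in one pass. Spatial sizes are zero-padded up to the next
#' multiple of `2^depth` and the output is cropped back, so the result
#' always matches the input shape.
#'
#' @param net a `hep_segnet` or [oracle_segnet()].
#' @param x a `hep_volume`, a 3-D (z, y, x) array, or a 4-D (z, y, x,
#'   channel) array of prepared input channels. Bare volumes/arrays are
#'   scaled by 1/100 to network units; prepared 4-D inputs are used as-is.
#' @param liver optional mask, forwarded to oracle functions.
#' @return probability array of shape (z, y, x), values in `[0, 1]`.
#' @export
predict_segnet <- function(net, x, liver = NULL) {
  if (inherits(net, "hep_oracle_net")) {
    src <- net$source
    out <- if (is.function(src)) src(x, liver) else as_array3d(src)
    return(out * 1)
  }
  stopifnot(inherits(net, "hep_segnet"))
  raw <- if (inherits(x, "hep_volume")) x$data else x
  d <- dim(raw)
  if (length(d) == 3) {
    arr <- array(scale_intensity(raw), c(d, 1))
  } else arr <- raw
  dv <- dim(arr)[1:3]
  m <- 2^net$cfg$depth
  if (net$dims == 2) {
    padv <- c(dv[1], ceiling(dv[2:3] / m) * m)
  } else {
    padv <- ceiling(dv / m) * m
  }
  cch <- dim(arr)[4]
  padded <- array(0, c(padv, cch))
  padded[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3]), ] <- arr
  out <- array(0, padv)
  if (net$dims == 2) {
    for (zi in seq_len(padv[1])) {
      sl <- array(padded[zi, , , ], c(padv[2], padv[3], cch))
      tape <- ag_tape()
      fw <- segnet_forward(net, sl, tape, training = FALSE)
      out[zi, , ] <- fw$out$val
    }
  } else {
    tape <- ag_tape()
    fw <- segnet_forward(net, padded, tape, training = FALSE)
    out <- array(fw$out$val, padv)
  }
  out[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3]), drop = FALSE]
}
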