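## Minimal reverse-mode automatic differentiation on dense arrays.
##
## Feature maps are numeric arrays with the channel as the last dimension:
## (h, w, c) on the 2-D path, (d, h, w, c) on the 3-D path. Convolutions
## are im2col gathers followed by one BLAS matrix multiply; gradients flow
## back through a scatter-add. The engine records a flat tape of nodes and
## replays it in reverse. It is deliberately small: stride-1 same-padded
## convolutions, 2x transposed convolutions, 2x max pooling, channel-wise
## batch normalization, dense layers and the elementwise/scalar ops the
## networks and losses need.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256)
  e$n <- 0L
  e
}

new_node <- function(tape, val, backfn = NULL, name = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val; nd$grad <- NULL; nd$backfn <- backfn; nd$name <- name
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", n))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ag_leaf <- function(tape, val, name = NULL) new_node(tape, val, name = name)

accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

# Run the reverse sweep from `loss` (a scalar node); afterwards every leaf
# reachable from it holds its gradient.
ag_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

ag_named_grads <- function(tape) {
  out <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$name) && !is.null(nd$grad)) out[[nd$name]] <- nd$grad
  }
  out
}

## ---- im2col machinery -----------------------------------------------------

.im2col_cache <- new.env(parent = emptyenv())

pad_array <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x); nd <- length(d) - 1L
  dp <- c(d[seq_len(nd)] + 2L * p, d[nd + 1L])
  out <- array(0, dp)
  if (nd == 2) out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  else out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  out
}

unpad_array <- function(x, p, sp) {
  if (p == 0) return(x)
  nd <- length(sp)
  if (nd == 2) x[(p + 1):(p + sp[1]), (p + 1):(p + sp[2]), , drop = FALSE]
  else x[(p + 1):(p + sp[1]), (p + 1):(p + sp[2]), (p + 1):(p + sp[3]), ,
         drop = FALSE]
}

# Gather-index matrix mapping a padded array to im2col patch columns
# (stride 1). Cached per shape signature.
im2col_idx <- function(sp, C, k, p) {
  key <- paste(c(sp, C, k, p), collapse = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  nd <- length(sp)
  dp <- sp + 2 * p
  strides <- cumprod(c(1, dp))[seq_len(nd)]
  pos <- as.matrix(do.call(expand.grid, lapply(sp, seq_len))) - 1
  base <- 1 + as.vector(pos %*% strides)
  koff <- as.matrix(do.call(expand.grid, rep(list(0:(k - 1)), nd)))
  off_sp <- as.vector(koff %*% strides)
  off <- as.vector(outer(off_sp, (0:(C - 1)) * prod(dp), `+`))
  idx <- outer(base, off, `+`)
  .im2col_cache[[key]] <- idx
  idx
}

## ---- array ops ------------------------------------------------------------

im2col <- function(a, k, p) {
  d <- dim(a); nd <- length(d) - 1L
  ap <- pad_array(a, p)
  idx <- im2col_idx(d[seq_len(nd)], d[nd + 1L], k, p)
  # index with a plain vector: a matrix subscript whose column count equals
  # the array's dimensionality would be read as coordinates
  m <- ap[as.vector(idx)]
  dim(m) <- dim(idx)
  m
}

# Same-padded stride-1 convolution; `Wn` is a ((k^nd * Cin) x Cout) matrix
# node, `bn` a length-Cout vector node. The input gradient is itself a
# convolution: a full correlation of the output gradient with the spatially
# flipped, channel-transposed kernel, so both directions ride on im2col +
# BLAS.
ag_conv <- function(tape, x, Wn, bn, k) {
  xv <- x$val; d <- dim(xv); nd <- length(d) - 1L
  sp <- d[seq_len(nd)]; Cin <- d[nd + 1L]
  p <- (k - 1L) %/% 2L
  cols <- im2col(xv, k, p)
  ym <- cols %*% Wn$val
  Cout <- ncol(ym)
  ym <- ym + rep(bn$val, each = nrow(ym))
  dim(ym) <- c(sp, Cout)
  node <- new_node(tape, ym)
  node$backfn <- function(g) {
    gm <- g
    dim(gm) <- c(prod(sp), Cout)
    accum(Wn, crossprod(cols, gm))
    accum(bn, colSums(gm))
    kd <- k^nd
    Warr <- Wn$val
    dim(Warr) <- c(kd, Cin, Cout)
    Wflip <- aperm(Warr[kd:1, , , drop = FALSE], c(1, 3, 2))
    dim(Wflip) <- c(kd * Cout, Cin)
    dim(g) <- c(sp, Cout)
    dx <- im2col(g, k, p) %*% Wflip
    dim(dx) <- d
    accum(x, dx)
  }
  node
}

# Transposed convolution, kernel 2, stride 2 (non-overlapping upsampling).
# `Wn` is a (Cin x (2^nd * Cout)) matrix node, blocks ordered by offset
# with the first spatial axis fastest.
ag_convT <- function(tape, x, Wn, bn, Cout) {
  xv <- x$val; d <- dim(xv); nd <- length(d) - 1L
  sp <- d[seq_len(nd)]; Cin <- d[nd + 1L]
  xm <- matrix(xv, nrow = prod(sp))
  ym <- xm %*% Wn$val                     # prod(sp) x (2^nd * Cout)
  osp <- 2L * sp
  out <- array(0, c(osp, Cout))
  offs <- as.matrix(do.call(expand.grid, rep(list(0:1), nd)))
  for (q in seq_len(nrow(offs))) {
    blk <- array(ym[, ((q - 1) * Cout + 1):(q * Cout)], c(sp, Cout))
    if (nd == 2)
      out[seq(1, osp[1], 2) + offs[q, 1], seq(1, osp[2], 2) + offs[q, 2], ] <- blk
    else
      out[seq(1, osp[1], 2) + offs[q, 1], seq(1, osp[2], 2) + offs[q, 2],
          seq(1, osp[3], 2) + offs[q, 3], ] <- blk
  }
  out <- out + rep(bn$val, each = prod(osp))
  node <- new_node(tape, out)
  node$backfn <- function(g) {
    accum(bn, colSums(matrix(g, ncol = Cout)))
    dW <- matrix(0, Cin, ncol(Wn$val))
    dxm <- matrix(0, nrow = prod(sp), ncol = Cin)
    for (q in seq_len(nrow(offs))) {
      gq <- if (nd == 2)
        g[seq(1, osp[1], 2) + offs[q, 1], seq(1, osp[2], 2) + offs[q, 2], ,
          drop = FALSE]
      else
        g[seq(1, osp[1], 2) + offs[q, 1], seq(1, osp[2], 2) + offs[q, 2],
          seq(1, osp[3], 2) + offs[q, 3], , drop = FALSE]
      gqm <- matrix(gq, nrow = prod(sp))
      cols <- ((q - 1) * Cout + 1):(q * Cout)
      dW[, cols] <- crossprod(xm, gqm)
      dxm <- dxm + gqm %*% t(Wn$val[, cols])
    }
    accum(Wn, dW)
    accum(x, array(dxm, d))
  }
  node
}

# 2x max pooling along every spatial axis.
ag_maxpool <- function(tape, x) {
  xv <- x$val; d <- dim(xv); nd <- length(d) - 1L
  sp <- d[seq_len(nd)]
  offs <- as.matrix(do.call(expand.grid, rep(list(0:1), nd)))
  get_q <- function(a, q) {
    if (nd == 2) a[seq(1, sp[1], 2) + offs[q, 1],
                   seq(1, sp[2], 2) + offs[q, 2], , drop = FALSE]
    else a[seq(1, sp[1], 2) + offs[q, 1], seq(1, sp[2], 2) + offs[q, 2],
           seq(1, sp[3], 2) + offs[q, 3], , drop = FALSE]
  }
  m <- get_q(xv, 1); which_q <- array(1L, dim(m))
  for (q in 2:nrow(offs)) {
    aq <- get_q(xv, q)
    sel <- aq > m
    m[sel] <- aq[sel]; which_q[sel] <- q
  }
  node <- new_node(tape, m)
  node$backfn <- function(g) {
    dx <- array(0, d)
    for (q in seq_len(nrow(offs))) {
      dq <- array(0, dim(m))
      sel <- which_q == q
      dq[sel] <- g[sel]
      if (nd == 2) dx[seq(1, sp[1], 2) + offs[q, 1],
                      seq(1, sp[2], 2) + offs[q, 2], ] <- dq
      else dx[seq(1, sp[1], 2) + offs[q, 1], seq(1, sp[2], 2) + offs[q, 2],
              seq(1, sp[3], 2) + offs[q, 3], ] <- dq
    }
    accum(x, dx)
  }
  node
}

ag_relu <- function(tape, x) {
  v <- x$val; m <- v > 0
  node <- new_node(tape, v * m)
  node$backfn <- function(g) accum(x, g * m)
  node
}

ag_lrelu <- function(tape, x, alpha = 0.01) {
  v <- x$val; m <- v > 0
  node <- new_node(tape, ifelse(m, v, alpha * v))
  node$backfn <- function(g) accum(x, g * ifelse(m, 1, alpha))
  node
}

ag_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$val))
  node <- new_node(tape, s)
  node$backfn <- function(g) accum(x, g * s * (1 - s))
  node
}

ag_add <- function(tape, x, y) {
  node <- new_node(tape, x$val + y$val)
  node$backfn <- function(g) { accum(x, g); accum(y, g) }
  node
}

ag_concat_c <- function(tape, x, y) {
  dx <- dim(x$val); dy <- dim(y$val); nd <- length(dx) - 1L
  cx <- dx[nd + 1L]; cy <- dy[nd + 1L]
  out <- array(c(x$val, y$val), c(dx[seq_len(nd)], cx + cy))
  node <- new_node(tape, out)
  nx <- prod(dx)
  node$backfn <- function(g) {
    accum(x, array(g[seq_len(nx)], dx))
    accum(y, array(g[(nx + 1):length(g)], dy))
  }
  node
}

# Global average pool: channel means as a vector node.
ag_global_mean <- function(tape, x) {
  d <- dim(x$val); nd <- length(d) - 1L
  n_sp <- prod(d[seq_len(nd)])
  m <- colMeans(matrix(x$val, nrow = n_sp))
  node <- new_node(tape, m)
  node$backfn <- function(g)
    accum(x, array(rep(g, each = n_sp) / n_sp, d))
  node
}

# Multiply channel c of x by scalar s[c].
ag_scale_channels <- function(tape, x, s) {
  d <- dim(x$val); nd <- length(d) - 1L
  n_sp <- prod(d[seq_len(nd)])
  sv <- rep(s$val, each = n_sp)
  node <- new_node(tape, x$val * sv)
  node$backfn <- function(g) {
    accum(x, g * sv)
    accum(s, colSums(matrix(g * x$val, nrow = n_sp)))
  }
  node
}

# Multiply every channel of x by a single-channel spatial field alpha.
ag_mul_pixel <- function(tape, x, alpha) {
  d <- dim(x$val); nd <- length(d) - 1L
  n_sp <- prod(d[seq_len(nd)])
  av <- as.vector(alpha$val)              # length n_sp, recycled per channel
  node <- new_node(tape, x$val * av)
  node$backfn <- function(g) {
    accum(x, g * av)
    da <- rowSums(matrix(g * x$val, nrow = n_sp))
    accum(alpha, array(da, dim(alpha$val)))
  }
  node
}

ag_dense <- function(tape, x, Wn, bn) {
  y <- as.vector(x$val %*% Wn$val) + bn$val
  node <- new_node(tape, y)
  node$backfn <- function(g) {
    g <- matrix(g, nrow = 1)
    accum(Wn, crossprod(matrix(x$val, nrow = 1), g))
    accum(bn, as.vector(g))
    accum(x, as.vector(g %*% t(Wn$val)))
  }
  node
}

# Channel-wise batch normalization over the spatial dimensions of one
# sample; running statistics live in `state` (an environment) under `name`.
ag_batchnorm <- function(tape, x, gamma, beta, state, name, training,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$val); nd <- length(d) - 1L
  n_sp <- prod(d[seq_len(nd)]); C <- d[nd + 1L]
  xm <- matrix(x$val, nrow = n_sp)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    rs <- state[[name]] %||% list(mean = mu, var = va)
    state[[name]] <- list(mean = (1 - momentum) * rs$mean + momentum * mu,
                          var = (1 - momentum) * rs$var + momentum * va)
  } else {
    rs <- state[[name]] %||% list(mean = numeric(C), var = rep(1, C))
    mu <- rs$mean; va <- rs$var
  }
  sd_c <- sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu, `-`), 2, sd_c, `/`)
  y <- sweep(sweep(xhat, 2, gamma$val, `*`), 2, beta$val, `+`)
  node <- new_node(tape, array(y, d))
  node$backfn <- function(g) {
    gm <- matrix(g, nrow = n_sp)
    accum(gamma, colSums(gm * xhat))
    accum(beta, colSums(gm))
    dxhat <- sweep(gm, 2, gamma$val, `*`)
    if (training) {
      # full batch-norm backward through the per-pass statistics
      t1 <- sweep(dxhat, 2, colMeans(dxhat), `-`)
      t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), `*`)
      dx <- sweep(t1 - t2, 2, sd_c, `/`)
    } else {
      dx <- sweep(dxhat, 2, sd_c, `/`)
    }
    accum(x, array(dx, d))
  }
  node
}

## ---- scalar ops and losses ------------------------------------------------

ag_sum_prod <- function(tape, x, w) {
  node <- new_node(tape, sum(x$val * w))
  node$backfn <- function(g) accum(x, g * w)
  node
}

ag_s <- function(tape, op, a, b = NULL) {
  av <- if (inherits(a, "environment")) a$val else a
  bv <- if (inherits(b, "environment")) b$val else b
  val <- switch(op, add = av + bv, sub = av - bv, mul = av * bv,
                div = av / bv, sqrt = sqrt(av), rsub = bv - av)
  node <- new_node(tape, val)
  node$backfn <- function(g) {
    da <- switch(op, add = g, sub = g, mul = g * bv, div = g / bv,
                 sqrt = g / (2 * sqrt(av)), rsub = -g)
    db <- switch(op, add = g, sub = -g, mul = g * av,
                 div = -g * av / bv^2, sqrt = NULL, rsub = g)
    if (inherits(a, "environment")) accum(a, da)
    if (!is.null(b) && inherits(b, "environment")) accum(b, db)
  }
  node
}

# Mean voxel binary cross-entropy of probability node p against constant y.
ag_bce_mean <- function(tape, p, y) {
  pv <- pmin(pmax(p$val, BCE_EPS), 1 - BCE_EPS)
  n <- length(pv)
  node <- new_node(tape, mean(-((1 - y) * log(1 - pv) + y * log(pv))))
  node$backfn <- function(g)
    accum(p, g * (pv - y) / (pv * (1 - pv)) / n)
  node
}

# Combined loss on a probability-map node: the differentiable counterpart
# of combined_loss().
ag_combined_loss <- function(tape, p, y, w = loss_weights(), eps = 1e-8) {
  total <- NULL
  sy <- sum(y); n <- length(y)
  stp <- ag_sum_prod(tape, p, y)            # soft TP
  sp_ <- ag_sum_prod(tape, p, array(1, dim(y)))
  if (w$w_dice > 0) {
    dice_s <- ag_s(tape, "div", ag_s(tape, "mul", stp, 2),
                   ag_s(tape, "add", sp_, sy + eps))
    total <- ag_s(tape, "mul", ag_s(tape, "rsub", dice_s, 1), w$w_dice)
  }
  if (w$w_bce > 0) {
    t_bce <- ag_s(tape, "mul", ag_bce_mean(tape, p, y), w$w_bce)
    total <- if (is.null(total)) t_bce else ag_s(tape, "add", total, t_bce)
  }
  if (w$w_mcc > 0) {
    fp <- ag_s(tape, "sub", sp_, stp)
    fn <- ag_s(tape, "rsub", stp, sy)
    tn <- ag_s(tape, "rsub", ag_s(tape, "add", fp, sy), n)
    num <- ag_s(tape, "sub", ag_s(tape, "mul", stp, tn),
                ag_s(tape, "mul", fp, fn))
    den <- ag_s(tape, "mul",
                ag_s(tape, "mul", ag_s(tape, "add", stp, fn),
                     ag_s(tape, "add", stp, fp)),
                ag_s(tape, "mul", ag_s(tape, "add", tn, fn),
                     ag_s(tape, "add", tn, fp)))
    mcc_s <- ag_s(tape, "div", num,
                  ag_s(tape, "sqrt", ag_s(tape, "add", den, eps)))
    t_mcc <- ag_s(tape, "mul",
                  ag_s(tape, "div", ag_s(tape, "rsub", mcc_s, 1), 2),
                  w$w_mcc)
    total <- if (is.null(total)) t_mcc else ag_s(tape, "add", total, t_mcc)
  }
  total
}
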