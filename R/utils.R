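#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 9973) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Shift a 3-D array by integer offsets (dz, dy, dx), filling with `fill`.
shift3d <- function(a, dz, dy, dx, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  zs <- seq_len(d[1]); ys <- seq_len(d[2]); xs <- seq_len(d[3])
  z_src <- zs - dz; y_src <- ys - dy; x_src <- xs - dx
  zk <- z_src >= 1 & z_src <= d[1]
  yk <- y_src >= 1 & y_src <= d[2]
  xk <- x_src >= 1 & x_src <= d[3]
  out[zs[zk], ys[yk], xs[xk]] <- a[z_src[zk], y_src[yk], x_src[xk]]
  out
}

# All 26- or 6-neighbourhood integer offsets in (z, y, x) order.
neighbor_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

#' Label connected components of a binary 3-D array
#'
#' Breadth-first labelling with 6- or 26-connectivity, used to split a
#' post-processed tumor mask into lesion instances and to find homogeneous
#' zones for size-zone texture features.
#'
#' @param a binary 3-D array.
#' @param connectivity 6 or 26.
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1 in scan order.
#' @export
label_components <- function(a, connectivity = 26) {
  d <- dim(a)
  if (length(d) != 3) stopf("label_components expects a 3-D array")
  # pad by one voxel so neighbour indexing never wraps
  dp <- d + 2L
  pa <- array(FALSE, dp)
  pa[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- (a != 0)
  offs <- neighbor_offsets(connectivity)
  lin_offs <- offs[, 1] + offs[, 2] * dp[1] + offs[, 3] * dp[1] * dp[2]
  lab <- integer(prod(dp))
  fg <- which(pa)
  nlab <- 0L
  for (s in fg) {
    if (lab[s] != 0L || !pa[s]) next
    nlab <- nlab + 1L
    frontier <- s
    lab[s] <- nlab
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, lin_offs, `+`)))
      nb <- nb[pa[nb] & lab[nb] == 0L]
      lab[nb] <- nlab
      frontier <- nb
    }
  }
  out <- array(lab, dp)[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  array(as.integer(out), d)
}

# Ensure a numeric 3-D array; accepts Volume/Mask/LabelMap or plain arrays.
as_array3d <- function(x) {
  if (inherits(x, c("hep_volume", "hep_mask", "hep_labelmap"))) x$data
  else if (is.array(x) && length(dim(x)) == 3) x
  else stopf("expected a 3-D array or a Volume/Mask/LabelMap")
}

spacing_of <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, c("hep_volume", "hep_mask", "hep_labelmap"))) x$spacing else default
}
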