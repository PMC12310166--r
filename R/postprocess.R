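## Online post-processing of the initial tumor segmentation: tri-planar
## morphology plus a plane-vote threshold. The published threshold of 2 is
## read as a 2-of-3 vote over the xy / xz / yz plane-wise cleaned masks --
## the only reading under which an integer threshold and the three named
## planes interact; it is exposed in the configuration so alternative
## readings can be tested.

#' Post-processing configuration
#'
#' @param vote_threshold keep a voxel when it is positive in at least this
#'   many of the three plane-wise cleaned masks (1, 2 or 3; default 2).
#' @param struct_radius radius (voxels) of the in-plane disk structuring
#'   element; default 1, the smallest non-trivial element.
#' @param order morphological sequence applied per plane; default closing
#'   (fill gaps) then opening (drop islands).
#' @export
postprocess_config <- function(vote_threshold = 2, struct_radius = 1,
                               order = c("closing", "opening")) {
  if (!vote_threshold %in% 1:3) stopf("vote_threshold must be 1, 2 or 3")
  if (struct_radius < 1) stopf("struct_radius must be >= 1")
  if (!all(order %in% c("closing", "opening"))) stopf("bad morphology order")
  structure(list(vote_threshold = as.integer(vote_threshold),
                 struct_radius = as.integer(struct_radius),
                 order = order, planes = c("xy", "xz", "yz")),
            class = "hep_postprocess_config")
}

morph_slice <- function(sl, op, kern) {
  out <- if (op == "closing") EBImage::closing(sl, kern)
         else EBImage::opening(sl, kern)
  matrix(as.numeric(out) != 0, nrow(sl), ncol(sl))
}

#' Apply a 2-D morphological operation slice-wise along one plane
#'
#' The operation runs independently on every slice of the given plane
#' (`"xy"`: slices along z; `"xz"`: along y; `"yz"`: along x) with a disk
#' structuring element of radius `r`.
#'
#' @param m a `hep_mask` or binary 3-D array.
#' @param plane one of `"xy"`, `"xz"`, `"yz"`.
#' @param op `"closing"` or `"opening"`.
#' @param r structuring-element radius in voxels.
#' @return object of the same kind as `m`.
#' @export
morph_plane <- function(m, plane = c("xy", "xz", "yz"),
                        op = c("closing", "opening"), r = 1) {
  plane <- match.arg(plane); op <- match.arg(op)
  a <- as_array3d(m) != 0
  kern <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  d <- dim(a)
  out <- array(FALSE, d)
  ax <- switch(plane, xy = 1L, xz = 2L, yz = 3L)
  for (i in seq_len(d[ax])) {
    sl <- switch(plane, xy = a[i, , ], xz = a[, i, ], yz = a[, , i]) * 1
    if (!any(sl != 0)) next  # both ops map an empty slice to empty
    res <- morph_slice(sl, op, kern)
    switch(plane, xy = out[i, , ] <- res, xz = out[, i, ] <- res,
           yz = out[, , i] <- res)
  }
  if (inherits(m, "hep_mask")) mask(out, m$spacing) else out * 1
}

#' Solidify an initial tumor segmentation
#'
#' Runs the configured morphological sequence independently in the xy, xz
#' and yz planes, then keeps each voxel positive in at least
#' `vote_threshold` of the three cleaned masks.
#'
#' @param initial a `hep_mask` or binary 3-D array (thresholded network
#'   output).
#' @param cfg a [postprocess_config()].
#' @return cleaned mask of the same kind as `initial`.
#' @export
postprocess_tumor <- function(initial, cfg = postprocess_config()) {
  a <- as_array3d(initial) != 0
  votes <- array(0L, dim(a))
  for (plane in cfg$planes) {
    cur <- a * 1
    for (op in cfg$order)
      cur <- morph_plane(cur, plane, op, cfg$struct_radius)
    votes <- votes + (cur != 0)
  }
  out <- votes >= cfg$vote_threshold
  if (inherits(initial, "hep_mask")) mask(out, initial$spacing) else out * 1
}
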