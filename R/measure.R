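## Tumor size from a segmented mask: longest border-point distance (Feret
## diameter) followed by the linear pixel-to-centimeter regression
## size = b + a * length, with the published coefficients as defaults.

#' Pixel-to-centimeter size regression
#'
#' @param a slope, cm per pixel (default 0.0748).
#' @param b intercept, cm (default -0.2011).
#' @param length_mode how the longest diameter is measured: per axial slice
#'   in 2-D (`"slice2d"`, default — the in-plane reading consistent with a
#'   ~0.75 mm CT pixel implied by the default slope) or over all border
#'   voxels in 3-D index space (`"volume3d"`).
#' @export
size_regression <- function(a = 0.0748, b = -0.2011,
                            length_mode = c("slice2d", "volume3d")) {
  structure(list(a = a, b = b, length_mode = match.arg(length_mode)),
            class = "hep_size_regression")
}

#' @export
print.hep_size_regression <- function(x, ...) {
  cat(sprintf("<size regression: size_cm = %.4f + %.4f * length_px (%s)>\n",
              x$b, x$a, x$length_mode))
  invisible(x)
}

# Border voxels: positive voxels with at least one zero face-neighbour
# (6-connectivity); voxels on the array boundary count as border.
border_voxels <- function(a) {
  d <- dim(a)
  inner <- array(TRUE, d)
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    inner <- inner & shift3d(a, off[1], off[2], off[3], fill = 0) != 0
  which(a != 0 & !inner, arr.ind = TRUE)
}

# Max pairwise distance among points (rows), exact. Points are pruned to
# per-slice convex hull vertices first: a farthest pair consists of extreme
# points, and every extreme point of the 3-D cloud is a 2-D hull vertex of
# its slice.
max_pairwise_dist <- function(pts) {
  if (nrow(pts) < 2) return(0)
  if (nrow(pts) > 200) {
    keep <- logical(nrow(pts))
    for (zv in unique(pts[, 1])) {
      sel <- which(pts[, 1] == zv)
      if (length(sel) <= 3) { keep[sel] <- TRUE; next }
      h <- grDevices::chull(pts[sel, 2], pts[sel, 3])
      keep[sel[h]] <- TRUE
    }
    pts <- pts[keep, , drop = FALSE]
  }
  n <- nrow(pts)
  best <- 0
  step <- max(1, floor(2e6 / n))
  i <- 1
  sq <- rowSums(pts^2)
  tp <- t(pts)
  while (i <= n) {
    j <- min(n, i + step - 1)
    block <- pts[i:j, , drop = FALSE]
    d2 <- outer(rowSums(block^2), sq, `+`) - 2 * block %*% tp
    best <- max(best, max(d2))
    i <- j + 1
  }
  sqrt(max(best, 0))
}

#' Longest diameter of a tumor mask
#'
#' The longest Euclidean distance between tumor border points, in pixel
#' (index) units. `"slice2d"` measures within each axial slice and takes
#' the maximum over slices; `"volume3d"` measures over all border voxels in
#' 3-D index space. When `spacing` is supplied, coordinates are scaled to
#' millimetres first and the result is in mm (used for phantom ground
#' truth, not for the pixel-based regression).
#'
#' @param tumor a `hep_mask` or binary 3-D array; must be nonempty.
#' @param mode `"slice2d"` (default) or `"volume3d"`.
#' @param spacing optional mm-per-voxel triple for a physical measurement.
#' @return length in pixels (or mm when `spacing` is given).
#' @export
longest_diameter <- function(tumor, mode = c("slice2d", "volume3d"),
                             spacing = NULL) {
  mode <- match.arg(mode)
  a <- as_array3d(tumor)
  if (!any(a != 0)) stopf("longest_diameter: empty mask")
  if (mode == "slice2d") {
    best <- 0
    for (zi in seq_len(dim(a)[1])) {
      sl <- a[zi, , ]
      if (!any(sl != 0)) next
      # in-plane border: positive pixels with a zero 4-neighbour
      d <- dim(sl)
      inner <- rbind(sl[-1, ], 0) != 0 & rbind(0, sl[-d[1], ]) != 0 &
        cbind(sl[, -1], 0) != 0 & cbind(0, sl[, -d[2]]) != 0
      bp <- which(sl != 0 & !inner, arr.ind = TRUE)
      if (nrow(bp) < 2) next
      bp <- matrix(as.numeric(bp), ncol = 2)
      if (!is.null(spacing)) bp <- sweep(bp, 2, spacing[2:3], `*`)
      pts <- cbind(0, bp)
      best <- max(best, max_pairwise_dist(pts))
    }
    best
  } else {
    bp <- border_voxels(a)
    bp <- matrix(as.numeric(bp), ncol = 3)
    if (!is.null(spacing)) bp <- sweep(bp, 2, spacing, `*`)
    max_pairwise_dist(bp)
  }
}

#' Convert a pixel length to centimetres with the size regression
#'
#' `size = b + a * length`. The raw value is returned (it can be negative
#' for lengths below about 2.7 px with the default coefficients); clamping
#' at zero happens only when an annotation report is assembled.
#'
#' @param length_px longest diameter in pixels (>= 0).
#' @param r a [size_regression()].
#' @export
size_cm <- function(length_px, r = size_regression()) {
  stopifnot(inherits(r, "hep_size_regression"), all(length_px >= 0))
  r$b + r$a * length_px
}

#' Fit the size regression by ordinary least squares
#'
#' @param pairs data.frame with columns `length_px` and `size_cm`
#'   (as produced by [make_calibration_pairs()]).
#' @param length_mode stored in the returned model.
#' @export
fit_size_regression <- function(pairs, length_mode = "slice2d") {
  if (nrow(pairs) < 2 || length(unique(pairs$length_px)) < 2)
    stopf("fit_size_regression: need >= 2 distinct lengths")
  fit <- stats::lm(size_cm ~ length_px, data = pairs)
  co <- stats::coef(fit)
  size_regression(a = unname(co["length_px"]), b = unname(co["(Intercept)"]),
                  length_mode = length_mode)
}
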