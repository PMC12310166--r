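## Eight-model Couinaud-style liver partition and the overlap rule for
## tumor location. One binary segmentation model is trained per segment;
## their probability maps are merged into a single label map by argmax with
## a nearest-label fill, and a tumor is located in every segment holding
## strictly more than a quarter of its volume.

#' Tumor location rule
#'
#' A segment is reported when the fraction of the tumor inside it strictly
#' exceeds `threshold` (default 0.25).
#'
#' @param threshold fraction in (0, 1).
#' @export
location_rule <- function(threshold = 0.25) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0,1)")
  structure(list(threshold = threshold, comparison = ">"),
            class = "hep_location_rule")
}

#' Train the eight-model partition ensemble
#'
#' Model `k` is trained to segment the binary region `segments == k`
#' restricted to the liver. Inputs are the liver-masked intensity volume
#' plus three normalized coordinate channels (the compartments are defined
#' by position, which a translation-invariant network cannot otherwise
#' see). Seeds are derived per segment from `tc$seed`.
#'
#' @param cases list of phantom cases (or lists with `volume`, `liver`,
#'   `segments`).
#' @param cfg a [net_config()]; `dims` selects the 2-D or 3-D path and
#'   `in_channels` must be 4.
#' @param tc a [train_config()].
#' @return a `hep_partition_ensemble` with 8 trained models.
#' @export
train_partition <- function(cases, cfg, tc) {
  for (k in 1:8) {
    present <- any(vapply(cases, function(cs) any(cs$segments$data == k),
                          logical(1)))
    if (!present) stopf("segment %d absent from every training case", k)
  }
  models <- vector("list", 8)
  histories <- vector("list", 8)
  for (k in 1:8) {
    net <- if (cfg$dims == 3) build_unet3d(replace_seed(cfg, derive_seed(tc$seed, k)))
           else build_seresunet(replace_seed(cfg, derive_seed(tc$seed, k)))
    samples <- lapply(cases, function(cs) {
      cr <- partition_crop(cs$volume, cs$liver, cfg$depth)
      y <- array(0, cr$size)
      y[seq_along(cr$box$z), seq_along(cr$box$y), seq_along(cr$box$x)] <-
        (cs$segments$data == k)[cr$box$z, cr$box$y, cr$box$x]
      list(x = cr$x, y = y)
    })
    tck <- tc; tck$seed <- derive_seed(tc$seed, 100 + k)
    fit <- train_segnet(net, samples, tck)
    models[[k]] <- fit$net
    histories[[k]] <- fit$history
  }
  structure(list(models = models, dims = cfg$dims, merge = "argmax_fill",
                 histories = histories),
            class = "hep_partition_ensemble")
}

#' @export
print.hep_partition_ensemble <- function(x, ...) {
  cat(sprintf("<partition ensemble: 8 x %d-D models, merge=%s>\n",
              x$dims, x$merge))
  invisible(x)
}

# Liver-masked intensity plus normalized (z, y, x) coordinate channels,
# as a (z, y, x, channel) array. Coordinates are normalized within the
# array passed in, so the same helper must be used for training and
# prediction crops.
partition_input <- function(v, liver) {
  a <- as_array3d(v) * (as_array3d(liver) != 0)
  d <- dim(a)
  cz <- array(rep((seq_len(d[1]) - 0.5) / d[1],
                  times = d[2] * d[3]), d)
  cy <- aperm(array(rep((seq_len(d[2]) - 0.5) / d[2], times = d[1] * d[3]),
                    c(d[2], d[1], d[3])), c(2, 1, 3))
  cx <- aperm(array(rep((seq_len(d[3]) - 0.5) / d[3], times = d[1] * d[2]),
                    c(d[3], d[1], d[2])), c(2, 3, 1))
  out <- array(0, c(d, 4))
  out[, , , 1] <- scale_intensity(a)
  out[, , , 2] <- cz; out[, , , 3] <- cy; out[, , , 4] <- cx
  out
}

# Crop volume and liver to the liver bounding box, padded up to a multiple
# of 2^depth. Training and prediction share this view: it improves the
# foreground balance and keeps the coordinate channels consistent.
partition_crop <- function(v, liver, depth) {
  la <- as_array3d(liver) != 0
  a <- as_array3d(v)
  bb <- apply(which(la, arr.ind = TRUE), 2, range)
  m <- 2^depth
  size <- pmax(bb[2, ] - bb[1, ] + 1, m)
  size <- ceiling(size / m) * m
  lo <- pmax(1, pmin(bb[1, ], dim(a) - size + 1))
  hi <- lo + size - 1
  pad_needed <- any(hi > dim(a))
  zz <- lo[1]:min(hi[1], dim(a)[1])
  yy <- lo[2]:min(hi[2], dim(a)[2])
  xx <- lo[3]:min(hi[3], dim(a)[3])
  av <- array(0, size); lv <- array(FALSE, size)
  av[seq_along(zz), seq_along(yy), seq_along(xx)] <- a[zz, yy, xx]
  lv[seq_along(zz), seq_along(yy), seq_along(xx)] <- la[zz, yy, xx]
  list(x = partition_input(av, lv), box = list(z = zz, y = yy, x = xx),
       size = size)
}

#' Merge the ensemble's probability maps into a segment label map
#'
#' Each model predicts a probability map on the liver-masked input. Inside
#' the liver a voxel takes the argmax label when the maximum probability is
#' at least 0.5 (ties to the lowest label); remaining liver voxels take the
#' label of the nearest assigned voxel (iterative 6-neighbour fill).
#' Voxels outside the liver are 0. The result is always a partition of the
#' liver support.
#'
#' @param e a `hep_partition_ensemble` (or a list of 8 objects accepted by
#'   [predict_segnet()], e.g. oracle networks).
#' @param v the intensity volume.
#' @param liver liver mask aligned with `v`.
#' @export
partition <- function(e, v, liver) {
  models <- if (inherits(e, "hep_partition_ensemble")) e$models else e
  if (length(models) != 8) stopf("partition requires exactly 8 models")
  la <- as_array3d(liver) != 0
  if (!identical(dim(as_array3d(v)), dim(la))) stopf("partition: shape mismatch")
  d <- dim(la)
  trained <- all(vapply(models, inherits, logical(1), "hep_segnet"))
  cr <- if (trained) partition_crop(v, liver, models[[1]]$cfg$depth)
  probs <- array(0, c(d, 8))
  for (k in 1:8) {
    if (trained) {
      pk <- predict_segnet(models[[k]], cr$x, liver = liver)
      full <- array(0, d)
      full[cr$box$z, cr$box$y, cr$box$x] <-
        pk[seq_along(cr$box$z), seq_along(cr$box$y), seq_along(cr$box$x)]
      probs[, , , k] <- full
    } else {
      probs[, , , k] <- predict_segnet(models[[k]], partition_input(v, liver),
                                       liver = liver)
    }
  }
  pm <- probs[, , , 1]
  am <- array(1L, d)
  for (k in 2:8) {          # strict > keeps ties at the lowest label
    pk <- probs[, , , k]
    sel <- pk > pm
    pm[sel] <- pk[sel]; am[sel] <- k
  }
  lab <- array(0L, d)
  assigned <- la & pm >= 0.5
  lab[assigned] <- am[assigned]
  # nearest-label fill for unassigned liver voxels
  todo <- la & lab == 0L
  if (any(todo) && any(lab > 0L)) {
    while (any(todo)) {
      grew <- FALSE
      cand <- array(9L, d)  # 9 = sentinel above any label
      for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                       c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
        nb <- shift3d(lab, off[1], off[2], off[3], fill = 0L)
        sel <- todo & nb > 0L
        cand[sel] <- pmin(cand[sel], nb[sel])
      }
      sel <- todo & cand < 9L
      if (!any(sel)) break
      lab[sel] <- cand[sel]
      todo <- la & lab == 0L
    }
  }
  if (any(la & lab == 0L)) {
    # isolated liver voxels with no assigned neighbour anywhere: argmax
    rest <- la & lab == 0L
    lab[rest] <- am[rest]
  }
  labelmap(lab, spacing_of(v))
}

#' Coverage ratio of region b by region a
#'
#' `|a n b| / |b|`, the overlap-rule statistic.
#'
#' @param region_a,region_b binary masks or arrays of equal shape;
#'   `region_b` must be nonempty.
#' @export
coverage_ratio <- function(region_a, region_b) {
  a <- as_array3d(region_a) != 0; b <- as_array3d(region_b) != 0
  if (!identical(dim(a), dim(b))) stopf("coverage_ratio: shape mismatch")
  nb <- sum(b)
  if (nb == 0) stopf("coverage_ratio: empty reference region")
  sum(a & b) / nb
}

#' Locate a tumor within the segment partition
#'
#' Segment `k` is reported when the fraction of the tumor lying inside it
#' strictly exceeds the rule threshold (default 0.25). When no segment
#' passes, the single segment holding the largest fraction is returned
#' (ties to the lowest label), so a tumor inside the liver always has a
#' non-empty location.
#'
#' @param tumor nonempty binary mask.
#' @param segments a `hep_labelmap`.
#' @param rule a [location_rule()].
#' @return sorted integer vector, subset of 1..8.
#' @export
locate <- function(tumor, segments, rule = location_rule()) {
  tv <- as_array3d(tumor) != 0
  sv <- as_array3d(segments)
  if (!identical(dim(tv), dim(sv))) stopf("locate: shape mismatch")
  nt <- sum(tv)
  if (nt == 0) stopf("locate: empty tumor mask")
  frac <- vapply(1:8, function(k) sum(tv & sv == k) / nt, numeric(1))
  hit <- which(frac > rule$threshold)
  if (length(hit) == 0) hit <- which.max(frac)
  sort(as.integer(hit))
}

#' Micro-averaged location accuracy over tumors
#'
#' Treats each (tumor, segment) decision as one binary prediction and
#' micro-averages precision, recall and accuracy over all 8 x n decisions.
#'
#' @param pred_locs,true_locs lists of integer location sets.
#' @export
location_accuracy <- function(pred_locs, true_locs) {
  if (length(pred_locs) != length(true_locs))
    stopf("location_accuracy: length mismatch")
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred_locs)) {
    p <- 1:8 %in% pred_locs[[i]]
    y <- 1:8 %in% true_locs[[i]]
    tp <- tp + sum(p & y); fp <- fp + sum(p & !y)
    fn <- fn + sum(!p & y); tn <- tn + sum(!p & !y)
  }
  list(precision = if (tp + fp == 0) 1 else tp / (tp + fp),
       recall = if (tp + fn == 0) 1 else tp / (tp + fn),
       accuracy = (tp + tn) / (tp + fp + tn + fn))
}
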