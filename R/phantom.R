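## Synthetic CT phantom generator.
##
## Each case carries a smooth convex "liver", an 8-compartment plane-based
## pseudo-Couinaud partition, ellipsoidal tumors with known physical sizes
## and generative parameters, and 11 binary characteristic labels, each a
## fixed threshold on one generative parameter. The generator is the test
## bed for every downstream stage; it does not attempt anatomical realism
## (no vasculature, no HU calibration).

#' Phantom generator configuration
#'
#' @param shape grid dimensions (z, y, x); default 64 x 96 x 96.
#' @param spacing mm per voxel (z, y, x); default (2.5, 1, 1), a typical
#'   thick-slice CT geometry.
#' @param n_tumors number of tumors to place.
#' @param tumor_diameter_range_cm range the longest tumor axis is drawn
#'   from; default 1 to 5 cm, the range most liver lesions fall in.
#' @param tumor_diameters_cm optional fixed diameters (recycled), overriding
#'   the random draw.
#' @param noise_sd additive Gaussian noise, CT-like intensity units.
#' @param seed master seed; an identical seed reproduces the case bitwise.
#' @export
phantom_config <- function(shape = c(64, 96, 96), spacing = c(2.5, 1, 1),
                           n_tumors = 1, tumor_diameter_range_cm = c(1, 5),
                           tumor_diameters_cm = NULL, noise_sd = 3,
                           seed = 1) {
  if (any(shape < 8)) stopf("phantom shape too small")
  if (any(spacing <= 0)) stopf("spacing must be positive")
  r <- as.numeric(tumor_diameter_range_cm)
  if (length(r) != 2 || r[1] <= 0 || r[2] < r[1])
    stopf("tumor_diameter_range_cm must be a positive interval")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_tumors = as.integer(n_tumors),
                 tumor_diameter_range_cm = r,
                 tumor_diameters_cm = tumor_diameters_cm,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "hep_phantom_config")
}

# Fixed thresholds tying each characteristic label to one generative
# parameter. Cut points sit at the median of each parameter's sampling
# distribution so cohort prevalences are near 0.5. Continuous parameters
# are drawn with a narrow exclusion band around the cut (see runif_gap) so
# every label is a well-posed attribute rather than a coin flip at the
# threshold.
PHANTOM_LABEL_NAMES <- c(
  "hypodense", "irregular_margin", "heterogeneous", "large",
  "elongated", "flattened", "rim_enhancing", "noisy_core",
  "coarse_texture", "strong_contrast", "focal_inclusions")

PHANTOM_LABEL_CUTS <- c(irregularity = 0.25, blob_amplitude = 26.5,
                        diameter_cm = 3.0, b_ratio = 0.8, c_ratio = 0.65,
                        core_noise_sd = 4.0, grain_wavelength_mm = 5.3,
                        abs_offset = 40)

phantom_labels_from_params <- function(p) {
  cuts <- PHANTOM_LABEL_CUTS
  as.integer(c(
    p$intensity_offset < 0,
    p$irregularity > cuts["irregularity"],
    p$blob_amplitude > cuts["blob_amplitude"],
    p$diameter_cm > cuts["diameter_cm"],
    p$b_ratio < cuts["b_ratio"],
    p$c_ratio < cuts["c_ratio"],
    p$rim > 0,
    p$core_noise_sd > cuts["core_noise_sd"],
    p$grain_wavelength_mm > cuts["grain_wavelength_mm"],
    abs(p$intensity_offset) > cuts["abs_offset"],
    p$inclusions > 0))
}

# Uniform draw excluding a narrow ambiguity band around a label cut point.
runif_gap <- function(lo, hi, cut, gap) {
  repeat {
    u <- stats::runif(1, lo, hi)
    if (abs(u - cut) >= gap) return(u)
  }
}

# Smooth low-frequency field on the grid (liver parenchyma texture).
smooth_field <- function(shape, amplitude, nwaves = 3) {
  z <- seq_len(shape[1]) / shape[1]
  y <- seq_len(shape[2]) / shape[2]
  x <- seq_len(shape[3]) / shape[3]
  f <- array(0, shape)
  for (i in seq_len(nwaves)) {
    kz <- stats::runif(1, 0.5, 2.5) * 2 * pi; pz <- stats::runif(1, 0, 2 * pi)
    ky <- stats::runif(1, 0.5, 2.5) * 2 * pi; py <- stats::runif(1, 0, 2 * pi)
    kx <- stats::runif(1, 0.5, 2.5) * 2 * pi; px <- stats::runif(1, 0, 2 * pi)
    f <- f + outer(outer(cos(kz * z + pz), cos(ky * y + py)), cos(kx * x + px))
  }
  amplitude * f / nwaves
}

# Voxelize one tumor: an ellipsoid with semi-axes `semi_mm` (z, y, x) at
# `center` (voxel coords), with inward boundary modulation of relative
# depth `irr` that vanishes at the poles of the major axis so the longest
# extent is preserved.
tumor_mask_array <- function(shape, spacing, center, semi_mm, irr,
                             major_axis, phase) {
  semi_vox <- semi_mm / spacing
  lo <- pmax(1, floor(center - semi_vox - 1))
  hi <- pmin(shape, ceiling(center + semi_vox + 1))
  zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
  uz <- (zz - center[1]) / semi_vox[1]
  uy <- (yy - center[2]) / semi_vox[2]
  ux <- (xx - center[3]) / semi_vox[3]
  UZ <- array(rep(uz, times = length(yy) * length(xx)),
              c(length(zz), length(yy), length(xx)))
  UY <- aperm(array(rep(uy, times = length(zz) * length(xx)),
                    c(length(yy), length(zz), length(xx))), c(2, 1, 3))
  UX <- aperm(array(rep(ux, times = length(zz) * length(yy)),
                    c(length(xx), length(zz), length(yy))), c(2, 3, 1))
  rho <- sqrt(UZ^2 + UY^2 + UX^2)
  um <- switch(major_axis, z = UZ, y = UY, x = UX)
  # in-plane polar angle, so the margin lobes live at in-plane resolution
  rest <- switch(major_axis,
                 z = atan2(UY, UX), y = atan2(UX, UY), x = atan2(UY, UX))
  s2 <- ifelse(rho > 0, 1 - (um / rho)^2, 0)
  mod <- 0.5 * (1 + cos(8 * rest + phase))
  inside <- rho <= 1 - irr * s2 * mod & rho > 0 | rho == 0
  out <- array(FALSE, shape)
  out[zz, yy, xx] <- inside
  list(mask = out, box = list(z = zz, y = yy, x = xx),
       rho = rho, inside = inside)
}

#' Generate one synthetic phantom case
#'
#' @param config a [phantom_config()].
#' @return a `hep_phantom` with fields `volume`, `liver`, `segments`,
#'   `tumors` (list of masks), `true_size_cm`, `labels` (tumors x 11 binary
#'   matrix), and `params` (per-tumor generative parameters).
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "hep_phantom_config"))
  with_seed(config$seed, make_phantom_impl(config))
}

make_phantom_impl <- function(config) {
  shape <- config$shape; spacing <- config$spacing
  half <- (shape + 1) / 2

  # --- liver: convex super-ellipsoid, axis-aligned ---
  semi_frac <- c(0.62, 0.66, 0.70) * stats::runif(3, 0.95, 1.05)
  center <- half * c(1, 1, 0.98)
  semi <- semi_frac * (shape / 2)
  p_exp <- 2.5
  z <- seq_len(shape[1]); y <- seq_len(shape[2]); x <- seq_len(shape[3])
  AZ <- (abs(z - center[1]) / semi[1])^p_exp
  AY <- (abs(y - center[2]) / semi[2])^p_exp
  AX <- (abs(x - center[3]) / semi[3])^p_exp
  liver_arr <- outer(outer(AZ, AY, `+`), AX, `+`) <= 1

  # --- 8 plane-based compartments at per-axis medians of liver support ---
  idx <- which(liver_arr, arr.ind = TRUE)
  med <- apply(idx, 2, stats::median)
  seg_arr <- array(0L, shape)
  code <- 1L + 4L * (idx[, 1] > med[1]) + 2L * (idx[, 2] > med[2]) +
    1L * (idx[, 3] > med[3])
  seg_arr[idx] <- code

  # --- intensities: background 20, liver 100 + smooth texture ---
  vol <- array(20, shape)
  vol[liver_arr] <- 100
  vol <- vol + ifelse(liver_arr, 1, 0) * smooth_field(shape, amplitude = 8)

  # --- tumors ---
  n <- config$n_tumors
  tumors <- list(); sizes <- numeric(0); params <- list()
  labels <- matrix(integer(0), nrow = 0, ncol = 11,
                   dimnames = list(NULL, PHANTOM_LABEL_NAMES))
  occupied <- array(FALSE, shape)
  if (n > 0) {
    for (t in seq_len(n)) {
      D <- if (!is.null(config$tumor_diameters_cm))
        rep(config$tumor_diameters_cm, length.out = n)[t]
      else stats::runif(1, config$tumor_diameter_range_cm[1],
                        config$tumor_diameter_range_cm[2])
      cuts <- PHANTOM_LABEL_CUTS
      b_ratio <- runif_gap(0.6, 1.0, cuts["b_ratio"], 0.03)
      repeat {        # z semi-axis shortest, so sorted axis ratios map
        c_ratio <- stats::runif(1, 0.5, min(0.9, b_ratio - 0.02))
        if (abs(c_ratio - cuts["c_ratio"]) >= 0.03) break
      }
      pr <- list(
        diameter_cm = D,
        b_ratio = b_ratio,
        c_ratio = c_ratio,
        major_axis = sample(c("y", "x"), 1),
        intensity_offset = sample(c(-1, 1), 1) *
          runif_gap(15, 65, cuts["abs_offset"], 6),
        irregularity = runif_gap(0.05, 0.45, cuts["irregularity"], 0.03),
        n_blobs = sample(3:6, 1),
        blob_amplitude = runif_gap(3, 50, cuts["blob_amplitude"], 3),
        blob_width_mm = stats::runif(1, 3, 6),
        core_noise_sd = runif_gap(0.5, 7.5, cuts["core_noise_sd"], 0.4),
        grain_wavelength_mm = runif_gap(2.6, 8, cuts["grain_wavelength_mm"],
                                        0.4),
        rim = stats::rbinom(1, 1, 0.5),
        inclusions = stats::rbinom(1, 1, 0.5),
        phase = stats::runif(1, 0, 2 * pi))
      M <- D * 10 / 2                      # major semi-axis, mm
      semi_mm <- c(pr$c_ratio * M, 0, 0)
      if (pr$major_axis == "y") {
        semi_mm[2] <- M; semi_mm[3] <- pr$b_ratio * M
      } else {
        semi_mm[3] <- M; semi_mm[2] <- pr$b_ratio * M
      }
      placed <- FALSE
      centroid <- colMeans(idx)
      for (try in 1:60) {
        # bias draws toward the liver centroid so large tumors still fit
        vx <- idx[sample.int(nrow(idx), 1), ]
        ctr <- centroid + stats::runif(1)^1.5 * (vx - centroid) +
          stats::runif(3, -0.49, 0.49)
        tm <- tumor_mask_array(shape, spacing, ctr, semi_mm,
                               pr$irregularity, pr$major_axis, pr$phase)
        if (!any(tm$mask) || any(tm$mask & !liver_arr) ||
            any(tm$mask & occupied)) next
        placed <- TRUE; break
      }
      if (!placed)
        stopf("could not place tumor %d (diameter %.2f cm) inside the liver",
              t, D)
      occupied <- occupied | tm$mask
      # paint the tumor: offset + Gaussian blob mixture + core noise + rim
      bx <- tm$box
      nb <- pr$n_blobs
      blob_field <- array(0, dim(tm$rho))
      ctr_box <- ctr - c(bx$z[1], bx$y[1], bx$x[1]) + 1
      bz <- matrix(stats::runif(nb * 3, -0.6, 0.6), ncol = 3)
      sgn <- rep_len(c(1, -1), nb)
      zz <- (bx$z - bx$z[1] + 1 - ctr_box[1]) * spacing[1]
      yy <- (bx$y - bx$y[1] + 1 - ctr_box[2]) * spacing[2]
      xx <- (bx$x - bx$x[1] + 1 - ctr_box[3]) * spacing[3]
      for (bix in seq_len(nb)) {
        bc <- bz[bix, ] * semi_mm              # blob centre in mm
        d2 <- outer(outer((zz - bc[1])^2, (yy - bc[2])^2, `+`),
                    (xx - bc[3])^2, `+`)
        blob_field <- blob_field +
          sgn[bix] * pr$blob_amplitude * exp(-d2 / (2 * pr$blob_width_mm^2))
      }
      # fixed-amplitude in-plane grain whose wavelength carries the
      # texture-scale label (no z variation: 2.5 mm slices would alias it)
      lam <- pr$grain_wavelength_mm
      gyx <- outer(sin(2 * pi * yy / lam), sin(2 * pi * xx / lam))
      grain <- array(rep(as.vector(gyx), each = length(zz)),
                     c(length(zz), length(yy), length(xx)))
      grain <- 12 * grain
      delta <- pr$intensity_offset + blob_field + grain +
        stats::rnorm(length(blob_field), 0, pr$core_noise_sd)
      if (pr$inclusions > 0) {
        for (ii in seq_len(sample(2:4, 1))) {
          ic <- stats::runif(3, -0.55, 0.55) * semi_mm
          ir <- stats::runif(1, 1.5, 2.5)
          d2 <- outer(outer((zz - ic[1])^2, (yy - ic[2])^2, `+`),
                      (xx - ic[3])^2, `+`)
          delta[d2 < ir^2] <- delta[d2 < ir^2] + 90
        }
      }
      if (pr$rim > 0) {
        shell <- tm$inside & tm$rho >= 0.8
        delta[shell] <- delta[shell] + 35
      }
      sub <- vol[bx$z, bx$y, bx$x]
      sub[tm$inside] <- sub[tm$inside] + delta[tm$inside]
      vol[bx$z, bx$y, bx$x] <- sub
      tumors[[t]] <- mask(tm$mask, spacing)
      sizes[t] <- D
      params[[t]] <- pr
      labels <- rbind(labels, phantom_labels_from_params(pr))
    }
  }

  vol <- vol + stats::rnorm(length(vol), 0, config$noise_sd)
  structure(list(volume = volume(vol, spacing),
                 liver = mask(liver_arr, spacing),
                 segments = labelmap(seg_arr, spacing),
                 tumors = tumors,
                 true_size_cm = sizes,
                 labels = labels,
                 params = params,
                 config = config),
            class = "hep_phantom")
}

#' @export
print.hep_phantom <- function(x, ...) {
  cat(sprintf("<Phantom %s: %d liver voxels, %d tumor(s)%s>\n",
              paste(dim(x$volume$data), collapse = "x"),
              sum(x$liver$data), length(x$tumors),
              if (length(x$true_size_cm))
                sprintf(", sizes %s cm",
                        paste(sprintf("%.2f", x$true_size_cm), collapse = ", "))
              else ""))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' Cases use seeds `seed, seed + 1, ...`. For cohorts of 30 or more the
#' generator checks that every characteristic label has prevalence in
#' `[0.2, 0.8]` and re-draws the cohort (derived seeds) in the rare event
#' the check fails.
#'
#' @param n number of cases (>= 1).
#' @param config base [phantom_config()]; its seed seeds case 1.
#' @export
make_cohort <- function(n, config = phantom_config()) {
  if (n < 1) stopf("n must be >= 1")
  for (attempt in 0:19) {
    cases <- lapply(seq_len(n), function(i) {
      cfg <- config
      cfg$seed <- if (attempt == 0) config$seed + i - 1L
                  else derive_seed(config$seed, i + attempt * n)
      make_phantom(cfg)
    })
    if (n < 30) return(cases)
    lab <- do.call(rbind, lapply(cases, function(cs) cs$labels))
    prev <- colMeans(lab)
    if (all(prev >= 0.2 & prev <= 0.8)) return(cases)
  }
  stopf("could not reach label prevalence in [0.2, 0.8] after 20 attempts")
}

#' Noisy calibration pairs for the pixel-to-centimeter size regression
#'
#' Draws `n` lengths uniformly from 5 to 300 px and returns
#' `size = b + a * length + N(0, noise_sd)`.
#'
#' @param a slope (cm per pixel).
#' @param b intercept (cm).
#' @param n number of pairs (>= 2).
#' @param noise_sd Gaussian noise on the sizes.
#' @param seed RNG seed.
#' @return data.frame with columns `length_px`, `size_cm`.
#' @export
make_calibration_pairs <- function(a, b, n, noise_sd = 0, seed = 1) {
  if (n < 2) stopf("need at least 2 calibration pairs")
  with_seed(seed, {
    len <- stats::runif(n, 5, 300)
    data.frame(length_px = len,
               size_cm = b + a * len + stats::rnorm(n, 0, noise_sd))
  })
}
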