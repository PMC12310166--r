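# Shared fixtures, built once per test run and memoized. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# Default-geometry phantom with one ~3 cm tumor.
fx_phantom3 <- function() memo("phantom3", function()
  make_phantom(phantom_config(seed = 11, tumor_diameters_cm = 3)))

# Small multi-tumor phantom for pipeline tests.
fx_phantom_multi <- function() memo("phantom_multi", function()
  make_phantom(phantom_config(seed = 23, n_tumors = 2,
                              tumor_diameter_range_cm = c(1.5, 3))))

# 30-case cohort with extracted radiomics features (the expensive fixture;
# used by the recognition tests).
fx_cohort30 <- function() memo("cohort30", function() {
  cohort <- make_cohort(30, phantom_config(seed = 100))
  cf <- cohort_features(cohort)
  list(cohort = cohort, features = cf$features, labels = cf$labels,
       sizes = cf$sizes)
})

# One tumor-bearing 64 x 64 liver-masked slice for the overfit oracle.
fx_overfit_slice <- function() memo("overfit_slice", function() {
  ph <- fx_phantom3()
  tz <- which(apply(ph$tumors[[1]]$data, 1, sum) > 0)
  zi <- tz[ceiling(length(tz) / 2)]
  full_x <- hepannot:::scale_intensity(ph$volume$data[zi, , ] *
                                         ph$liver$data[zi, , ])
  full_y <- ph$tumors[[1]]$data[zi, , ]
  ctr <- round(colMeans(which(full_y != 0, arr.ind = TRUE)))
  lo <- pmin(pmax(ctr - 31, 1), dim(full_y) - 63)
  list(x = full_x[lo[1]:(lo[1] + 63), lo[2]:(lo[2] + 63)],
       y = full_y[lo[1]:(lo[1] + 63), lo[2]:(lo[2] + 63)])
})

# MRAU-Net overfit to the single slice (200 epochs, base 16) -- the
# training oracle reused across tests.
fx_overfit_fit <- function() memo("overfit_fit", function() {
  sl <- fx_overfit_slice()
  net <- build_mraunet(net_config(dims = 2, depth = 4, base_filters = 16,
                                  seed = 1))
  train_segnet(net, list(list(x = sl$x, y = sl$y)),
               train_config(epochs = 200, seed = 1))
})

# Tiny coarse phantoms for partition training (liver only).
fx_partition_cases <- function() memo("partition_cases", function()
  make_cohort(6, phantom_config(shape = c(16, 32, 32),
                                spacing = c(5, 2.5, 2.5),
                                n_tumors = 0, seed = 400)))

fx_partition_fit <- function() memo("partition_fit", function()
  train_partition(fx_partition_cases(),
                  net_config(dims = 3, depth = 2, base_filters = 4,
                             in_channels = 4),
                  train_config(epochs = 30, batch_size = 6,
                               learning_rate = 3e-3, seed = 5)))

# Random small mask helper.
random_mask <- function(dims, p = 0.3, seed = 1) {
  set.seed(seed)
  array(stats::rbinom(prod(dims), 1, p), dims)
}

# Brute-force all-pairs diameter on a set of index points (oracle).
brute_diameter <- function(pts, scale = NULL) {
  if (nrow(pts) < 2) return(0)
  if (!is.null(scale)) pts <- sweep(pts, 2, scale, `*`)
  best <- 0
  for (i in seq_len(nrow(pts) - 1))
    best <- max(best, max(sqrt(colSums((t(pts[-seq_len(i), , drop = FALSE]) -
                                          pts[i, ])^2))))
  best
}
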