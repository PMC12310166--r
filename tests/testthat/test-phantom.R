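test_that("phantom generation is deterministic and respects invariants", {
  ph <- fx_phantom3()
  ph2 <- make_phantom(phantom_config(seed = 11, tumor_diameters_cm = 3))
  expect_identical(ph$volume$data, ph2$volume$data)
  expect_identical(ph$segments$data, ph2$segments$data)

  # tumors inside the liver
  expect_true(all(ph$tumors[[1]]$data <= ph$liver$data))
  # segments cover the liver support exactly with 8 nonempty compartments
  expect_identical(ph$segments$data > 0, ph$liver$data > 0)
  counts <- table(factor(ph$segments$data[ph$segments$data > 0],
                         levels = 1:8))
  expect_true(all(counts > 0))
  expect_equal(length(ph$labels[1, ]), 11)
})

test_that("a phantom with no tumors has an empty tumor list", {
  ph <- make_phantom(phantom_config(seed = 5, n_tumors = 0))
  expect_length(ph$tumors, 0)
  expect_length(ph$true_size_cm, 0)
  expect_equal(nrow(ph$labels), 0)
})

test_that("segment compartments are 6-connected", {
  ph <- make_phantom(phantom_config(shape = c(16, 32, 32),
                                    spacing = c(5, 2.5, 2.5),
                                    n_tumors = 0, seed = 42))
  for (k in 1:8) {
    mk <- ph$segments$data == k
    lab <- label_components(mk * 1, connectivity = 6)
    expect_equal(max(lab), 1)
  }
})

test_that("forced tumor diameter matches the physical mask extent", {
  ph <- fx_phantom3()
  d_cm <- longest_diameter(ph$tumors[[1]], "volume3d",
                           spacing = ph$volume$spacing) / 10
  expect_gte(d_cm, 2.8)
  expect_lte(d_cm, 3.2)
  # and the recorded truth is the generating major axis
  expect_equal(ph$true_size_cm[1], 3)
})

test_that("ground-truth size equals the max pairwise border distance", {
  ph <- fx_phantom3()
  bp <- hepannot:::border_voxels(ph$tumors[[1]]$data)
  d_brute <- brute_diameter(matrix(as.numeric(bp), ncol = 3),
                            scale = ph$volume$spacing)
  tol <- 2 * sqrt(sum(ph$volume$spacing^2))     # two voxel diagonals
  expect_lt(abs(d_brute - ph$true_size_cm[1] * 10), tol)
})

test_that("cohorts reuse sequential seeds and balance label prevalence", {
  cfg <- phantom_config(seed = 300, shape = c(16, 32, 32),
                        spacing = c(5, 2.5, 2.5),
                        tumor_diameter_range_cm = c(1, 3))
  c1 <- make_cohort(3, cfg)
  expect_identical(c1[[1]]$volume$data, make_phantom(cfg)$volume$data)
  c2 <- make_cohort(3, cfg)
  expect_identical(c1[[2]]$volume$data, c2[[2]]$volume$data)

  co <- fx_cohort30()
  prev <- colMeans(co$labels)
  expect_true(all(prev >= 0.2 & prev <= 0.8))
  expect_true(all(colSums(co$labels) >= 1))
  expect_true(all(colSums(1 - co$labels) >= 1))
})

test_that("calibration pairs follow the linear model", {
  p0 <- make_calibration_pairs(0.0748, -0.2011, 10, noise_sd = 0, seed = 3)
  expect_equal(p0$size_cm, -0.2011 + 0.0748 * p0$length_px)
  expect_error(make_calibration_pairs(1, 0, 1), "at least 2")

  # least-squares refit recovers the generating coefficients
  p <- make_calibration_pairs(0.0748, -0.2011, 50, noise_sd = 0.05,
                              seed = 9)
  fit <- fit_size_regression(p)
  expect_lt(abs(fit$a - 0.0748), 0.01)
  expect_lt(abs(fit$b + 0.2011), 0.01)
})
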