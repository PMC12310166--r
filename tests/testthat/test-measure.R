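test_that("longest diameter matches brute-force all-pairs on known masks", {
  m <- array(0, c(3, 8, 8))
  m[2, 1, 1] <- 1
  expect_equal(longest_diameter(m, "slice2d"), 0)  # single voxel
  m[2, 4, 5] <- 1                                  # (0,0) to (3,4): 5 px
  expect_equal(longest_diameter(m, "slice2d"), 5)
  expect_equal(longest_diameter(m, "volume3d"), 5)
  expect_error(longest_diameter(array(0, c(2, 2, 2))), "empty")
})

test_that("hull-pruned diameter equals brute force on random masks", {
  for (s in 1:25) {
    m <- random_mask(c(4, 10, 10), p = 0.25, seed = s)
    if (!any(m != 0)) next
    got3 <- longest_diameter(m, "volume3d")
    bp <- hepannot:::border_voxels(m)
    expect_equal(got3, brute_diameter(matrix(as.numeric(bp), ncol = 3)))
  }
})

test_that("longest diameter is invariant to translation and 90-degree
           rotation", {
  m <- array(0, c(2, 12, 12))
  m[1, 3:6, 2:9] <- 1
  d0 <- longest_diameter(m, "slice2d")
  mt <- array(0, c(2, 12, 12)); mt[2, 5:8, 4:11] <- 1
  expect_equal(longest_diameter(mt, "slice2d"), d0)
  mr <- array(0, c(2, 12, 12)); mr[1, 2:9, 3:6] <- 1  # transposed in-plane
  expect_equal(longest_diameter(mr, "slice2d"), d0)
})

test_that("size regression evaluates the printed linear form", {
  r <- size_regression()
  expect_equal(size_cm(0, r), -0.2011)
  expect_equal(size_cm(1, r) - size_cm(0, r), 0.0748)
  expect_equal(size_cm(100, r), -0.2011 + 7.48)
  # affine in the length
  expect_equal(size_cm(60, r) - size_cm(0, r),
               3 * (size_cm(20, r) - size_cm(0, r)))
})

test_that("least-squares fit is exact on collinear data and beats any
           constant predictor", {
  pairs <- data.frame(length_px = c(10, 20, 40), size_cm = 1 + 0.1 * c(10, 20, 40))
  fit <- fit_size_regression(pairs)
  expect_equal(fit$a, 0.1)
  expect_equal(fit$b, 1)
  expect_error(fit_size_regression(data.frame(length_px = c(5, 5),
                                              size_cm = c(1, 2))),
               "distinct")
  p <- make_calibration_pairs(0.08, -0.1, 40, noise_sd = 0.2, seed = 21)
  fit2 <- fit_size_regression(p)
  pred <- size_cm(p$length_px, fit2)
  mae_fit <- mean(abs(pred - p$size_cm))
  for (const in stats::quantile(p$size_cm, c(0.25, 0.5, 0.75)))
    expect_lte(mae_fit, mean(abs(const - p$size_cm)))
})
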