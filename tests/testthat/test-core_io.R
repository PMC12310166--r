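test_that("volumes and masks round-trip through NIfTI", {
  set.seed(1)
  v <- volume(array(rnorm(64), c(4, 4, 4)), spacing = c(5.0, 0.7, 0.7))
  tf <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, tf)
  v2 <- read_volume(tf)
  expect_equal(v2$data, v$data, tolerance = 1e-6)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)

  # all-zero, single-voxel and random masks round-trip bit-exactly
  for (m in list(mask(array(0L, c(4, 4, 4))),
                 mask(array(c(1L, rep(0L, 63)), c(4, 4, 4))),
                 mask(random_mask(c(8, 8, 8), seed = 3)))) {
    tm <- withr::local_tempfile(fileext = ".nii.gz")
    write_mask(m, tm)
    expect_identical(read_mask(tm)$data, m$data)
  }
})

test_that("read_volume rejects missing files and non-3-D payloads", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")), "not found")
  tf <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(0, 4, 4)), tf)
  expect_error(read_volume(tf), "3-D")
})

test_that("label map projections partition the nonzero support", {
  ph <- fx_phantom3()
  lm <- ph$segments
  support <- lm$data > 0
  acc <- array(0L, dim(lm$data))
  for (k in 1:8) {
    mk <- segment_mask(lm, k)
    expect_true(all(mk$data[!support] == 0))
    acc <- acc + mk$data
  }
  # pairwise disjoint and covering: every support voxel hit exactly once
  expect_true(all(acc[support] == 1L))
  expect_true(all(acc[!support] == 0L))
})

test_that("annotation reports round-trip through JSON", {
  tf <- withr::local_tempfile(fileext = ".json")
  write_report(list(), tf)
  expect_length(read_report(tf), 0)

  a1 <- annotation(1, 3.1, c(6, 5), rep(c(0L, 1L), c(6, 5)),
                   provenance = list(tumor = "mraunet-2D"))
  a2 <- annotation(2, 0.8, 3, rep(0L, 11))
  write_report(list(a1, a2), tf)
  back <- read_report(tf)
  expect_length(back, 2)
  expect_equal(back[[1]]$locations, c(5L, 6L))  # sorted ascending
  expect_equal(back[[1]]$size_cm, 3.1)
  expect_equal(back[[2]]$characteristics, rep(0L, 11))

  expect_error(annotation(1, 1, 1, c(0, 1)), "length 11")
  expect_error(annotation(1, 1, 9, rep(0, 11)), "subset")
})
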