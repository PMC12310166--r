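test_that("coverage ratio counts voxels", {
  a <- array(0, c(2, 3, 2)); b <- a
  a[1:6] <- 1; b[1:6] <- 1
  expect_equal(coverage_ratio(a, b), 1)
  b2 <- array(0, c(2, 3, 2)); b2[7:12] <- 1
  expect_equal(coverage_ratio(a, b2), 0)
  aa <- array(0, c(2, 3, 2)); aa[1:3] <- 1
  bb <- array(1, c(2, 3, 2))
  expect_equal(coverage_ratio(aa, bb), 3 / 12)
  expect_error(coverage_ratio(a, array(0, c(2, 3, 2))), "empty")
})

test_that("locate implements the strict quarter-overlap rule", {
  seg <- array(0L, c(2, 4, 10))
  seg[, 1:2, ] <- 5L; seg[, 3:4, ] <- 6L
  lm <- labelmap(seg)
  t1 <- array(0, c(2, 4, 10)); t1[1, 1, 1:4] <- 1   # wholly in segment 5
  expect_equal(locate(t1, lm), 5L)
  t2 <- array(0, c(2, 4, 10)); t2[1, 2, 1:5] <- 1; t2[1, 3, 1:5] <- 1
  expect_equal(locate(t2, lm), c(5L, 6L))           # 50/50 split
  # 26/74 split: both reported; exactly 25/75: only the dominant (strict >)
  tA <- array(0, c(2, 4, 10))
  tA[1, 1, 1:10] <- 1; tA[1, 2, 1:3] <- 1              # 13 voxels in seg 5
  tA[, 3, 1:10] <- 1; tA[1, 4, 1:9] <- 1; tA[2, 4, 1:8] <- 1  # 37 in seg 6
  expect_equal(sum(tA & seg == 5) / sum(tA), 0.26)
  expect_equal(locate(tA, lm), c(5L, 6L))
  tB <- array(0, c(2, 4, 10))
  tB[1, 1, 1:10] <- 1; tB[1, 2, 1:2] <- 1              # 12 voxels in seg 5
  tB[, 3, 1:10] <- 1; tB[, 4, 1:8] <- 1                # 36 in seg 6
  expect_equal(sum(tB & seg == 5) / sum(tB), 0.25)
  expect_equal(locate(tB, lm), 6L)
  expect_error(locate(array(0, dim(seg)), lm), "empty")
})

test_that("locate matches a brute-force fraction oracle on random cases", {
  set.seed(31)
  for (rep in 1:100) {
    seg <- array(sample(1:8, 4 * 6 * 6, replace = TRUE), c(4, 6, 6))
    tum <- array(rbinom(4 * 6 * 6, 1, 0.2), c(4, 6, 6))
    if (!any(tum != 0)) next
    got <- locate(tum, labelmap(seg))
    frac <- vapply(1:8, function(k) sum(tum == 1 & seg == k) / sum(tum),
                   numeric(1))
    want <- which(frac > 0.25)
    if (length(want) == 0) want <- which.max(frac)
    expect_equal(got, sort(as.integer(want)))
  }
})

test_that("locate is invariant under consistent segment relabeling", {
  ph <- fx_phantom3()
  tum <- ph$tumors[[1]]
  base <- locate(tum, ph$segments)
  perm <- c(3L, 1L, 4L, 2L, 8L, 6L, 7L, 5L)
  seg2 <- array(0L, dim(ph$segments$data))
  for (k in 1:8) seg2[ph$segments$data == k] <- perm[k]
  expect_equal(locate(tum, labelmap(seg2, ph$segments$spacing)),
               sort(perm[base]))
})

test_that("oracle per-segment models reproduce the ground-truth partition", {
  ph <- make_phantom(phantom_config(shape = c(16, 32, 32),
                                    spacing = c(5, 2.5, 2.5),
                                    n_tumors = 0, seed = 77))
  oracles <- lapply(1:8, function(k)
    oracle_segnet(segment_mask(ph$segments, k), id = sprintf("oracle%d", k)))
  lm <- partition(oracles, ph$volume, ph$liver)
  expect_identical(lm$data, ph$segments$data)
  # partition contract: liver voxels labelled 1..8, background 0
  expect_true(all(lm$data[ph$liver$data == 1] %in% 1:8))
  expect_true(all(lm$data[ph$liver$data == 0] == 0))
})

test_that("argmax ties break toward the lowest segment label", {
  ph <- make_phantom(phantom_config(shape = c(16, 32, 32),
                                    spacing = c(5, 2.5, 2.5),
                                    n_tumors = 0, seed = 78))
  all_on <- oracle_segnet(ph$liver, id = "on")   # probability 1 on liver
  off <- oracle_segnet(array(0, dim(ph$liver$data)), id = "off")
  models <- c(list(off, all_on, off, all_on), rep(list(off), 4))
  lm <- partition(models, ph$volume, ph$liver)
  expect_true(all(lm$data[ph$liver$data == 1] == 2L))
})

test_that("micro-averaged location accuracy counts decisions", {
  same <- list(c(1, 2), c(5))
  r <- location_accuracy(same, same)
  expect_equal(r, list(precision = 1, recall = 1, accuracy = 1))
  r2 <- location_accuracy(list(c(1), c(2)), list(c(3), c(4)))
  expect_equal(r2$precision, 0)
  expect_equal(r2$recall, 0)
  # one extra predicted segment among 4 true over 2 tumors
  r3 <- location_accuracy(list(c(1, 2, 3), c(4, 5)), list(c(1, 2), c(4, 5)))
  expect_equal(r3$precision, 4 / 5)
  expect_equal(r3$recall, 1)
  expect_equal(r3$accuracy, 15 / 16)
})
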