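test_that("information gain matches direct entropy arithmetic", {
  # feature perfectly separating a balanced label: 1 bit
  y <- rep(c(0, 1), each = 10)
  f <- c(rnorm(10, 0), rnorm(10, 100))
  expect_equal(info_gain(f, y), 1)
  # independent feature on a balanced label: near zero
  set.seed(4)
  expect_lt(info_gain(rnorm(200), rep(c(0, 1), 100)), 0.05)
  # constructed 2-bin contingency table: H(y) - H(y|bin)
  f2 <- c(1, 2, 3, 4, 10, 11, 12, 13)
  y2 <- c(0, 0, 0, 1, 1, 1, 1, 0)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  want <- h(c(0.5, 0.5)) -
    (0.5 * h(c(3, 1) / 4) + 0.5 * h(c(1, 3) / 4))
  expect_equal(info_gain(f2, y2), want)
  # bounded by H(label)
  for (s in 1:20) {
    set.seed(s)
    ff <- rnorm(30); yy <- rbinom(30, 1, 0.4)
    ig <- info_gain(ff, yy)
    expect_gte(ig, 0)
    expect_lte(ig, h(table(yy) / 30) + 1e-12)
  }
})

test_that("pearson score is the absolute correlation", {
  y <- rep(c(0, 1), 8)
  expect_equal(pearson_score(y, y), 1)
  expect_equal(pearson_score(1 - y, y), 1)
  set.seed(5)
  f <- rnorm(16)
  expect_equal(pearson_score(f, y), abs(stats::cor(f, y)))
  expect_error(pearson_score(rep(1, 16), y), "variance")
})

test_that("selection ranks a planted label copy first under both
           selectors", {
  set.seed(6)
  m <- matrix(rnorm(40 * 30), 40, 30)
  y <- rbinom(40, 1, 0.5)
  m[, 17] <- y + rnorm(40, sd = 1e-3)
  labs <- cbind(y)
  for (sel in c("ig", "pcc")) {
    idx <- select_features(m, labs, sel, k = 5)
    expect_equal(idx[[1]][1], 17)
    expect_identical(idx, select_features(m, labs, sel, k = 5))
  }
  # k = ncol keeps everything, ties in column order
  all_idx <- select_features(m, labs, "ig", k = 100)
  expect_equal(sort(all_idx[[1]]), 1:30)
})

test_that("binary relevance trains, memorizes separable data and is
           deterministic", {
  set.seed(7)
  n <- 40
  lab <- matrix(rbinom(n * 3, 1, 0.5), n, 3)
  feat <- cbind(lab + matrix(rnorm(n * 3, sd = 0.05), n, 3),
                matrix(rnorm(n * 20), n, 20))
  for (li in 1:3) if (length(unique(lab[, li])) < 2) lab[1, li] <- 1 - lab[1, li]
  fit <- train_multilabel(feat, lab, base = "svm", selector = "ig", k = 4)
  pred <- predict_labels(fit, feat)
  expect_equal(dim(pred), dim(lab))
  expect_gte(eval_multilabel(pred, lab)$f1, 0.99)
  # single-row prediction has width n_labels
  expect_length(predict_labels(fit, feat[1, ]), 3)
  expect_error(predict_labels(fit, feat[1, -1]), "features")
  # deterministic random forest under a fixed seed
  f1 <- train_multilabel(feat, lab, base = "rf", k = 4, seed = 11)
  f2 <- train_multilabel(feat, lab, base = "rf", k = 4, seed = 11)
  expect_identical(predict_labels(f1, feat), predict_labels(f2, feat))
  # selector swap changes only the selected indices, not the interface
  fp <- train_multilabel(feat, lab, base = "svm", selector = "pcc", k = 4)
  expect_equal(dim(predict_labels(fp, feat)), dim(lab))
  expect_error(train_multilabel(feat, matrix(1, n, 2)), "single class")
})

test_that("feature extraction is deterministic with stable names", {
  ph <- fx_phantom3()
  f1 <- extract_features(ph$volume, ph$tumors[[1]])
  f2 <- extract_features(ph$volume, ph$tumors[[1]])
  expect_identical(f1, f2)
  expect_false(any(is.na(f1)))
  expect_error(extract_features(ph$volume,
                                mask(array(c(1, rep(0, 7)), c(2, 2, 2)))),
               "degenerate|shape")
})

test_that("first-order features respond to the intensity distribution", {
  a <- array(50, c(6, 6, 6))
  m <- array(0, c(6, 6, 6)); m[2:5, 2:5, 2:5] <- 1
  v <- volume(a)
  f <- extract_features(v, mask(m), radiomics_config(log_sigmas_mm = 1,
                                                     wavelet = FALSE))
  expect_equal(unname(f["original_firstorder_Variance"]), 0)
  expect_equal(unname(f["original_firstorder_Mean"]), 50)
  expect_equal(unname(f["original_firstorder_Range"]), 0)
})

test_that("a near-spherical tumor has sphericity close to 1", {
  sp <- c(2.5, 1, 1)
  d <- c(24, 48, 48); ctr <- (d + 1) / 2
  zz <- ((1:d[1]) - ctr[1]) * sp[1]
  yy <- ((1:d[2]) - ctr[2]) * sp[2]
  xx <- ((1:d[3]) - ctr[3]) * sp[3]
  sphere <- (outer(outer(zz^2, yy^2, `+`), xx^2, `+`) <= 15^2) * 1
  f <- hepannot:::shape_features(sphere, sp)
  expect_lt(abs(f[["Sphericity"]] - 1), 0.05)
  expect_lt(abs(f[["Maximum3DDiameter"]] - 30), 2 * sqrt(sum(sp^2)))
})
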