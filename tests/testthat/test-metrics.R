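test_that("dice matches brute-force arithmetic and handles empties", {
  a <- array(0, c(2, 2, 2)); b <- a
  expect_equal(dice(a, b), 1)           # empty vs empty
  a[1:4] <- 1
  expect_equal(dice(a, a), 1)
  b[5:8] <- 1
  expect_equal(dice(a, b), 0)           # disjoint
  b <- array(0, c(2, 2, 2)); b[3:6] <- 1  # |a|=|b|=4, overlap 2
  expect_equal(dice(a, b), 0.5)
  expect_error(dice(a, array(0, c(2, 2, 3))), "shape")
})

test_that("dice agrees with set arithmetic on all 2x2x2 mask pairs", {
  combos <- as.matrix(expand.grid(rep(list(0:1), 8)))
  set.seed(4)
  ii <- sample(nrow(combos), 40)
  jj <- sample(nrow(combos), 40)
  for (t in seq_along(ii)) {
    a <- array(combos[ii[t], ], c(2, 2, 2))
    b <- array(combos[jj[t], ], c(2, 2, 2))
    expected <- if (sum(a) + sum(b) == 0) 1
                else 2 * sum(a * b) / (sum(a) + sum(b))
    expect_equal(dice(a, b), expected)
    expect_equal(dice(a, b), dice(b, a))  # symmetry
  }
})

test_that("bce matches its closed form", {
  expect_lt(bce(1, 1 - 1e-9), 1e-6)
  expect_equal(bce(1, 0.5), log(2))
  expect_equal(bce(0, 0.9), -log(0.1))
  expect_true(all(bce(c(0, 1, 1), c(0.2, 0.7, 0.01)) >= 0))
})

test_that("mcc matches the confusion-count formula and stays in [-1, 1]", {
  expect_equal(mcc(list(TP = 5, TN = 5, FP = 0, FN = 0)), 1)
  expect_equal(mcc(list(TP = 1, TN = 1, FP = 1, FN = 1)), 0)
  expect_equal(mcc(list(TP = 6, TN = 3, FP = 1, FN = 2)),
               (6 * 3 - 1 * 2) / sqrt((6 + 2) * (6 + 1) * (3 + 2) * (3 + 1)))
  expect_equal(mcc(list(TP = 0, TN = 0, FP = 0, FN = 5)), 0)  # degenerate
  set.seed(7)
  for (i in 1:100) {
    cnt <- as.list(stats::setNames(sample(0:20, 4, replace = TRUE),
                                   c("TP", "FP", "TN", "FN")))
    v <- mcc(cnt)
    expect_gte(v, -1); expect_lte(v, 1)
    # swapping (TP<->TN, FP<->FN) leaves MCC unchanged
    expect_equal(v, mcc(list(TP = cnt$TN, TN = cnt$TP,
                             FP = cnt$FN, FN = cnt$FP)))
  }
})

test_that("combined loss vanishes on perfect hard predictions and is
           monotone toward the truth", {
  set.seed(9)
  y <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  expect_lt(combined_loss(y, y), 1e-5)
  # w = (1,0,0), uniform 0.5: loss = 1 - soft-dice
  p05 <- array(0.5, dim(y))
  sd_expect <- 2 * sum(0.5 * y) / (sum(p05) + sum(y))
  expect_equal(combined_loss(p05, y, loss_weights(1, 0, 0)), 1 - sd_expect)
  # loss decreases as prob interpolates from 0.5 toward the truth
  lambdas <- seq(0, 1, by = 0.2)
  losses <- vapply(lambdas, function(l)
    combined_loss((1 - l) * p05 + l * y, y), numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("soft MCC on hard probabilities equals count MCC", {
  set.seed(11)
  for (i in 1:20) {
    p <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
    y <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
    counts <- list(TP = sum(p & y), FP = sum(p & !y),
                   TN = sum(!p & !y), FN = sum(!p & y))
    expect_equal(hepannot:::soft_mcc_val(p, y), mcc(counts))
  }
})

test_that("example-based multi-label metrics follow the per-record rule", {
  tr <- matrix(c(1, 0, 1, 0, 1, 0), 2, 3, byrow = TRUE)
  expect_equal(eval_multilabel(tr, tr),
               list(precision = 1, recall = 1, accuracy = 1, f1 = 1))
  comp <- 1 - tr
  r <- eval_multilabel(comp, tr)
  expect_equal(r$precision, 0); expect_equal(r$recall, 0)
  expect_equal(r$f1, 0)
  # one record with precision 1 and recall 1/2 has F1 = 2/3
  pred <- matrix(c(1, 0, 0, 0), 1)
  tru <- matrix(c(1, 1, 0, 0), 1)
  expect_equal(eval_multilabel(pred, tru)$f1, 2 / 3)
  # both-empty record contributes 1.0
  expect_equal(eval_multilabel(matrix(0, 1, 4), matrix(0, 1, 4))$f1, 1)
})

test_that("mae/rmse follow their definitions with rmse >= mae", {
  expect_equal(mae_rmse(1:3, 1:3), list(mae = 0, rmse = 0))
  expect_equal(mae_rmse(c(2, 0), c(1, 1)), list(mae = 1, rmse = 1))
  expect_equal(mae_rmse(c(0, 2), c(0, 0)), list(mae = 1, rmse = sqrt(2)))
  set.seed(13)
  for (i in 1:25) {
    r <- mae_rmse(rnorm(10), rnorm(10))
    expect_gte(r$rmse, r$mae)
  }
  expect_error(mae_rmse(numeric(0), numeric(0)), "nonzero")
})
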