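## Loss coefficients (Dice, binary cross-entropy, Matthews correlation) and
## evaluation metrics (dice, MAE/RMSE, example-based multi-label metrics).

BCE_EPS <- 1e-7

mask_values <- function(x) {
  if (inherits(x, "hep_mask")) x$data else x
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b binary masks or arrays of equal shape.
#' @export
dice <- function(a, b) {
  av <- mask_values(a); bv <- mask_values(b)
  if (!identical(dim(av), dim(bv))) stopf("dice: shape mismatch")
  sa <- sum(av != 0); sb <- sum(bv != 0)
  if (sa + sb == 0) return(1)
  2 * sum(av != 0 & bv != 0) / (sa + sb)
}

#' Binary cross-entropy of a predicted probability against a binary truth
#'
#' `-( (1-y) log(1-p) + y log p )`, with p clipped to
#' `[1e-7, 1 - 1e-7]`. Vectorized; returns per-element values.
#'
#' @param y binary truth (0/1), any shape.
#' @param p predicted probability in `[0,1]`, same shape.
#' @export
bce <- function(y, p) {
  p <- pmin(pmax(p, BCE_EPS), 1 - BCE_EPS)
  -((1 - y) * log(1 - p) + y * log(p))
}

#' Matthews correlation coefficient from confusion counts
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))`,
#' with the convention that a zero denominator yields 0.
#'
#' @param counts a list/vector with elements TP, FP, TN, FN.
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, fp, tn, fn) < 0)) stopf("mcc: negative counts")
  num <- tp * tn - fp * fn
  den <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  if (den <= 0) return(0)
  num / sqrt(den)
}

#' Loss weights for the combined segmentation loss
#'
#' The three coefficients weight the Dice, binary cross-entropy and Matthews
#' correlation terms. Defaults are (1, 1, 1); the MCC term is mapped from
#' `[-1, 1]` to `[0, 1]` so the three terms have comparable magnitude.
#'
#' @param w_dice,w_bce,w_mcc non-negative weights; at least one positive.
#' @export
loss_weights <- function(w_dice = 1, w_bce = 1, w_mcc = 1) {
  w <- c(w_dice = w_dice, w_bce = w_bce, w_mcc = w_mcc)
  if (any(w < 0) || all(w == 0)) stopf("invalid loss weights")
  as.list(w)
}

# Soft (probabilistic) dice and MCC used by both the public combined loss
# and the training graph; counts are replaced by sums of probabilities.
soft_dice_val <- function(p, y) {
  s <- sum(p * y)
  den <- sum(p) + sum(y)
  if (den == 0) return(1)
  2 * s / den
}

soft_mcc_val <- function(p, y, eps = 1e-8) {
  tp <- sum(p * y); fp <- sum(p * (1 - y))
  fn <- sum((1 - p) * y); tn <- sum((1 - p) * (1 - y))
  num <- tp * tn - fp * fn
  den <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  if (den <= eps) return(0)
  num / sqrt(den)
}

#' Combined segmentation loss
#'
#' `w_dice (1 - softDice) + w_bce mean(BCE) + w_mcc (1 - softMCC)/2`,
#' where the soft variants substitute voxel probabilities for hard counts.
#' This is the quantity minimized by [train_segnet()].
#'
#' @param prob probability map (array in `[0,1]`).
#' @param truth binary mask or array of the same shape.
#' @param w a [loss_weights()] record.
#' @export
combined_loss <- function(prob, truth, w = loss_weights()) {
  y <- mask_values(truth); p <- if (is.list(prob)) prob$data else prob
  if (!identical(dim(p), dim(y))) stopf("combined_loss: shape mismatch")
  w$w_dice * (1 - soft_dice_val(p, y)) +
    w$w_bce * mean(bce(y, p)) +
    w$w_mcc * (1 - soft_mcc_val(p, y)) / 2
}

#' Mean absolute error and root-mean-squared error
#'
#' @param pred,truth numeric vectors of equal nonzero length.
#' @return list with elements `mae` and `rmse`.
#' @export
mae_rmse <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth))
    stopf("mae_rmse: lengths must be equal and nonzero")
  e <- pred - truth
  list(mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

#' Example-based multi-label evaluation
#'
#' Per-record precision, recall, F1 (harmonic mean per record, then
#' averaged) and example accuracy `|Y n Z| / |Y u Z|`. A record whose
#' predicted and true positive sets are both empty contributes 1 to every
#' metric.
#'
#' @param pred,truth binary matrices (records x labels) or lists of equal
#'   length binary vectors.
#' @return list with precision, recall, accuracy, f1.
#' @export
eval_multilabel <- function(pred, truth) {
  pm <- if (is.matrix(pred)) pred else do.call(rbind, pred)
  tm <- if (is.matrix(truth)) truth else do.call(rbind, truth)
  if (!all(dim(pm) == dim(tm))) stopf("eval_multilabel: dimension mismatch")
  n <- nrow(pm)
  pr <- re <- f1 <- ac <- numeric(n)
  for (i in seq_len(n)) {
    z <- pm[i, ] != 0; y <- tm[i, ] != 0
    inter <- sum(z & y); un <- sum(z | y)
    if (sum(z) == 0 && sum(y) == 0) {
      pr[i] <- re[i] <- f1[i] <- ac[i] <- 1
    } else {
      pr[i] <- if (sum(z) == 0) 0 else inter / sum(z)
      re[i] <- if (sum(y) == 0) 0 else inter / sum(y)
      f1[i] <- if (pr[i] + re[i] == 0) 0 else 2 * pr[i] * re[i] / (pr[i] + re[i])
      ac[i] <- inter / un
    }
  }
  list(precision = mean(pr), recall = mean(re),
       accuracy = mean(ac), f1 = mean(f1))
}
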