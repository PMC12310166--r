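## Multi-label recognition of tumor characteristics: univariate feature
## selection (information gain with a median split, or absolute Pearson
## correlation) followed by binary-relevance classification — one base
## classifier per label.

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a feature for a binary label (bits)
#'
#' The feature is discretized by a median split (two bins) and the gain is
#' `H(label) - H(label | bin)`; always in `[0, H(label)]`.
#'
#' @param feature numeric vector.
#' @param label binary vector of the same length.
#' @export
info_gain <- function(feature, label) {
  if (length(feature) != length(label)) stopf("info_gain: length mismatch")
  y <- as.integer(label != 0)
  h <- entropy_bits(table(y) / length(y))
  b <- feature > stats::median(feature)
  hc <- 0
  for (side in c(TRUE, FALSE)) {
    sel <- b == side
    if (!any(sel)) next
    hc <- hc + mean(sel) * entropy_bits(table(y[sel]) / sum(sel))
  }
  max(0, h - hc)
}

#' Absolute Pearson correlation of a feature with a binary label
#'
#' @param feature numeric vector with nonzero variance.
#' @param label binary vector with both classes present.
#' @export
pearson_score <- function(feature, label) {
  if (length(feature) != length(label)) stopf("pearson_score: length mismatch")
  if (stats::sd(feature) == 0 || stats::sd(label) == 0)
    stopf("pearson_score: zero variance")
  abs(stats::cor(feature, as.numeric(label != 0)))
}

#' Select the top-k features per label
#'
#' Scores every column independently for each label with the chosen
#' selector and keeps the `k` best, ties broken by column order. Columns
#' with zero variance score 0 under either selector (they carry no signal)
#' rather than erroring.
#'
#' @param m feature matrix (tumors x features).
#' @param labels binary label matrix (tumors x n_labels).
#' @param selector `"ig"` or `"pcc"`.
#' @param k number of features per label.
#' @return list of integer index vectors, one per label.
#' @export
select_features <- function(m, labels, selector = c("ig", "pcc"), k = 50) {
  selector <- match.arg(selector)
  if (k < 1) stopf("select_features: k must be >= 1")
  k <- min(k, ncol(m))
  sds <- apply(m, 2, stats::sd)
  lapply(seq_len(ncol(labels)), function(li) {
    y <- labels[, li]
    score <- vapply(seq_len(ncol(m)), function(j) {
      if (sds[j] == 0) return(0)
      if (selector == "ig") info_gain(m[, j], y)
      else if (stats::sd(y) == 0) 0 else abs(stats::cor(m[, j], y))
    }, numeric(1))
    order(-score, seq_along(score))[seq_len(k)]
  })
}

fit_base <- function(base, x, y, seed) {
  y <- factor(y, levels = c(0, 1))
  switch(base,
    svm = e1071::svm(x, y, kernel = "radial", scale = FALSE),
    rf = with_seed(seed, randomForest::randomForest(x, y, ntree = 200)),
    lda = {
      if (!requireNamespace("MASS", quietly = TRUE))
        stopf("base 'lda' needs the MASS package")
      MASS::lda(x, grouping = y)
    },
    nn = {
      if (!requireNamespace("nnet", quietly = TRUE))
        stopf("base 'nn' needs the nnet package")
      with_seed(seed, nnet::nnet(x, as.numeric(as.character(y)), size = 5,
                                 maxit = 200, decay = 1e-3, trace = FALSE))
    },
    xgboost = {
      if (!requireNamespace("xgboost", quietly = TRUE))
        stopf("base 'xgboost' needs the xgboost package")
      xgboost::xgboost(data = x, label = as.numeric(as.character(y)),
                       nrounds = 50, objective = "binary:logistic",
                       verbose = 0, nthread = 1)
    },
    stopf("unknown base classifier '%s'", base))
}

predict_base <- function(base, fit, x) {
  out <- switch(base,
    svm = as.integer(as.character(stats::predict(fit, x))),
    rf = as.integer(as.character(stats::predict(fit, x))),
    lda = as.integer(as.character(stats::predict(fit, x)$class)),
    nn = as.integer(stats::predict(fit, x) > 0.5),
    xgboost = as.integer(stats::predict(fit, x) > 0.5))
  out
}

#' Train the binary-relevance multi-label recognizer
#'
#' Selects features per label, standardizes them, and fits one base
#' classifier per label. Supported bases: `"svm"` (radial kernel),
#' `"rf"` (random forest), `"lda"`, `"nn"` (single-hidden-layer), and
#' `"xgboost"`.
#'
#' @param m feature matrix (tumors x features).
#' @param labels binary matrix (tumors x 11).
#' @param base base classifier name.
#' @param selector `"ig"` or `"pcc"`.
#' @param k features kept per label.
#' @param seed RNG seed for stochastic bases.
#' @return a `hep_multilabel_model`.
#' @export
train_multilabel <- function(m, labels, base = "svm", selector = "ig",
                             k = 50, seed = 1) {
  if (nrow(m) != nrow(labels)) stopf("train_multilabel: row mismatch")
  for (li in seq_len(ncol(labels)))
    if (length(unique(labels[, li])) < 2)
      stopf("label %d has a single class in the training data", li)
  sel <- select_features(m, labels, selector, k)
  fits <- vector("list", ncol(labels))
  for (li in seq_len(ncol(labels))) {
    x <- m[, sel[[li]], drop = FALSE]
    mu <- colMeans(x); sdev <- apply(x, 2, stats::sd); sdev[sdev == 0] <- 1
    xs <- sweep(sweep(x, 2, mu, `-`), 2, sdev, `/`)
    fits[[li]] <- list(fit = fit_base(base, xs, labels[, li],
                                      derive_seed(seed, li)),
                       mu = mu, sd = sdev)
  }
  structure(list(base = base, selector = selector, k = k,
                 selected_feature_indices = sel, fits = fits,
                 n_features = ncol(m), n_labels = ncol(labels)),
            class = "hep_multilabel_model")
}

#' @export
print.hep_multilabel_model <- function(x, ...) {
  cat(sprintf("<multilabel model: %d labels, base=%s, selector=%s, k=%d>\n",
              x$n_labels, x$base, x$selector, x$k))
  invisible(x)
}

#' Predict the characteristic bits for one tumor (or a matrix of tumors)
#'
#' @param model a `hep_multilabel_model`.
#' @param feat feature vector of the training width, or a matrix of rows.
#' @return binary vector of length `n_labels`, or a matrix.
#' @export
predict_labels <- function(model, feat) {
  fm <- if (is.matrix(feat)) feat else matrix(feat, nrow = 1)
  if (ncol(fm) != model$n_features)
    stopf("predict_labels: expected %d features, got %d",
          model$n_features, ncol(fm))
  out <- matrix(0L, nrow(fm), model$n_labels)
  for (li in seq_len(model$n_labels)) {
    f <- model$fits[[li]]
    x <- fm[, model$selected_feature_indices[[li]], drop = FALSE]
    xs <- sweep(sweep(x, 2, f$mu, `-`), 2, f$sd, `/`)
    out[, li] <- predict_base(model$base, f$fit, xs)
  }
  if (is.matrix(feat)) out else out[1, ]
}

#' Cross-validated example-based evaluation of the recognizer
#'
#' Stratification-free fold assignment by shuffled row index; feature
#' selection is redone inside every training fold. Folds where a label is
#' single-class in the training part fall back to predicting that class.
#'
#' @param m feature matrix.
#' @param labels binary matrix.
#' @param base,selector,k as in [train_multilabel()].
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return list with the pooled example-based metrics and the fold id per
#'   row.
#' @export
cv_multilabel <- function(m, labels, base = "svm", selector = "ig", k = 50,
                          folds = 5, seed = 1) {
  n <- nrow(m)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- matrix(0L, n, ncol(labels))
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- fold_id == f
    single <- vapply(seq_len(ncol(labels)),
                     function(li) length(unique(labels[tr, li])) < 2,
                     logical(1))
    if (any(!single)) {
      fit <- train_multilabel(m[tr, , drop = FALSE],
                              labels[tr, !single, drop = FALSE],
                              base, selector, k, seed = derive_seed(seed, f))
      pred[te, !single] <- predict_labels(fit, m[te, , drop = FALSE])
    }
    for (li in which(single))
      pred[te, li] <- labels[which(tr)[1], li]
  }
  c(eval_multilabel(pred, labels), list(fold_id = fold_id, pred = pred))
}

#' Stratified-random multi-label baseline
#'
#' Predicts each label independently as a Bernoulli draw with the label's
#' empirical prevalence; the chance-level reference the trained models
#' must beat.
#'
#' @param labels binary matrix.
#' @param seed RNG seed.
#' @export
random_baseline_multilabel <- function(labels, seed = 1) {
  prev <- colMeans(labels)
  pred <- with_seed(seed, {
    vapply(prev, function(p) stats::rbinom(nrow(labels), 1, p),
           numeric(nrow(labels)))
  })
  eval_multilabel(pred, labels)
}
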