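#' Chou cosine-type distance between two sample vectors
#'
#' \deqn{D(e_1, e_2) = 1 - \frac{e_1 \cdot e_2}{|e_1|\,|e_2|}}
#' The distance lies in [0, 2], is symmetric, and is invariant to positive
#' rescaling of either argument. Zero-norm vectors are rejected because the
#' direction of such a sample is undefined.
#'
#' @param e1,e2 Numeric vectors of equal length over the same feature order.
#' @return Distance in [0, 2].
#' @export
chou_distance <- function(e1, e2) {
  if (length(e1) != length(e2)) stop("feature vectors must have equal length")
  n1 <- sqrt(sum(e1^2))
  n2 <- sqrt(sum(e2^2))
  if (n1 == 0) stop("zero-norm sample vector: e1")
  if (n2 == 0) stop("zero-norm sample vector: e2")
  d <- 1 - sum(e1 * e2) / (n1 * n2)
  min(max(d, 0), 2)
}

#' k-nearest-neighbour prediction under the Chou distance
#'
#' Majority vote among the k training samples closest to the query. Distance
#' ties are broken by training-sample order; vote ties are broken by the
#' label of the single nearest neighbour.
#'
#' @param train Numeric matrix, training samples in rows, features in columns.
#' @param train_labels Label per training row.
#' @param query Numeric feature vector of the sample to classify.
#' @param k Neighbour count, `1 <= k <= nrow(train)`.
#' @return The predicted label.
#' @export
knn_predict <- function(train, train_labels, query, k = 1L) {
  train <- as.matrix(train)
  if (nrow(train) == 0L) stop("empty training set")
  stopifnot(length(train_labels) == nrow(train), k >= 1L, k <= nrow(train))
  d <- vapply(seq_len(nrow(train)), function(i) chou_distance(train[i, ], query),
              numeric(1))
  vote_labels(d, train_labels, k)
}

# shared voting rule: stable order by (distance, training index)
vote_labels <- function(d, labels, k) {
  ord <- order(d, seq_along(d), method = "radix")
  top <- labels[ord[seq_len(k)]]
  tab <- table(top)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) {
    cast_label(winners, labels)
  } else {
    labels[ord[1L]]
  }
}

cast_label <- function(value, template) {
  if (is.integer(template)) as.integer(value)
  else if (is.numeric(template)) as.numeric(value)
  else value
}

#' Jackknife (leave-one-out) classification accuracy
#'
#' Each sample is predicted from all remaining samples with
#' k-nearest-neighbour under the Chou distance, restricted to a feature
#' subset. Accuracy is \eqn{(TP+TN)/(TP+TN+FP+FN)} with tumour (label 1) as
#' the positive class.
#'
#' @param dataset An `expression_dataset` with at least 2 samples and both
#'   classes present.
#' @param feature_subset Probe IDs (or row indices) of the features to use.
#' @param k Neighbour count.
#' @param standardize If `TRUE`, z-score each feature across samples before
#'   computing distances. The cosine-type distance is scale-invariant per
#'   sample but not per feature; default `FALSE` uses values as loaded.
#' @return A list with `accuracy`, `confusion` (named integer vector TP, TN,
#'   FP, FN) and `predictions` (per-sample predicted labels).
#' @export
jackknife_accuracy <- function(dataset, feature_subset, k = 1L,
                               standardize = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  m <- ncol(dataset$values)
  if (m < 2L) stop("jackknife requires at least 2 samples")
  if (length(unique(dataset$labels)) < 2L)
    stop("both phenotype classes must be present")
  if (is.character(feature_subset)) {
    idx <- match(feature_subset, dataset$probe_ids)
    if (anyNA(idx)) stop("unknown probe ID(s): ",
                         paste(feature_subset[is.na(idx)], collapse = ", "))
  } else idx <- feature_subset
  X <- t(dataset$values[idx, , drop = FALSE])   # samples x features
  if (standardize) X <- scale(X)
  norms <- sqrt(rowSums(X^2))
  if (any(norms == 0)) {
    stop("zero-norm sample vector: ",
         paste(dataset$sample_ids[norms == 0], collapse = ", "))
  }
  Xn <- X / norms
  D <- 1 - tcrossprod(Xn)
  D <- pmin(pmax(D, 0), 2)

  labels <- dataset$labels
  preds <- integer(m)
  for (i in seq_len(m)) {
    train_idx <- setdiff(seq_len(m), i)
    if (length(train_idx) == 0L) stop("empty training set in jackknife round")
    kk <- min(k, length(train_idx))
    preds[i] <- vote_labels(D[i, train_idx], labels[train_idx], kk)
  }
  conf <- confusion_counts(labels, preds)
  list(accuracy = confusion_accuracy(conf), confusion = conf,
       predictions = stats::setNames(preds, dataset$sample_ids))
}

#' Confusion counts with tumour (1) as the positive class
#' @param truth,predicted Integer label vectors (1 = tumour, 0 = non-tumour).
#' @return Named integer vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  c(TP = sum(truth == 1L & predicted == 1L),
    TN = sum(truth == 0L & predicted == 0L),
    FP = sum(truth == 0L & predicted == 1L),
    FN = sum(truth == 1L & predicted == 0L))
}

#' Accuracy from confusion counts
#'
#' \eqn{(TP + TN) / (TP + TN + FP + FN)}.
#'
#' @param confusion Named vector with elements TP, TN, FP, FN.
#' @return Accuracy in [0, 1].
#' @export
confusion_accuracy <- function(confusion) {
  total <- sum(confusion[c("TP", "TN", "FP", "FN")])
  if (total == 0) stop("no evaluated samples")
  unname((confusion[["TP"]] + confusion[["TN"]]) / total)
}
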